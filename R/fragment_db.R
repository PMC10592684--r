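# Fragment-pair cluster database: greedy RMSD clustering, per-position
# amino-acid frequencies, and per-position interaction weights.

FRAG_LEN <- 5L
RMSD_CLUSTER_FLOOR <- 0.01  # avoids division blowup for singleton clusters

#' Construct a 5-residue fragment
#'
#' @param bb 15 x 3 backbone coordinates (N, CA, C per residue, in order).
#' @param seq character vector of 5 one-letter amino acids.
#' @param cb optional 5 x 3 C-beta coordinates (NA rows where absent).
#' @param sc optional list of 5 side-chain heavy-atom coordinate matrices
#'   (0-row matrices for glycine).
#' @return Object of class `fragment`.
#' @export
make_fragment <- function(bb, seq = rep("A", FRAG_LEN), cb = NULL,
                          sc = NULL) {
  bb <- as.matrix(bb)
  if (nrow(bb) != 3L * FRAG_LEN) stop("fragment backbone must be 15 x 3")
  seq <- toupper(seq)
  if (length(seq) == 1L && nchar(seq) == FRAG_LEN) {
    seq <- strsplit(seq, "")[[1]]
  }
  bad <- !(seq %in% AA20)
  if (any(bad)) {
    mapped <- c(MSE = "M", SEC = "C")[seq[bad]]
    if (anyNA(mapped)) stop("non-canonical residue(s): ",
                            paste(seq[bad][is.na(mapped)], collapse = ","))
    seq[bad] <- mapped
  }
  if (is.null(sc)) {
    sc <- lapply(seq_len(FRAG_LEN), function(i) {
      if (!is.null(cb) && !anyNA(cb[i, ]) && seq[i] != "G") {
        matrix(cb[i, ], 1, 3)
      } else matrix(numeric(0), 0, 3)
    })
  }
  structure(list(bb = bb, seq = seq, cb = cb, sc = sc), class = "fragment")
}

#' Construct a paired fragment (mapped + paired fragment)
#' @param f1,f2 `fragment` objects (the mapped and the paired fragment).
#' @export
fragment_pair <- function(f1, f2) {
  structure(list(f1 = f1, f2 = f2), class = "fragment_pair")
}

# All heavy atoms of a fragment (backbone + CB + side chain).
fragment_atoms <- function(f) {
  sc <- do.call(rbind, f$sc)
  rbind(f$bb, sc)
}

# Orientation RMSD between two pairs: superpose on the mapped fragment's
# backbone, measure over the paired fragment's backbone. This matches the
# geometry of ghost-fragment matching.
pair_rmsd <- function(p, q) {
  fit <- kabsch_superpose(p$f1$bb, q$f1$bb)
  coord_rmsd(transform_points(p$f2$bb, fit$transform), q$f2$bb)
}

#' Cluster paired fragments by orientation RMSD
#'
#' Deterministic greedy leader clustering in input order: each pair joins
#' the first existing cluster whose representative lies within
#' `rmsd_threshold` (measured over the paired fragment after superposing
#' the mapped fragments); otherwise it founds a new cluster and becomes
#' its representative. `rmsd_cluster` is the mean member RMSD to the
#' representative.
#'
#' @param pairs list of `fragment_pair` objects sharing one type pair.
#' @param rmsd_threshold clustering radius in Angstrom.
#' @param type_pair length-2 character type labels carried on the output.
#' @return list of cluster objects (fields: id, type_pair, rep, members,
#'   member_rmsd, rmsd_cluster, M, freq, t).
#' @export
cluster_fragment_pairs <- function(pairs, rmsd_threshold = 1,
                                   type_pair = c("f1", "f2")) {
  clusters <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      r <- pair_rmsd(p, clusters[[k]]$rep)
      if (r <= rmsd_threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, list(p))
        clusters[[k]]$member_rmsd <- c(clusters[[k]]$member_rmsd, r)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters <- c(clusters, list(list(rep = p, members = list(p),
                                        member_rmsd = 0)))
    }
  }
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    cl$id <- sprintf("%s_%s_%d", type_pair[1], type_pair[2], k)
    cl$type_pair <- type_pair
    cl$M <- length(cl$members)
    cl$rmsd_cluster <- mean(cl$member_rmsd)
    cl$freq <- cluster_frequencies(cl$members)
    cl$t <- interaction_weight(cl$members)
    clusters[[k]] <- cl
  }
  clusters
}

#' Cumulative amino-acid frequencies of cluster members
#'
#' Tallies the amino acids observed at each of the ten positions (five per
#' fragment) over all members; each row sums to one.
#'
#' @param members list of `fragment_pair` objects.
#' @return 10 x 20 frequency matrix (rows: mapped positions 1-5 then
#'   paired positions 6-10; columns: [AA20]).
#' @export
cluster_frequencies <- function(members) {
  if (!length(members)) stop("no members")
  freq <- matrix(0, 2L * FRAG_LEN, length(AA20),
                 dimnames = list(NULL, AA20))
  for (m in members) {
    aa <- c(m$f1$seq, m$f2$seq)
    for (p in seq_along(aa)) freq[p, aa[p]] <- freq[p, aa[p]] + 1
  }
  freq / length(members)
}

#' Per-position interaction weights
#'
#' For each member and each residue position, the fraction of the
#' residue's side-chain heavy atoms that contact (any heavy-atom pair
#' within `contact_dist`) the opposite fragment of the pair; each atom
#' counts at most once per member. The position weight t_r is the mean of
#' that fraction over members. Glycine (no side-chain atoms) contributes 0.
#'
#' @param members list of `fragment_pair` objects.
#' @param contact_dist heavy-atom contact distance (default 4.5 Angstrom).
#' @return numeric vector of length 10 in \[0, 1\].
#' @export
interaction_weight <- function(members, contact_dist = 4.5) {
  if (!length(members)) stop("no members")
  acc <- matrix(0, length(members), 2L * FRAG_LEN)
  for (mi in seq_along(members)) {
    m <- members[[mi]]
    opp <- list(fragment_atoms(m$f2), fragment_atoms(m$f1))
    frs <- list(m$f1, m$f2)
    for (side in 1:2) {
      f <- frs[[side]]
      for (p in seq_len(FRAG_LEN)) {
        sc <- f$sc[[p]]
        pos <- (side - 1L) * FRAG_LEN + p
        if (!nrow(sc)) { acc[mi, pos] <- 0; next }
        o <- opp[[side]]
        d2 <- outer(rowSums(sc^2), rowSums(o^2), "+") - 2 * sc %*% t(o)
        hits <- rowSums(d2 < contact_dist^2 + 1e-12) > 0
        acc[mi, pos] <- sum(hits) / nrow(sc)
      }
    }
  }
  pmin(pmax(colMeans(acc), 0), 1)
}

#' Assemble a fragment database
#'
#' @param types named list of single-fragment type representatives
#'   (15 x 3 backbone matrices).
#' @param clusters list of clusters from [cluster_fragment_pairs()].
#' @param typing_threshold backbone RMSD below which a window is assigned
#'   a fragment type.
#' @return Object of class `fragment_db`.
#' @export
fragment_db <- function(types, clusters, typing_threshold = 0.75) {
  names(clusters) <- vapply(clusters, `[[`, "", "id")
  for (cl in clusters) {
    if (!all(cl$type_pair %in% names(types))) {
      stop("cluster ", cl$id, " declares unknown fragment type")
    }
    if (any(abs(rowSums(cl$freq) - 1) > 1e-9)) {
      stop("cluster ", cl$id, " frequencies do not sum to 1")
    }
  }
  structure(list(version = "cageforge-db-1", frag_length = FRAG_LEN,
                 typing_threshold = typing_threshold,
                 types = types, clusters = clusters),
            class = "fragment_db")
}

#' @export
print.fragment_db <- function(x, ...) {
  cat(sprintf("fragment_db: %d type(s), %d cluster(s), typing threshold %.2f A\n",
              length(x$types), length(x$clusters), x$typing_threshold))
  invisible(x)
}

fmt_mat <- function(m) apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                                     collapse = "\t"))
parse_mat <- function(lines, ncol) {
  m <- do.call(rbind, lapply(strsplit(lines, "\t"), as.numeric))
  if (is.null(m) || ncol(m) != ncol) stop("malformed matrix block")
  m
}

write_fragment_block <- function(f, con) {
  writeLines(c(paste0("seq\t", paste(f$seq, collapse = "")),
               "bb", fmt_mat(f$bb)), con)
  writeLines("sc", con)
  for (p in seq_len(FRAG_LEN)) {
    writeLines(paste0("res\t", p, "\t", nrow(f$sc[[p]])), con)
    if (nrow(f$sc[[p]])) writeLines(fmt_mat(f$sc[[p]]), con)
  }
}

read_fragment_block <- function(lines, pos) {
  seq <- strsplit(sub("^seq\t", "", lines[pos]), "")[[1]]
  stopifnot(lines[pos + 1] == "bb")
  bb <- parse_mat(lines[pos + 2:16], 3)
  pos <- pos + 17
  stopifnot(lines[pos] == "sc")
  pos <- pos + 1
  sc <- vector("list", FRAG_LEN)
  for (p in seq_len(FRAG_LEN)) {
    hdr <- strsplit(lines[pos], "\t")[[1]]
    nat <- as.integer(hdr[3])
    sc[[p]] <- if (nat > 0) parse_mat(lines[pos + seq_len(nat)], 3)
               else matrix(numeric(0), 0, 3)
    pos <- pos + 1 + nat
  }
  list(fragment = make_fragment(bb, seq, sc = sc), next_pos = pos)
}

#' Save a fragment database to a directory
#'
#' Plain-text layout: a JSON manifest (version, typing threshold, type and
#' cluster ids) plus per-type and per-cluster TSV tables. Round-trips all
#' fields losslessly.
#'
#' @param db `fragment_db`.
#' @param path output directory (created if needed).
#' @export
save_fragment_db <- function(db, path) {
  dir.create(file.path(path, "types"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "clusters"), showWarnings = FALSE)
  manifest <- list(version = db$version, frag_length = db$frag_length,
                   typing_threshold = db$typing_threshold,
                   types = names(db$types), clusters = names(db$clusters))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(db$types)) {
    writeLines(fmt_mat(db$types[[nm]]),
               file.path(path, "types", paste0(nm, ".tsv")))
  }
  for (nm in names(db$clusters)) {
    cl <- db$clusters[[nm]]
    con <- file.path(path, "clusters", paste0(nm, ".txt"))
    out <- file(con, "w")
    on.exit(close(out), add = TRUE)
    writeLines(c(paste0("id\t", cl$id),
                 paste0("type_pair\t", paste(cl$type_pair, collapse = "\t")),
                 paste0("M\t", cl$M),
                 paste0("rmsd_cluster\t", sprintf("%.17g", cl$rmsd_cluster)),
                 paste0("t\t", paste(sprintf("%.17g", cl$t), collapse = "\t")),
                 "freq", fmt_mat(cl$freq), "rep_f1"), out)
    write_fragment_block(cl$rep$f1, out)
    writeLines("rep_f2", out)
    write_fragment_block(cl$rep$f2, out)
    close(out)
    on.exit(NULL, add = FALSE)
  }
  invisible(path)
}

#' Load a fragment database saved by [save_fragment_db()]
#' @param path database directory.
#' @return `fragment_db`.
#' @export
load_fragment_db <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a fragment database: missing manifest")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$version, "cageforge-db-1")) {
    stop("fragment database version mismatch: ", manifest$version)
  }
  types <- lapply(manifest$types, function(nm) {
    parse_mat(readLines(file.path(path, "types", paste0(nm, ".tsv"))), 3)
  })
  names(types) <- manifest$types
  clusters <- lapply(manifest$clusters, function(nm) {
    lines <- readLines(file.path(path, "clusters", paste0(nm, ".txt")))
    field <- function(tag) {
      ln <- lines[startsWith(lines, paste0(tag, "\t"))][1]
      if (is.na(ln)) stop("truncated cluster file for ", nm)
      strsplit(ln, "\t")[[1]][-1]
    }
    fstart <- which(lines == "freq")[1]
    if (is.na(fstart) || fstart + 10 > length(lines)) {
      stop("truncated cluster file for ", nm)
    }
    r1 <- which(lines == "rep_f1")[1]
    r2 <- which(lines == "rep_f2")[1]
    f1 <- read_fragment_block(lines, r1 + 1L)
    f2 <- read_fragment_block(lines, r2 + 1L)
    list(id = field("id"), type_pair = field("type_pair"),
         M = as.integer(field("M")),
         rmsd_cluster = as.numeric(field("rmsd_cluster")),
         t = as.numeric(field("t")),
         freq = {
           f <- parse_mat(lines[fstart + 1:10], 20)
           colnames(f) <- AA20
           f
         },
         rep = fragment_pair(f1$fragment, f2$fragment),
         members = NULL, member_rmsd = NULL)
  })
  names(clusters) <- manifest$clusters
  db <- fragment_db(types, clusters,
                    typing_threshold = manifest$typing_threshold)
  db
}
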