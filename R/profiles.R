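# Position-specific amino-acid profiles: fragment profile, evolutionary
# profile (hhm), tertiary blend, cross-entropy and profile losses.

PROFILE_EPS <- 1e-9  # additive smoothing inside logarithms (nats)

#' Construct an amino-acid profile
#'
#' @param freq L x 20 matrix of per-residue frequencies over the 20
#'   canonical amino acids ([AA20] column order); valid rows must sum to 1.
#' @param valid logical length-L validity flags (invalid rows carry no
#'   information and are excluded from all losses).
#' @param flavor one of fragment, evolutionary, tertiary, inference,
#'   structure-inference.
#' @return Object of class `aa_profile`.
#' @export
aa_profile <- function(freq, valid = NULL,
                       flavor = c("fragment", "evolutionary", "tertiary",
                                  "inference", "structure-inference")) {
  flavor <- match.arg(flavor)
  freq <- as.matrix(freq)
  if (ncol(freq) != 20L) stop("profile needs 20 amino-acid columns")
  colnames(freq) <- AA20
  if (is.null(valid)) valid <- !apply(freq, 1, anyNA) & rowSums(freq) > 0
  bad <- valid & abs(rowSums(freq) - 1) > 1e-9
  if (any(bad)) stop("valid profile rows must sum to 1 (rows ",
                     paste(utils::head(which(bad), 3), collapse = ","), ")")
  structure(list(freq = freq, valid = valid, flavor = flavor),
            class = "aa_profile")
}

#' @export
print.aa_profile <- function(x, ...) {
  cat(sprintf("aa_profile (%s): %d positions, %d valid\n",
              x$flavor, nrow(x$freq), sum(x$valid)))
  invisible(x)
}

#' Fragment profile from pose observations
#'
#' Per residue, every covering fragment observation contributes its
#' cluster's amino-acid distribution at the matching fragment position,
#' scaled by the observation's match score times the position's
#' interaction weight and normalized by the summed weights:
#' `P_aa = sum_F f_aa^F (m_F t_F) / mt_total`. Residues without
#' observations (or with all-zero weights) are invalid rows.
#'
#' @param observations observation table (see [find_observations()]).
#' @param db `fragment_db` providing cluster frequencies and weights.
#' @param n_res profile length (residues of the component, numbered 1..L).
#' @param component `"a"` or `"b"`: which side of the observations to
#'   profile.
#' @return `aa_profile` of flavor fragment, with per-residue mean match
#'   score and interaction weight attached as the `quality` attribute.
#' @export
fragment_profile <- function(observations, db, n_res,
                             component = c("a", "b")) {
  component <- match.arg(component)
  num <- matrix(0, n_res, 20L, dimnames = list(NULL, AA20))
  den <- numeric(n_res)
  msum <- tsum <- nobs <- numeric(n_res)
  if (!is.null(observations) && nrow(observations)) {
    resi <- if (component == "a") observations$resi_a else observations$resi_b
    off <- if (component == "a") 0L else FRAG_LEN
    for (i in seq_len(nrow(observations))) {
      cl <- db$clusters[[observations$cluster[i]]]
      if (is.null(cl)) stop("observation references unknown cluster ",
                            observations$cluster[i])
      m <- observations$m[i]
      for (p in seq_len(FRAG_LEN)) {
        r <- resi[i] + p - 3L
        if (r < 1L || r > n_res) next
        w <- m * cl$t[off + p]
        num[r, ] <- num[r, ] + w * cl$freq[off + p, ]
        den[r] <- den[r] + w
        msum[r] <- msum[r] + m
        tsum[r] <- tsum[r] + cl$t[off + p]
        nobs[r] <- nobs[r] + 1
      }
    }
  }
  valid <- den > 0
  if (any(!valid & nobs > 0)) {
    warning("residue(s) with observations but zero match-weight: ",
            paste(utils::head(which(!valid & nobs > 0), 5), collapse = ","))
  }
  freq <- num
  freq[valid, ] <- num[valid, , drop = FALSE] / den[valid]
  prof <- aa_profile(freq, valid, flavor = "fragment")
  attr(prof, "quality") <- data.frame(
    resi = seq_len(n_res),
    m_bar = ifelse(nobs > 0, msum / nobs, 0),
    t_bar = ifelse(nobs > 0, tsum / nobs, 0))
  prof
}

#' Parse an hhm profile HMM into an evolutionary profile
#'
#' Reads the hhm dialect (20 emission columns per match state). Model
#' values convert to frequencies as `2^(-v/1000)`; `*` maps to 0; rows are
#' renormalized to sum 1.
#'
#' @param path hhm file path.
#' @return `aa_profile` of flavor evolutionary, with the model's residue
#'   letters attached as attribute `sequence`.
#' @export
read_hhm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^HMM\\s", lines)[1]
  if (is.na(hdr)) stop("malformed hhm: no 'HMM' header line found")
  aa_order <- strsplit(trimws(sub("^HMM", "", lines[hdr])), "\\s+")[[1]]
  if (length(aa_order) != 20L || !all(aa_order %in% AA20)) {
    stop(sprintf("malformed hhm header at line %d: expected 20 amino-acid columns",
                 hdr))
  }
  i <- hdr + 2L  # skip the transition header line
  rows <- list()
  seqs <- character(0)
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "//") break
    if (ln == "") { i <- i + 1L; next }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 22L || !grepl("^[A-Z-]$", tok[1])) {
      # preamble lines (begin-state transitions) may precede match states
      if (!length(rows)) { i <- i + 1L; next }
      stop(sprintf("malformed hhm match state at line %d", i))
    }
    v <- tok[3:22]
    freq <- ifelse(v == "*", 0, 2^(-suppressWarnings(as.numeric(v)) / 1000))
    if (anyNA(freq)) stop(sprintf("malformed hhm value at line %d", i))
    rows[[length(rows) + 1L]] <- freq
    seqs <- c(seqs, tok[1])
    i <- i + 2L  # skip the transition line
  }
  if (!length(rows)) stop("malformed hhm: no match states")
  raw <- do.call(rbind, rows)
  # map the file's column order onto AA20
  freq <- matrix(0, nrow(raw), 20L, dimnames = list(NULL, AA20))
  freq[, aa_order] <- raw
  tot <- rowSums(freq)
  valid <- tot > 0
  freq[valid, ] <- freq[valid, , drop = FALSE] / tot[valid]
  prof <- aa_profile(freq, valid, flavor = "evolutionary")
  attr(prof, "sequence") <- paste(seqs, collapse = "")
  prof
}

#' Tertiary profile: quality-weighted blend of fragment and evolution
#'
#' Rows without fragment information copy the evolutionary row. Rows with
#' fragment data mix with an effective fragment weight
#' `alpha' = alpha * min(1, m_bar/m_thresh) * min(1, t_bar/t_thresh)`:
#' at or above both quality thresholds the fragment profile receives the
#' full maximum weight `alpha` (0.5 by default) and the evolutionary
#' profile the remaining `1 - alpha`; weak observations shrink the
#' fragment contribution in proportion to their discrepancy.
#'
#' @param frag fragment `aa_profile` (with its `quality` attribute, or
#'   supply `quality`).
#' @param evo evolutionary `aa_profile` of equal length.
#' @param alpha maximum fragment weight (default 0.5).
#' @param m_thresh,t_thresh quality thresholds; defaults are the database
#'   means implied by the observations (see `quality`).
#' @param quality optional data frame resi, m_bar, t_bar.
#' @return `aa_profile` of flavor tertiary.
#' @export
blend_tertiary <- function(frag, evo, alpha = 0.5, m_thresh = 0.5,
                           t_thresh = 0.5, quality = NULL) {
  if (nrow(frag$freq) != nrow(evo$freq)) stop("profile lengths differ")
  if (is.null(quality)) quality <- attr(frag, "quality")
  if (is.null(quality)) stop("per-residue quality (m_bar, t_bar) required")
  L <- nrow(frag$freq)
  freq <- evo$freq
  valid <- evo$valid
  aprime <- numeric(L)
  for (r in seq_len(L)) {
    if (!frag$valid[r]) next
    a <- alpha * min(1, quality$m_bar[r] / m_thresh) *
      min(1, quality$t_bar[r] / t_thresh)
    aprime[r] <- a
    if (!evo$valid[r]) {
      freq[r, ] <- frag$freq[r, ]
      valid[r] <- TRUE
    } else {
      freq[r, ] <- a * frag$freq[r, ] + (1 - a) * evo$freq[r, ]
    }
  }
  prof <- aa_profile(freq, valid, flavor = "tertiary")
  attr(prof, "alpha_prime") <- aprime
  prof
}

# Resolve a residue subset to valid row indices.
resolve_subset <- function(n, subset, valid) {
  idx <- if (is.null(subset)) seq_len(n) else as.integer(subset)
  idx <- idx[idx >= 1L & idx <= n & valid[idx]]
  if (!length(idx)) stop("empty residue subset (or no valid rows in it)")
  idx
}

#' Cross-entropy between two profiles
#'
#' `CE(P, Q) = -sum_aa P_aa * ln(Q_aa + eps)` per residue (natural log;
#' values are in nats). Lower values mean closer agreement.
#'
#' @param p,q `aa_profile`s of equal length.
#' @param subset residue indices (default: rows valid in both).
#' @param eps additive smoothing (default 1e-9).
#' @return list with `per_residue` (named by residue index) and `mean`.
#' @export
cross_entropy <- function(p, q, subset = NULL, eps = PROFILE_EPS) {
  if (nrow(p$freq) != nrow(q$freq)) stop("profile lengths differ")
  idx <- resolve_subset(nrow(p$freq), subset, p$valid & q$valid)
  ce <- -rowSums(p$freq[idx, , drop = FALSE] *
                   log(q$freq[idx, , drop = FALSE] + eps))
  list(per_residue = stats::setNames(ce, idx), mean = mean(ce))
}

#' Negative log likelihood of a sequence under a profile
#'
#' Mean over the subset of `-ln(P[residue, aa] + eps)`. The same operation
#' serves the fragment profile loss, the evolution profile loss, and a
#' neural-network inference score when the supplied profile holds
#' inference probabilities.
#'
#' @param sequence one-letter string or character vector, same length as
#'   the profile.
#' @param profile `aa_profile`.
#' @param subset residue indices (default: all valid rows).
#' @param eps additive smoothing.
#' @return list with `per_residue` and `mean` (nats).
#' @export
profile_loss <- function(sequence, profile, subset = NULL,
                         eps = PROFILE_EPS) {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  if (length(aa) != nrow(profile$freq)) {
    stop("sequence length does not match profile length")
  }
  idx <- resolve_subset(nrow(profile$freq), subset, profile$valid)
  col <- match(aa[idx], AA20)
  if (anyNA(col)) stop("non-canonical residue in sequence")
  nll <- -log(profile$freq[cbind(idx, col)] + eps)
  list(per_residue = stats::setNames(nll, idx), mean = mean(nll))
}

#' Percent sequence identity over a subset
#' @param a,b one-letter strings or character vectors of equal length.
#' @param subset residue indices (default all).
#' @return Percent identity in \[0, 100\].
#' @export
sequence_identity <- function(a, b, subset = NULL) {
  aa <- if (length(a) == 1L) strsplit(a, "")[[1]] else a
  bb <- if (length(b) == 1L) strsplit(b, "")[[1]] else b
  if (length(aa) != length(bb)) stop("sequence lengths differ")
  idx <- if (is.null(subset)) seq_along(aa) else as.integer(subset)
  if (!length(idx)) stop("empty residue subset")
  100 * mean(aa[idx] == bb[idx])
}

#' Fraction of mutated positions
#' @param designed,reference sequences of equal length.
#' @param subset residue indices (default all).
#' @export
mutation_fraction <- function(designed, reference, subset = NULL) {
  1 - sequence_identity(designed, reference, subset) / 100
}

#' Read an L x 20 amino-acid probability table
#'
#' Consumes externally produced per-residue probability matrices (e.g.
#' neural-network inference output) as TSV with a header of one-letter
#' amino acids. Rows are renormalized.
#'
#' @param path TSV path.
#' @param flavor profile flavor tag (default inference).
#' @return `aa_profile`.
#' @export
read_profile_tsv <- function(path, flavor = "inference") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  miss <- setdiff(AA20, names(df))
  if (length(miss)) stop("probability table missing columns: ",
                         paste(miss, collapse = ","))
  m <- as.matrix(df[, AA20])
  tot <- rowSums(m)
  valid <- tot > 0
  m[valid, ] <- m[valid, , drop = FALSE] / tot[valid]
  aa_profile(m, valid, flavor = flavor)
}

#' Write a profile as TSV
#' @param profile `aa_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile$freq)
  df <- cbind(resi = seq_len(nrow(df)), valid = as.integer(profile$valid),
              df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
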