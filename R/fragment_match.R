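# Fragment typing of surface residues, ghost-fragment generation,
# observation matching and the normalized Nanohedra score.

#' Fragment match score (closed form)
#'
#' `m = 1 / (1 + (rmsd_frag / rmsd_cluster)^2)`: 1 at a perfect match,
#' 0.5 when the observation deviates exactly as much as an average cluster
#' member, strictly decreasing in `rmsd_frag`.
#'
#' @param rmsd_frag RMSD of the observation to the cluster representative
#'   (Angstrom, non-negative).
#' @param rmsd_cluster mean member RMSD of the cluster; floored at 0.01
#'   Angstrom to keep singleton clusters finite.
#' @return Match score in (0, 1\].
#' @export
match_score <- function(rmsd_frag, rmsd_cluster) {
  if (any(rmsd_frag < 0) || any(rmsd_cluster < 0)) {
    stop("RMSD values must be non-negative")
  }
  rc <- pmax(rmsd_cluster, RMSD_CLUSTER_FLOOR)
  1 / (1 + (rmsd_frag / rc)^2)
}

#' Assign a fragment type to a 5-residue backbone window
#'
#' Returns the type whose representative has minimal backbone RMSD to the
#' window, provided it is below the database typing threshold. Ties break
#' deterministically to the lexicographically lowest type id.
#'
#' @param window_bb 15 x 3 backbone coordinates (N, CA, C per residue).
#' @param db `fragment_db`.
#' @return Type id (character) or `NA_character_` when untypeable.
#' @export
assign_fragment_type <- function(window_bb, db) {
  ids <- sort(names(db$types))
  if (!length(ids)) return(NA_character_)
  rmsds <- vapply(ids, function(nm) {
    kabsch_superpose(db$types[[nm]], window_bb)$rmsd
  }, numeric(1))
  best <- which.min(rmsds)  # which.min takes the first (lowest id) on ties
  if (rmsds[best] <= db$typing_threshold) ids[best] else NA_character_
}

#' Typed surface fragments of an oligomer
#'
#' Slides a 5-residue window over every chain (terminal residues lacking
#' +/-2 neighbours are untyped), keeps windows whose central residue is
#' surface exposed (relative side-chain SASA above `exposure_min`), and
#' assigns each a fragment type from the database. With `trim_termini`,
#' terminal coil residues (up to the first helix/strand residue) are
#' removed from the searchable surface before typing.
#'
#' @param s Structure (one oligomer).
#' @param db `fragment_db`.
#' @param exposure_min minimum relative side-chain SASA (default 0.1).
#' @param trim_termini drop terminal loop/coil stretches first.
#' @param n_points SASA quadrature points for the exposure gate (a coarse
#'   default keeps the gate cheap).
#' @return list of typed fragments: chain, resi (central), residues, type,
#'   bb (15 x 3), cb (5 x 3).
#' @export
surface_fragments <- function(s, db, exposure_min = 0.1,
                              trim_termini = FALSE, n_points = 120) {
  rs <- residue_sasa(s, n_points = n_points)
  ss <- if (trim_termini) assign_secondary_structure(s) else NULL
  rt <- residue_table(s)
  akey <- atom_residue_key(s)
  keys <- residue_key(rt$chain, rt$resi, rt$icode)
  out <- list()
  for (ch in unique(rt$chain)) {
    idx <- which(rt$chain == ch)
    keep <- rep(TRUE, length(idx))
    if (trim_termini) {
      lab <- ss$ss[match(paste(ch, rt$resi[idx]), paste(ss$chain, ss$resi))]
      first <- match(TRUE, lab != "C")
      last <- length(lab) + 1L - match(TRUE, rev(lab) != "C")
      if (is.na(first)) keep[] <- FALSE
      else keep <- seq_along(idx) >= first & seq_along(idx) <= last
    }
    for (j in seq_along(idx)) {
      if (j < 3L || j > length(idx) - 2L) next
      if (!all(keep[(j - 2L):(j + 2L)])) next
      i <- idx[j]
      if (rs$sc_rel[i] < exposure_min) next
      win <- idx[(j - 2L):(j + 2L)]
      bb <- matrix(NA_real_, 15, 3)
      cb <- matrix(NA_real_, 5, 3)
      ok <- TRUE
      for (w in seq_along(win)) {
        in_res <- which(akey == keys[win[w]])
        for (bi in 1:3) {
          at <- in_res[s$atoms$name[in_res] == c("N", "CA", "C")[bi]]
          if (!length(at)) { ok <- FALSE; break }
          bb[(w - 1L) * 3L + bi, ] <-
            as.numeric(s$atoms[at[1], c("x", "y", "z")])
        }
        cbat <- in_res[s$atoms$name[in_res] == "CB"]
        if (length(cbat)) {
          cb[w, ] <- as.numeric(s$atoms[cbat[1], c("x", "y", "z")])
        }
        if (!ok) break
      }
      if (!ok) next
      ty <- assign_fragment_type(bb, db)
      if (is.na(ty)) next
      out[[length(out) + 1L]] <- list(chain = ch, resi = rt$resi[i],
                                      residues = rt$resi[win], type = ty,
                                      bb = bb, cb = cb)
    }
  }
  out
}

#' Generate ghost fragments
#'
#' For each typed surface fragment and each database cluster whose mapped
#' type matches the fragment's type, the cluster's paired-fragment
#' representative is placed by superposing the mapped representative onto
#' the observed fragment. Placements clashing with the source oligomer's
#' backbone or C-beta atoms (any heavy atom within `clash_dist`) are
#' discarded; the survivors are the ghost fragments.
#'
#' @param frags typed fragments from [surface_fragments()].
#' @param db `fragment_db`.
#' @param clash_structure Structure providing the backbone/CB clash atoms
#'   (normally the source oligomer itself).
#' @param clash_dist clash distance in Angstrom (default 2.1).
#' @return list of ghosts: source_chain, source_resi, cluster, target_type,
#'   bb, cb, type_rmsd.
#' @export
generate_ghosts <- function(frags, db, clash_structure, clash_dist = 2.1) {
  sel <- clash_structure$atoms$name %in% c(BACKBONE_NAMES, "CB")
  wall <- atom_coords(clash_structure)[sel, , drop = FALSE]
  w2 <- rowSums(wall^2)
  ghosts <- list()
  for (fr in frags) {
    for (cl in db$clusters) {
      if (cl$type_pair[1] != fr$type) next
      fit <- kabsch_superpose(cl$rep$f1$bb, fr$bb)
      gbb <- transform_points(cl$rep$f2$bb, fit$transform)
      gcb <- if (!is.null(cl$rep$f2$cb)) {
        transform_points(cl$rep$f2$cb, fit$transform)
      } else NULL
      gatoms <- rbind(gbb, gcb[stats::complete.cases(gcb), , drop = FALSE])
      d2 <- outer(rowSums(gatoms^2), w2, "+") - 2 * gatoms %*% t(wall)
      if (min(d2) < clash_dist^2) next
      ghosts[[length(ghosts) + 1L]] <-
        list(source_chain = fr$chain, source_resi = fr$resi,
             cluster = cl$id, target_type = cl$type_pair[2],
             bb = gbb, cb = gcb, type_rmsd = fit$rmsd)
    }
  }
  ghosts
}

#' Continuous-ghost filter
#'
#' Keeps only ghosts whose placement co-locates (backbone RMSD within
#' `match_threshold`, no superposition) with a ghost originating from a
#' different source residue of the same component — e.g. residues i and
#' i+4 of one helix produce continuous ghosts when their ghost fragments
#' occupy the same location.
#'
#' @param ghosts list from [generate_ghosts()].
#' @param match_threshold co-location RMSD threshold (default 1 Angstrom).
#' @return Filtered ghost list.
#' @export
continuous_ghost_filter <- function(ghosts, match_threshold = 1) {
  n <- length(ghosts)
  if (n < 2L) return(list())
  src <- vapply(ghosts, function(g) paste(g$source_chain, g$source_resi), "")
  keep <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || src[i] == src[j]) next
      if (coord_rmsd(ghosts[[i]]$bb, ghosts[[j]]$bb) <= match_threshold) {
        keep[i] <- TRUE
        break
      }
    }
  }
  ghosts[keep]
}

#' Match ghost fragments against partner-surface fragments
#'
#' Both inputs must already be in the same frame (post-transform). A match
#' is an observation: a ghost and a partner fragment of the ghost's target
#' type whose direct backbone RMSD (no superposition) is below the match
#' threshold. Each observation carries the Eq.-style match score against
#' the ghost's cluster.
#'
#' @param ghosts ghosts of component A (transformed into the pose frame).
#' @param frags typed surface fragments of component B (same frame).
#' @param db `fragment_db`.
#' @param match_threshold RMSD threshold in Angstrom (default 1).
#' @return data frame of observations: chain_a, resi_a, chain_b, resi_b,
#'   cluster, rmsd, m, central.
#' @export
find_observations <- function(ghosts, frags, db, match_threshold = 1) {
  rows <- list()
  for (g in ghosts) {
    rc <- db$clusters[[g$cluster]]$rmsd_cluster
    for (fr in frags) {
      if (fr$type != g$target_type) next
      r <- coord_rmsd(g$bb, fr$bb)
      if (r > match_threshold) next
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = g$source_chain, resi_a = g$source_resi,
        chain_b = fr$chain, resi_b = fr$resi,
        cluster = g$cluster, rmsd = r, m = match_score(r, rc),
        central = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chain_a = character(), resi_a = integer(),
                      chain_b = character(), resi_b = integer(),
                      cluster = character(), rmsd = numeric(),
                      m = numeric(), central = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Nanohedra score of an observation set
#'
#' Each observation contributes its match score `m` to both of its central
#' residues; the per-residue sum is capped at 2, the total is the sum of
#' the capped per-residue contributions, and the normalized score divides
#' by the number of distinct central fragment residues — giving a maximum
#' normalized value of 2 for any input.
#'
#' @param observations data frame from [find_observations()] (columns
#'   chain_a, resi_a, chain_b, resi_b, m).
#' @param cap per-residue contribution cap (default 2).
#' @return list with `total`, `normalized` and `n_residues`.
#' @export
nanohedra_score <- function(observations, cap = 2) {
  if (is.null(observations) || !nrow(observations)) {
    return(list(total = 0, normalized = 0, n_residues = 0L))
  }
  keys <- c(paste("a", observations$chain_a, observations$resi_a),
            paste("b", observations$chain_b, observations$resi_b))
  contrib <- tapply(rep(observations$m, 2), keys, sum)
  contrib <- pmin(contrib, cap)
  list(total = sum(contrib), normalized = sum(contrib) / length(contrib),
       n_residues = length(contrib))
}
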