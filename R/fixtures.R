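# Deterministic synthetic-structure generators: ideal helical trimers,
# planted fragment training sets and planted docking scenarios. These are
# first-class test-bed generators, not stored fixtures: every output is a
# pure function of its arguments and seed.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Place atom D given three predecessors and internal coordinates
# (NeRF construction).
place_atom <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- -torsion_deg * pi / 180  # right-handed torsion convention
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal-geometry internal coordinates.
GEO <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ca_cb = 1.521,
            ang_c_n_ca = 121.7, ang_n_ca_c = 111.0, ang_ca_c_n = 116.2,
            ang_ca_c_o = 120.5, ang_n_ca_cb = 110.5, tor_cb = -122.6)

# Build one ideal helix backbone (phi=-57, psi=-47, omega=180) of n_res
# residues with N/CA/C/O/CB atoms, axis aligned to +z and centered.
build_ideal_helix <- function(n_res, phi = -57, psi = -47) {
  atoms <- list()
  N <- c(0, 0, 0)
  CA <- c(GEO$n_ca, 0, 0)
  ang <- GEO$ang_n_ca_c * pi / 180
  C <- CA + c(-GEO$ca_c * cos(ang), GEO$ca_c * sin(ang), 0)
  coords <- list(list(N = N, CA = CA, C = C))
  for (i in seq_len(n_res - 1L)) {
    prev <- coords[[i]]
    N2 <- place_atom(prev$N, prev$CA, prev$C, GEO$c_n, GEO$ang_ca_c_n, psi)
    CA2 <- place_atom(prev$CA, prev$C, N2, GEO$n_ca, GEO$ang_c_n_ca, 180)
    C2 <- place_atom(prev$C, N2, CA2, GEO$ca_c, GEO$ang_n_ca_c, phi)
    coords[[i + 1L]] <- list(N = N2, CA = CA2, C = C2)
  }
  # O from the following N (trans to it); last O uses ideal psi
  for (i in seq_len(n_res)) {
    cc <- coords[[i]]
    coords[[i]]$O <- place_atom(cc$N, cc$CA, cc$C, GEO$c_o, GEO$ang_ca_c_o,
                                psi + 180)
    coords[[i]]$CB <- place_atom(cc$C, cc$N, cc$CA, GEO$ca_cb,
                                 GEO$ang_n_ca_cb, GEO$tor_cb)
  }
  ca <- do.call(rbind, lapply(coords, `[[`, "CA"))
  ctr <- colMeans(ca)
  pc <- svd(sweep(ca, 2, ctr))$v[, 1]
  if (pc[3] < 0) pc <- -pc  # axis points from N- to C-terminus side
  if (sum((ca[n_res, ] - ca[1, ]) * pc) < 0) pc <- -pc
  A <- align_z_to(pc)
  tf <- rigid_transform(t(A), as.numeric(-t(A) %*% ctr))
  lapply(coords, function(cc) lapply(cc, function(p) {
    as.numeric(transform_points(matrix(p, 1, 3), tf))
  }))
}

#' Synthetic C3 helical trimer
#'
#' Three ideal alpha-helices (1.5 Angstrom rise and 100 degrees of twist
#' per residue arise from the ideal phi/psi) parallel to z, placed at
#' `radius` from the 3-fold axis and related by exact 120-degree
#' rotations. Backbone geometry is ideal within 0.02 Angstrom / 2 degrees;
#' C-beta atoms are placed at ideal geometry. The sequence is drawn from
#' the seed (backbone independent of it); glycine and proline are excluded
#' so every residue carries a C-beta and helical dihedrals.
#'
#' @param n_res residues per chain (>= 10).
#' @param radius helix-axis distance from the trimer axis (Angstrom).
#' @param seed integer seed (sequence only).
#' @param chains three chain ids.
#' @return A `Structure` with three chains forming one entity.
#' @export
make_helical_trimer <- function(n_res = 18, radius = 8, seed = 1,
                                chains = c("A", "B", "C")) {
  stopifnot(n_res >= 10)
  helix <- build_ideal_helix(n_res)
  seqaa <- with_seed(seed, sample(setdiff(AA20, c("G", "P")), n_res,
                                  replace = TRUE))
  rows <- list()
  for (ci in 1:3) {
    R <- rot_z(120 * (ci - 1))
    shift <- as.numeric(R %*% c(radius, 0, 0))
    for (ri in seq_len(n_res)) {
      for (at in c("N", "CA", "C", "O", "CB")) {
        p <- as.numeric(R %*% helix[[ri]][[at]]) + shift
        rows[[length(rows) + 1L]] <- data.frame(
          name = at, resn = AA1TO3[[seqaa[ri]]], chain = chains[ci],
          resi = ri, x = p[1], y = p[2], z = p[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  new_structure(atoms, entities = stats::setNames(rep("E1", 3), chains))
}

#' Gaussian coordinate perturbation
#'
#' Adds i.i.d. Gaussian noise (s.d. `sigma` per coordinate) to every atom.
#'
#' @param s Structure.
#' @param sigma noise standard deviation in Angstrom.
#' @param seed integer seed.
#' @return Perturbed Structure.
#' @export
perturb_structure <- function(s, sigma, seed = 1) {
  if (sigma == 0) return(s)
  xyz <- atom_coords(s)
  noise <- with_seed(seed, matrix(stats::rnorm(length(xyz), 0, sigma),
                                  nrow(xyz), 3))
  set_atom_coords(s, xyz + noise)
}

# Ideal helical 5-mer backbone used as the single fragment-type
# representative of toy databases.
ideal_helix_window <- function() {
  helix <- build_ideal_helix(FRAG_LEN)
  do.call(rbind, lapply(helix, function(cc) {
    rbind(cc$N, cc$CA, cc$C)
  }))
}

# Draw a length-5 sequence from planted per-position distributions
# (rows of a 5 x 20 matrix over AA20).
draw_seq <- function(probs) {
  vapply(seq_len(nrow(probs)), function(p) {
    sample(AA20, 1, prob = probs[p, ])
  }, "")
}

#' Planted fragment-pair training set
#'
#' Emits `m_members` paired fragments around each of `n_clusters` planted
#' representatives: coordinates carry Gaussian noise (s.d. `sigma`) on the
#' paired fragment, sequences are drawn from planted per-position
#' amino-acid distributions. The returned truth record (representatives,
#' distributions, cluster labels) feeds parameter-recovery tests directly.
#'
#' @param n_clusters planted orientation groups.
#' @param m_members members per cluster.
#' @param sigma coordinate noise (Angstrom) on the paired fragment.
#' @param separation spatial separation between planted representatives
#'   (Angstrom), far above any clustering threshold.
#' @param seed integer seed.
#' @return list: `pairs` (flat member list, cluster-blocked order),
#'   `truth` (list per cluster: rep pair, aa_probs 10 x 20, label vector).
#' @export
make_fragment_training_set <- function(n_clusters = 2, m_members = 20,
                                       sigma = 0.3, separation = 25,
                                       seed = 1) {
  base <- ideal_helix_window()
  with_seed(seed, {
    truth <- list()
    pairs <- list()
    labels <- integer(0)
    for (k in seq_len(n_clusters)) {
      axis <- stats::rnorm(3)
      R <- rotation_about_axis(axis, stats::runif(1, 30, 150))
      offset <- c(separation * k, 0, 0) + stats::rnorm(3)
      rep2_bb <- transform_points(base, rigid_transform(R, offset + c(6, 2, 0)))
      probs <- matrix(0.01, 2L * FRAG_LEN, length(AA20),
                      dimnames = list(NULL, AA20))
      for (p in seq_len(2L * FRAG_LEN)) {
        dom <- sample(length(AA20), 1)
        probs[p, dom] <- probs[p, dom] + 1
        probs[p, ] <- probs[p, ] / sum(probs[p, ])
      }
      members <- lapply(seq_len(m_members), function(j) {
        noise <- if (j == 1L) matrix(0, 15, 3)
                 else matrix(stats::rnorm(45, 0, sigma), 15, 3)
        aa <- c(draw_seq(probs[1:FRAG_LEN, , drop = FALSE]),
                draw_seq(probs[FRAG_LEN + 1:FRAG_LEN, , drop = FALSE]))
        cb1 <- base[seq(2, 15, by = 3), ] + 0.8
        fragment_pair(
          make_fragment(base, aa[1:5], cb = cb1),
          make_fragment(rep2_bb + noise, aa[6:10],
                        cb = rep2_bb[seq(2, 15, by = 3), ] +
                          noise[seq(2, 15, by = 3), , drop = FALSE] + 0.8))
      })
      truth[[k]] <- list(rep = members[[1]], aa_probs = probs,
                         rep2_bb = rep2_bb)
      pairs <- c(pairs, members)
      labels <- c(labels, rep(k, m_members))
    }
    list(pairs = pairs, truth = truth, labels = labels)
  })
}

#' Write a synthetic hhm profile HMM
#'
#' Emits the hhm dialect read by [read_hhm()]: model values are
#' `-1000 * log2(frequency)` rounded to integers, zero frequencies become
#' `*`. Intended for round-trip fixtures; the output is synthetic, not a
#' real alignment-derived model.
#'
#' @param freq L x 20 frequency matrix ([AA20] column order).
#' @param path output path.
#' @param sequence optional reference one-letter sequence (defaults to
#'   the per-row argmax).
#' @export
write_hhm <- function(freq, path, sequence = NULL) {
  freq <- as.matrix(freq)
  L <- nrow(freq)
  if (is.null(sequence)) sequence <- AA20[apply(freq, 1, which.max)]
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1]]
  lines <- c("HHsearch 1.5", "NAME  synthetic profile",
             sprintf("LENG  %d match states", L), "",
             paste(c("HMM", AA20), collapse = "\t"),
             paste(c("", "M->M", "M->I", "M->D", "I->M", "I->I",
                     "D->M", "D->D"), collapse = "\t"),
             paste(c("", "0", "*", "*", "*", "*", "*", "*"),
                   collapse = "\t"))
  for (r in seq_len(L)) {
    v <- ifelse(freq[r, ] > 0,
                as.character(round(-1000 * log2(freq[r, ]))), "*")
    lines <- c(lines,
               paste(c(sequence[r], r, v, r), collapse = "\t"),
               paste(c("", "0", "*", "*", "*", "*", "*", "*"),
                     collapse = "\t"),
               "")
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

# Minimum inter-atomic distance between two placed structures.
min_interatomic <- function(a, b) {
  A <- atom_coords(a); B <- atom_coords(b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Planted docking scenario
#'
#' Builds two synthetic C3 trimers, chooses a ground-truth pose in the
#' four T:{C3}{C3} degrees of freedom (random axial rotations; axial
#' translations set to the smallest values leaving a `gap` Angstrom
#' clearance between the components), and registers the fragment-pair
#' geometry realized at that pose as clusters of a toy database. At the
#' planted transform, ghost fragments generated from component A land
#' exactly on component B's surface windows, so the scenario is solvable
#' by construction and evaluating one grid bin away scores strictly lower.
#'
#' @param seed integer seed.
#' @param n_res residues per chain of each trimer.
#' @param gap target clearance between components at the planted pose
#'   (Angstrom).
#' @param n_pairs planted fragment-pair clusters (>= minimum_matched).
#' @param m_members members per planted cluster.
#' @param sigma member coordinate noise; sets the cluster RMSD scale.
#' @return list: `oligA`, `oligB`, `entry`, `db`, `planted` (dof + pair
#'   table), `search` (rotation period and translation window for
#'   docking).
#' @export
make_docking_scenario <- function(seed = 7, n_res = 16, gap = 4,
                                  n_pairs = 4, m_members = 12,
                                  sigma = 0.45) {
  entry <- symmetry_entry("T")
  oligA <- make_helical_trimer(n_res, radius = 7.5, seed = seed,
                               chains = c("A", "B", "C"))
  oligB <- make_helical_trimer(n_res, radius = 7.5, seed = seed + 1000L,
                               chains = c("D", "E", "F"))
  rots <- with_seed(seed, stats::runif(2, 0, 120))
  # push both components out along their axes until the gap is reached
  d <- 5
  repeat {
    pose <- make_pose(oligA, oligB, entry,
                      c(rot_a = rots[1], trans_a = d,
                        rot_b = rots[2], trans_b = d))
    pl <- place_pose(pose)
    if (min_interatomic(pl$A, pl$B) >= gap) break
    d <- d + 0.25
    if (d > 100) stop("could not separate components")
  }
  planted_dof <- c(rot_a = rots[1], trans_a = d, rot_b = rots[2],
                   trans_b = d)
  # typed windows on each isolated component (typing is frame-invariant)
  type_rep <- ideal_helix_window()
  db0 <- fragment_db(list(H = type_rep), list(), typing_threshold = 0.75)
  fragsA <- surface_fragments(oligA, db0)
  fragsB <- surface_fragments(oligB, db0)
  if (!length(fragsA) || !length(fragsB)) stop("scenario has no surface windows")
  tfs <- pose_transforms(pose)
  cA <- transform_points(stack_centers(fragsA), tfs$A)
  cB <- transform_points(stack_centers(fragsB), tfs$B)
  d2 <- outer(rowSums(cA^2), rowSums(cB^2), "+") - 2 * cA %*% t(cB)
  ord <- order(d2)
  used_a <- used_b <- integer(0)
  picks <- list()
  for (o in ord) {
    ai <- (o - 1L) %% nrow(cA) + 1L
    bi <- (o - 1L) %/% nrow(cA) + 1L
    if (ai %in% used_a || bi %in% used_b) next
    picks[[length(picks) + 1L]] <- c(ai, bi)
    used_a <- c(used_a, ai); used_b <- c(used_b, bi)
    if (length(picks) >= n_pairs) break
  }
  if (length(picks) < n_pairs) stop("not enough disjoint window pairs")
  clusters <- list()
  pair_tab <- list()
  for (k in seq_along(picks)) {
    fa <- fragsA[[picks[[k]][1]]]
    fb <- fragsB[[picks[[k]][2]]]
    # canonical cluster frame: mapped fragment superposed on the type rep
    a_bb <- transform_points(fa$bb, tfs$A)
    a_cb <- transform_points(fa$cb, tfs$A)
    b_bb <- transform_points(fb$bb, tfs$B)
    b_cb <- transform_points(fb$cb, tfs$B)
    can <- kabsch_superpose(a_bb, type_rep)$transform
    rep_pair <- fragment_pair(
      make_fragment(transform_points(a_bb, can), rep("A", 5),
                    cb = transform_points(a_cb, can)),
      make_fragment(transform_points(b_bb, can), rep("A", 5),
                    cb = transform_points(b_cb, can)))
    probs <- with_seed(seed + 100L + k, {
      pr <- matrix(0.02, 2L * FRAG_LEN, length(AA20),
                   dimnames = list(NULL, AA20))
      for (p in seq_len(2L * FRAG_LEN)) {
        dom <- sample(length(AA20), 1)
        pr[p, dom] <- pr[p, dom] + 1
        pr[p, ] <- pr[p, ] / sum(pr[p, ])
      }
      pr
    })
    members <- with_seed(seed + 200L + k, {
      lapply(seq_len(m_members), function(j) {
        noise <- if (j == 1L) matrix(0, 15, 3)
                 else matrix(stats::rnorm(45, 0, sigma), 15, 3)
        aa <- c(draw_seq(probs[1:5, , drop = FALSE]),
                draw_seq(probs[6:10, , drop = FALSE]))
        fragment_pair(
          make_fragment(rep_pair$f1$bb, aa[1:5], cb = rep_pair$f1$cb),
          make_fragment(rep_pair$f2$bb + noise, aa[6:10],
                        cb = rep_pair$f2$cb + noise[seq(2, 15, by = 3), ]))
      })
    })
    cl <- cluster_fragment_pairs(members, rmsd_threshold = 10,
                                 type_pair = c("H", "H"))
    if (length(cl) != 1L) stop("planted members split into several clusters")
    cl[[1]]$id <- sprintf("H_H_%d", k)
    clusters[[k]] <- cl[[1]]
    pair_tab[[k]] <- data.frame(
      cluster = cl[[1]]$id, chain_a = fa$chain, resi_a = fa$resi,
      chain_b = fb$chain, resi_b = fb$resi, stringsAsFactors = FALSE)
  }
  db <- fragment_db(list(H = type_rep), clusters, typing_threshold = 0.75)
  list(oligA = oligA, oligB = oligB, entry = entry, db = db,
       planted = list(dof = planted_dof, pairs = do.call(rbind, pair_tab)),
       search = list(rot_range = c(0, 120),
                     trans_range = c(d - 1.5, d + 1.5)))
}
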