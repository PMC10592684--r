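# Shared test helpers: tiny structures, toy clusters and random transforms.

random_rotation <- function() {
  axis <- stats::rnorm(3)
  rotation_about_axis(axis, stats::runif(1, 0, 360))
}

random_transform <- function(trans_scale = 10) {
  rigid_transform(random_rotation(), stats::rnorm(3, 0, trans_scale))
}

# A minimal Structure from a coordinate matrix: one atom per residue.
point_structure <- function(xyz, name = "CA", resn = "ALA", chain = "A",
                            element = NULL) {
  n <- nrow(xyz)
  atoms <- data.frame(name = rep_len(name, n), resn = rep_len(resn, n),
                      chain = rep_len(chain, n), resi = seq_len(n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  if (!is.null(element)) atoms$element <- rep_len(element, n)
  new_structure(atoms)
}

# A toy fragment pair with controllable side-chain contact geometry:
# sc_counts/contacts give, per position of the mapped fragment, the number
# of side-chain atoms and how many of them touch the paired fragment.
toy_pair <- function(sc_counts = rep(2L, 5), contacts = rep(1L, 5),
                     seq1 = rep("L", 5), seq2 = rep("A", 5), offset = 5) {
  bb1 <- cageforge:::ideal_helix_window()
  bb2 <- bb1
  bb2[, 1] <- bb2[, 1] + offset
  sc1 <- lapply(seq_len(5), function(p) {
    k <- sc_counts[p]
    if (k == 0L) return(matrix(numeric(0), 0, 3))
    base <- bb1[(p - 1L) * 3L + 2L, ]  # CA
    out <- matrix(rep(base, k), k, 3, byrow = TRUE)
    nc <- contacts[p]
    # contacting atoms sit within 4.5 A of the paired fragment,
    # non-contacting atoms are pushed far away
    for (j in seq_len(k)) {
      if (j <= nc) {
        out[j, 1] <- bb2[(p - 1L) * 3L + 2L, 1] - 3
        out[j, 2:3] <- bb2[(p - 1L) * 3L + 2L, 2:3]
      } else {
        out[j, ] <- base + c(-50, 10 * j, 0)
      }
    }
    out
  })
  f1 <- make_fragment(bb1, seq1, sc = sc1)
  f2 <- make_fragment(bb2, seq2,
                      sc = replicate(5, matrix(numeric(0), 0, 3),
                                     simplify = FALSE))
  fragment_pair(f1, f2)
}

# Independent brute-force evaluation of the interaction weight (the
# quadruple loop written straight from its definition).
bruteforce_t <- function(members, contact_dist = 4.5) {
  M <- length(members)
  t_out <- numeric(10)
  for (pos in 1:10) {
    side <- if (pos <= 5) 1 else 2
    p <- if (pos <= 5) pos else pos - 5L
    total <- 0
    for (m in members) {
      f <- if (side == 1) m$f1 else m$f2
      opp <- if (side == 1) m$f2 else m$f1
      opp_atoms <- rbind(opp$bb, do.call(rbind, opp$sc))
      sc <- f$sc[[p]]
      if (!nrow(sc)) next
      n_contact <- 0
      for (ai in seq_len(nrow(sc))) {
        touched <- FALSE
        for (bi in seq_len(nrow(opp_atoms))) {
          if (sqrt(sum((sc[ai, ] - opp_atoms[bi, ])^2)) < contact_dist) {
            touched <- TRUE
            break
          }
        }
        if (touched) n_contact <- n_contact + 1
      }
      total <- total + n_contact / nrow(sc)
    }
    t_out[pos] <- total / M
  }
  t_out
}

# Toy cluster list with planted frequency rows and weights, for profile
# arithmetic tests. `t_rows` is a 10-vector applied to every cluster.
toy_db <- function(n_clusters = 2, t_rows = rep(1, 10), rmsd_cluster = 0.5,
                   freq_builder = NULL) {
  rep_bb <- cageforge:::ideal_helix_window()
  clusters <- lapply(seq_len(n_clusters), function(k) {
    freq <- if (is.null(freq_builder)) {
      f <- matrix(0, 10, 20, dimnames = list(NULL, cageforge:::AA20))
      f[, k] <- 1
      f
    } else freq_builder(k)
    rp <- fragment_pair(make_fragment(rep_bb), make_fragment(rep_bb + 5))
    list(id = sprintf("H_H_%d", k), type_pair = c("H", "H"), rep = rp,
         M = 1L, rmsd_cluster = rmsd_cluster, freq = freq, t = t_rows)
  })
  fragment_db(list(H = rep_bb), clusters)
}

# One cached docking scenario + dock run shared by the docking tests
# (building it is the expensive part of the suite).
scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(scenario_cache[[key]])) {
    scenario_cache[[key]] <- make_docking_scenario(seed = seed)
  }
  scenario_cache[[key]]
}
cached_dock <- function(seed = 7) {
  key <- paste0("d", seed)
  if (is.null(scenario_cache[[key]])) {
    scen <- cached_scenario(seed)
    scenario_cache[[key]] <- dock(
      scen$oligA, scen$oligB, scen$db, scen$entry,
      dock_params(rot_step = 4, trans_step = 0.5,
                  trans_range = scen$search$trans_range))
  }
  scenario_cache[[key]]
}

# Smallest angular difference on the 120-degree rotation period.
rot_delta <- function(a, b) {
  d <- (a - b) %% 120
  pmin(d, 120 - d)
}
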