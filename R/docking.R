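# Rigid-body fragment-based docking in the T:{C3}{C3} architecture:
# DOF enumeration, coarse overlap search, transform-hash clustering and
# local grid optimization.

#' Default docking parameters
#'
#' Mirrors the published run settings: minimum 3 matched fragment
#' observations, match value 0.5, initial z-value 1, optional
#' continuous-ghost and termini-trimming constraints. Coarse grid defaults
#' are 3 degrees / 1 Angstrom.
#'
#' @param ... overrides for any default.
#' @return Named list of parameters.
#' @export
dock_params <- function(...) {
  p <- list(minimum_matched = 3L, match_value = 0.5, initial_z = 1,
            match_threshold = 1, trim_termini = FALSE,
            continuous_ghosts = FALSE, exposure_min = 0.1,
            rot_step = 3, trans_step = 1,
            rot_range = c(0, 120), trans_range = NULL,
            improvement_stop = 0.05,
            min_step = c(rot = 0.5, trans = 0.125),
            max_optimize = 5L, sasa_points = 120)
  over <- list(...)
  p[names(over)] <- over
  p
}

# Per-component placement transform: rotate the component about its own
# axis (built about z) by rot_deg, align z onto the assigned axis, then
# translate along the axis by trans.
component_transform <- function(axis, rot_deg, trans) {
  A <- align_z_to(axis)
  rigid_transform(A %*% rot_z(rot_deg), trans * axis)
}

#' Enumerate the docking degree-of-freedom grid
#'
#' Four DOF in T:{C3}{C3}: rotation about and translation along each
#' component's own 3-fold axis. Rotations are periodic, so the range
#' endpoint is excluded; translation endpoints are inclusive. Zero-width
#' ranges give a single sample.
#'
#' @param entry `SymmetryEntry` (two-component).
#' @param rot_step,trans_step grid steps (degrees, Angstrom; > 0).
#' @param rot_range,trans_range length-2 ranges, or a list of two ranges
#'   (one per component).
#' @return data frame with columns rot_a, trans_a, rot_b, trans_b in a
#'   deterministic order.
#' @export
enumerate_dof <- function(entry, rot_step, trans_step,
                          rot_range = c(0, 120), trans_range = c(0, 0)) {
  stopifnot(rot_step > 0, trans_step > 0)
  as_two <- function(r) if (is.list(r)) r else list(r, r)
  rr <- as_two(rot_range); tr <- as_two(trans_range)
  rot_seq <- function(r) {
    if (diff(r) == 0) return(r[1])
    n <- floor((r[2] - r[1]) / rot_step + 1e-9)
    r[1] + rot_step * seq.int(0L, max(n - 1L, 0L))
  }
  trans_seq <- function(r) {
    if (diff(r) == 0) return(r[1])
    seq(r[1], r[2], by = trans_step)
  }
  g <- expand.grid(trans_b = trans_seq(tr[[2]]), trans_a = trans_seq(tr[[1]]),
                   rot_b = rot_seq(rr[[2]]), rot_a = rot_seq(rr[[1]]),
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("rot_a", "trans_a", "rot_b", "trans_b")]
}

#' Construct a pose
#'
#' @param oligA,oligB component Structures (C3 oligomers built about z).
#' @param entry two-component `SymmetryEntry`.
#' @param dof named numeric: rot_a, trans_a, rot_b, trans_b (degrees and
#'   Angstrom along each component's own axis).
#' @param observations optional observation table.
#' @return Object of class `cage_pose`.
#' @export
make_pose <- function(oligA, oligB, entry, dof, observations = NULL) {
  dof <- stats::setNames(as.numeric(dof[c("rot_a", "trans_a",
                                          "rot_b", "trans_b")]),
                         c("rot_a", "trans_a", "rot_b", "trans_b"))
  structure(list(oligA = oligA, oligB = oligB, entry = entry, dof = dof,
                 observations = observations, metrics = NULL),
            class = "cage_pose")
}

#' @export
print.cage_pose <- function(x, ...) {
  ns <- nanohedra_score(x$observations)
  cat(sprintf(
    "cage_pose: rot (%.2f, %.2f) deg, trans (%.2f, %.2f) A, %d obs, score %.3f\n",
    x$dof["rot_a"], x$dof["rot_b"], x$dof["trans_a"], x$dof["trans_b"],
    if (is.null(x$observations)) 0L else nrow(x$observations),
    ns$normalized))
  invisible(x)
}

#' Per-component placement transforms of a pose
#' @param pose `cage_pose`.
#' @return list of `rigid_transform` (A and B).
#' @export
pose_transforms <- function(pose) {
  list(A = component_transform(pose$entry$axes$A,
                               pose$dof["rot_a"], pose$dof["trans_a"]),
       B = component_transform(pose$entry$axes$B,
                               pose$dof["rot_b"], pose$dof["trans_b"]))
}

#' Placed component structures of a pose
#' @param pose `cage_pose`.
#' @param relabel_b rename B chains to avoid collisions (default TRUE).
#' @return list of Structures `A` and `B` in the assembly frame.
#' @export
place_pose <- function(pose, relabel_b = TRUE) {
  tf <- pose_transforms(pose)
  A <- transform_structure(pose$oligA, tf$A)
  B <- transform_structure(pose$oligB, tf$B)
  A$entities[] <- "A"
  B$entities[] <- "B"
  if (relabel_b) {
    chA <- unique(A$atoms$chain)
    chB <- unique(B$atoms$chain)
    if (length(intersect(chA, chB))) {
      pool <- setdiff(CHAIN_POOL, chA)
      map <- stats::setNames(pool[seq_along(chB)], chB)
      B$atoms$chain <- map[B$atoms$chain]
      B$entities <- stats::setNames(rep("B", length(chB)), unname(map))
    }
  }
  list(A = A, B = B)
}

#' Expand a pose to the full tetrahedral assembly
#'
#' The asymmetric unit of the cage is one chain per entity: each trimer's
#' own 3-fold is a subgroup of the tetrahedral group (its axis lies on a
#' body diagonal), so applying the 12 group rotations to one A chain and
#' one B chain yields the complete A12-B12 assembly (24 chains) without
#' duplicates.
#'
#' @param pose `cage_pose`.
#' @return Structure of the full 24-chain assembly.
#' @export
expand_pose <- function(pose) {
  pl <- place_pose(pose)
  asu <- combine_structures(
    structure_subset(pl$A, pl$A$atoms$chain == pl$A$atoms$chain[1]),
    structure_subset(pl$B, pl$B$atoms$chain == pl$B$atoms$chain[1]))
  expand_point_group(asu, pose$entry)
}

# Stack fragment/ghost backbones into one matrix for fast transforms.
stack_bb <- function(items) {
  if (!length(items)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(items, `[[`, "bb"))
}

# Matrix of stacked centers (mean backbone coordinate per item).
stack_centers <- function(items) {
  if (!length(items)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(items, function(x) colMeans(x$bb)))
}

# Evaluate one DOF sample: returns the observation table (rmsd-gated only).
eval_dof <- function(dof, ctx) {
  tfa <- component_transform(ctx$axisA, dof[["rot_a"]], dof[["trans_a"]])
  tfb <- component_transform(ctx$axisB, dof[["rot_b"]], dof[["trans_b"]])
  Gc <- transform_points(ctx$ghost_centers, tfa)
  Fc <- transform_points(ctx$frag_centers, tfb)
  d2 <- outer(rowSums(Gc^2), rowSums(Fc^2), "+") - 2 * Gc %*% t(Fc)
  cand <- which(d2 <= (ctx$match_threshold + 0.5)^2, arr.ind = TRUE)
  if (!nrow(cand)) return(NULL)
  cand <- cand[ctx$type_ok[cand], , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  Gbb <- transform_points(ctx$ghost_bb, tfa)
  Fbb <- transform_points(ctx$frag_bb, tfb)
  rmsd <- vapply(seq_len(nrow(cand)), function(k) {
    gi <- cand[k, 1]; fi <- cand[k, 2]
    coord_rmsd(Gbb[(gi - 1L) * 15L + 1:15, , drop = FALSE],
               Fbb[(fi - 1L) * 15L + 1:15, , drop = FALSE])
  }, numeric(1))
  ok <- rmsd <= ctx$gate[cand[, 1]]
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]
  rmsd <- rmsd[ok]
  data.frame(ghost = cand[, 1], frag = cand[, 2], rmsd = rmsd)
}

obs_table <- function(hits, ctx) {
  if (is.null(hits) || !nrow(hits)) {
    return(find_observations(list(), list(), NULL))
  }
  g <- ctx$ghosts[hits$ghost]
  f <- ctx$frags[hits$frag]
  data.frame(
    chain_a = vapply(g, `[[`, "", "source_chain"),
    resi_a = vapply(g, `[[`, 0L, "source_resi"),
    chain_b = vapply(f, `[[`, "", "chain"),
    resi_b = vapply(f, function(x) as.integer(x$resi), 0L),
    cluster = vapply(g, `[[`, "", "cluster"),
    rmsd = hits$rmsd,
    m = match_score(hits$rmsd, ctx$cluster_rmsd[vapply(g, `[[`, "", "cluster")]),
    central = TRUE, stringsAsFactors = FALSE)
}

# Precompute the docking context: typed fragments, ghosts, stacked
# coordinate blocks and per-ghost rmsd gates.
dock_context <- function(oligA, oligB, db, entry, params) {
  fragsA <- surface_fragments(oligA, db, exposure_min = params$exposure_min,
                              trim_termini = params$trim_termini,
                              n_points = params$sasa_points)
  fragsB <- surface_fragments(oligB, db, exposure_min = params$exposure_min,
                              trim_termini = params$trim_termini,
                              n_points = params$sasa_points)
  if (!length(fragsA) || !length(fragsB)) {
    warning("a component has no typeable surface fragments")
    return(NULL)
  }
  ghosts <- generate_ghosts(fragsA, db, oligA)
  if (params$continuous_ghosts) {
    ghosts <- continuous_ghost_filter(ghosts, params$match_threshold)
  }
  if (!length(ghosts)) {
    warning("no ghost fragments survive the clash/continuity checks")
    return(NULL)
  }
  cluster_rmsd <- vapply(db$clusters, function(cl) {
    max(cl$rmsd_cluster, RMSD_CLUSTER_FLOOR)
  }, numeric(1))
  gate <- pmin(params$match_threshold,
               params$initial_z *
                 cluster_rmsd[vapply(ghosts, `[[`, "", "cluster")])
  gtype <- vapply(ghosts, `[[`, "", "target_type")
  ftype <- vapply(fragsB, `[[`, "", "type")
  list(axisA = entry$axes$A, axisB = entry$axes$B,
       ghosts = ghosts, frags = fragsB, fragsA = fragsA,
       ghost_bb = stack_bb(ghosts), frag_bb = stack_bb(fragsB),
       ghost_centers = stack_centers(ghosts),
       frag_centers = stack_centers(fragsB),
       type_ok = outer(gtype, ftype, "=="),
       gate = unname(gate), cluster_rmsd = cluster_rmsd,
       match_threshold = params$match_threshold)
}

#' Fragment-based rigid-body docking of two C3 trimers
#'
#' Enumerates the four T:{C3}{C3} degrees of freedom on a grid, keeps
#' samples where at least `minimum_matched` ghost-fragment overlaps pass
#' the initial-z gate, clusters the candidates by their 6-D transform
#' hash, locally grid-optimizes the cluster representatives against the
#' Nanohedra score (the total: optimizing the per-residue mean instead
#' would reward shedding observations), and returns poses whose final
#' observation sets hold `minimum_matched` observations with match score
#' at least `match_value`, ranked by score.
#'
#' @param oligA,oligB C3 trimer Structures built about the z axis.
#' @param db `fragment_db`.
#' @param entry `SymmetryEntry` (default the tetrahedral two-trimer
#'   architecture).
#' @param params list from [dock_params()]. `trans_range` must be given
#'   (the contact window along each component axis).
#' @return list of `cage_pose` objects, best first.
#' @export
dock <- function(oligA, oligB, db, entry = symmetry_entry("T"),
                 params = dock_params()) {
  if (is.null(params$trans_range)) {
    stop("params$trans_range is required (translation window, Angstrom)")
  }
  ctx <- dock_context(oligA, oligB, db, entry, params)
  if (is.null(ctx)) return(list())
  grid <- enumerate_dof(entry, params$rot_step, params$trans_step,
                        params$rot_range, params$trans_range)
  cand <- vector("list", 64L)
  ncand <- 0L
  for (i in seq_len(nrow(grid))) {
    dof <- as.numeric(grid[i, ])
    names(dof) <- names(grid)
    hits <- eval_dof(dof, ctx)
    if (is.null(hits) || nrow(hits) < params$minimum_matched) next
    obs <- obs_table(hits, ctx)
    sc <- nanohedra_score(obs)
    ncand <- ncand + 1L
    if (ncand > length(cand)) cand <- c(cand, vector("list", length(cand)))
    cand[[ncand]] <- list(dof = dof, n = nrow(hits),
                          score = sc$total, obs = obs)
  }
  if (!ncand) return(list())
  cand <- cand[seq_len(ncand)]
  poses <- lapply(seq_along(cand), function(i) {
    p <- make_pose(oligA, oligB, entry, cand[[i]]$dof, cand[[i]]$obs)
    p$id <- i
    p$score <- cand[[i]]$score
    p
  })
  clusters <- cluster_poses(poses, translation_bin = params$trans_step,
                            angle_bin = params$rot_step)
  reps <- lapply(clusters, `[[`, "representative")
  ord <- order(-vapply(reps, `[[`, 0, "score"),
               vapply(reps, `[[`, 0L, "id"))
  reps <- reps[ord][seq_len(min(length(ord), params$max_optimize))]
  out <- lapply(reps, function(p) {
    optimize_pose(p, ctx, step = c(rot = params$rot_step,
                                   trans = params$trans_step),
                  improvement_stop = params$improvement_stop,
                  min_step = params$min_step)
  })
  keep <- vapply(out, function(p) {
    sum(p$observations$m >= params$match_value) >= params$minimum_matched
  }, logical(1))
  out <- out[keep]
  out[order(-vapply(out, `[[`, 0, "score"))]
}

#' Cluster poses by 6-D transform hash
#'
#' Groups poses whose relative transforms (B frame into A frame) share a
#' transform-hash key. The cluster representative is the member with the
#' highest Nanohedra score (ties: lowest pose id).
#'
#' @param poses list of `cage_pose` (sharing one `SymmetryEntry`).
#' @param translation_bin,angle_bin hash bin widths.
#' @return list of clusters: key, members (pose list), representative.
#' @export
cluster_poses <- function(poses, translation_bin = 1, angle_bin = 3) {
  if (!length(poses)) return(list())
  keys <- vapply(poses, function(p) {
    tf <- pose_transforms(p)
    rel <- compose_transforms(invert_transform(tf$B), tf$A)
    paste(transform_hash(rel, translation_bin, angle_bin), collapse = ",")
  }, "")
  out <- list()
  for (k in unique(keys)) {
    members <- poses[keys == k]
    score <- vapply(members, function(p) {
      if (!is.null(p$score)) p$score
      else nanohedra_score(p$observations)$total
    }, numeric(1))
    id <- vapply(members, function(p) {
      if (is.null(p$id)) NA_integer_ else as.integer(p$id)
    }, 0L)
    best <- order(-score, id)[1]
    out[[length(out) + 1L]] <- list(key = k, members = members,
                                    representative = members[[best]])
  }
  out
}

#' Local grid optimization of a pose
#'
#' Iterative 3^4 neighbourhood search in the four DOF. Each round moves to
#' the best neighbour; when the relative score improvement of a round
#' falls below `improvement_stop` the grid step is halved, and the search
#' stops once every step drops below `min_step` (the resolution of a
#' unique transformation). The returned score never decreases and the
#' per-round trace is attached as the `trace` field.
#'
#' @param pose `cage_pose`.
#' @param ctx docking context (internal) or a list
#'   `(oligA, oligB, db, params)` from which one is built.
#' @param step initial named steps `c(rot=, trans=)`.
#' @param improvement_stop relative improvement threshold (default 0.05).
#' @param min_step named minimum steps `c(rot=, trans=)`.
#' @return Optimized `cage_pose` with fields `score` and `trace`.
#' @export
optimize_pose <- function(pose, ctx, step = c(rot = 3, trans = 1),
                          improvement_stop = 0.05,
                          min_step = c(rot = 0.5, trans = 0.125)) {
  if (!is.null(ctx$db)) {
    params <- if (!is.null(ctx$params)) ctx$params else dock_params()
    ctx <- dock_context(pose$oligA, pose$oligB, ctx$db, pose$entry, params)
  }
  score_of <- function(dof) {
    obs <- obs_table(eval_dof(dof, ctx), ctx)
    list(score = nanohedra_score(obs)$total, obs = obs)
  }
  cur <- pose$dof
  cur_eval <- score_of(cur)
  trace <- cur_eval$score
  rot_step <- step[["rot"]]; trans_step <- step[["trans"]]
  repeat {
    deltas <- expand.grid(da = c(-1, 0, 1) * rot_step,
                          ta = c(-1, 0, 1) * trans_step,
                          db_ = c(-1, 0, 1) * rot_step,
                          tb = c(-1, 0, 1) * trans_step)
    best <- cur_eval; best_dof <- cur
    for (r in seq_len(nrow(deltas))) {
      d <- deltas[r, ]
      if (all(d == 0)) next
      dof <- cur + c(rot_a = d$da, trans_a = d$ta,
                     rot_b = d$db_, trans_b = d$tb)
      ev <- score_of(dof)
      if (ev$score > best$score) {
        best <- ev
        best_dof <- dof
      }
    }
    improvement <- if (cur_eval$score > 0) {
      (best$score - cur_eval$score) / cur_eval$score
    } else if (best$score > 0) Inf else 0
    if (best$score > cur_eval$score) {
      cur <- best_dof
      cur_eval <- best
    }
    trace <- c(trace, cur_eval$score)
    if (improvement < improvement_stop) {
      rot_step <- rot_step / 2
      trans_step <- trans_step / 2
    }
    if (rot_step < min_step[["rot"]] && trans_step < min_step[["trans"]]) {
      break
    }
  }
  out <- make_pose(pose$oligA, pose$oligB, pose$entry, cur, cur_eval$obs)
  out$id <- pose$id
  out$score <- cur_eval$score
  out$trace <- trace
  out
}

#' Filter poses on interface size and secondary-structure diversity
#'
#' @param poses list of `cage_pose` with observations.
#' @param min_interface_residues minimum count of distinct fragment
#'   residues implicated across both components (NULL to skip).
#' @param min_distinct_ss_elements minimum number of distinct secondary
#'   structure elements carrying fragment residues, summed over components
#'   (NULL to skip).
#' @param per_component_ss_minimum minimum distinct SS elements per
#'   component (NULL to skip).
#' @return Surviving pose list.
#' @export
filter_poses <- function(poses, min_interface_residues = NULL,
                         min_distinct_ss_elements = NULL,
                         per_component_ss_minimum = NULL) {
  keep <- vapply(poses, function(p) {
    obs <- p$observations
    if (is.null(obs) || !nrow(obs)) return(FALSE)
    n_res <- length(unique(c(paste("a", obs$chain_a, obs$resi_a),
                             paste("b", obs$chain_b, obs$resi_b))))
    if (!is.null(min_interface_residues) &&
        n_res < min_interface_residues) return(FALSE)
    if (is.null(min_distinct_ss_elements) &&
        is.null(per_component_ss_minimum)) return(TRUE)
    nA <- count_fragment_ss_elements(p$oligA, obs$chain_a, obs$resi_a)
    nB <- count_fragment_ss_elements(p$oligB, obs$chain_b, obs$resi_b)
    if (!is.null(min_distinct_ss_elements) &&
        nA + nB < min_distinct_ss_elements) return(FALSE)
    if (!is.null(per_component_ss_minimum) &&
        min(nA, nB) < per_component_ss_minimum) return(FALSE)
    TRUE
  }, logical(1))
  poses[keep]
}

# Distinct secondary-structure elements containing fragment residues:
# maximal runs of (expanded +/-2) fragment residues within one SS segment.
count_fragment_ss_elements <- function(olig, chains, resis) {
  ss <- assign_secondary_structure(olig)
  # segment id: run index of equal consecutive SS labels per chain
  seg <- integer(nrow(ss))
  sid <- 0L
  for (i in seq_len(nrow(ss))) {
    if (i == 1L || ss$chain[i] != ss$chain[i - 1L] ||
        ss$ss[i] != ss$ss[i - 1L]) sid <- sid + 1L
    seg[i] <- sid
  }
  cov <- unique(data.frame(
    chain = rep(chains, each = 5L),
    resi = as.vector(vapply(resis, function(r) r + (-2L:2L), integer(5)))))
  m <- match(paste(cov$chain, cov$resi), paste(ss$chain, ss$resi))
  cov <- cov[!is.na(m), , drop = FALSE]
  segs <- seg[m[!is.na(m)]]
  ord <- order(cov$chain, cov$resi)
  cov <- cov[ord, , drop = FALSE]
  segs <- segs[ord]
  if (!length(segs)) return(0L)
  runs <- 1L
  for (i in seq_along(segs)[-1]) {
    new_run <- segs[i] != segs[i - 1L] ||
      cov$chain[i] != cov$chain[i - 1L] ||
      cov$resi[i] != cov$resi[i - 1L] + 1L
    if (new_run) runs <- runs + 1L
  }
  runs
}
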