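# DOF enumeration, docking with planted-transform recovery, pose
# clustering, grid optimization and pose filtering.

test_that("DOF grid enumeration matches the combinatorial count", {
  entry <- symmetry_entry("T")
  g <- enumerate_dof(entry, rot_step = 60, trans_step = 5,
                     rot_range = c(0, 120), trans_range = c(0, 10))
  # rotations periodic (endpoint excluded): 2 each; translations: 3 each
  expect_equal(nrow(g), 2 * 2 * 3 * 3)
  expect_named(g, c("rot_a", "trans_a", "rot_b", "trans_b"))

  single <- enumerate_dof(entry, 10, 1, rot_range = c(30, 30),
                          trans_range = c(5, 5))
  expect_equal(nrow(single), 1L)
  expect_equal(as.numeric(single[1, ]), c(30, 5, 30, 5))

  # membership equals brute-force nested loops
  g2 <- enumerate_dof(entry, 40, 2, c(0, 120), c(4, 8))
  oracle <- expand.grid(tb = c(4, 6, 8), ta = c(4, 6, 8),
                        rb = c(0, 40, 80), ra = c(0, 40, 80))
  expect_setequal(paste(g2$rot_a, g2$trans_a, g2$rot_b, g2$trans_b),
                  paste(oracle$ra, oracle$ta, oracle$rb, oracle$tb))
  expect_error(enumerate_dof(entry, 0, 1), "rot_step > 0")
})

test_that("docking recovers the planted transform", {
  scen <- cached_scenario(7)
  poses <- cached_dock(7)
  expect_gt(length(poses), 0L)
  top <- poses[[1]]
  # within one fine-grid bin of the optimizer (2 x min_step per DOF)
  expect_lt(rot_delta(top$dof["rot_a"], scen$planted$dof["rot_a"]), 1)
  expect_lt(rot_delta(top$dof["rot_b"], scen$planted$dof["rot_b"]), 1)
  expect_lt(abs(top$dof["trans_a"] - scen$planted$dof["trans_a"]), 0.25)
  expect_lt(abs(top$dof["trans_b"] - scen$planted$dof["trans_b"]), 0.25)
  # the planted pairs are all recovered with high match scores
  expect_gte(sum(top$observations$m >= 0.5), 3)
  expect_setequal(top$observations$cluster, scen$planted$pairs$cluster)
})

test_that("docked poses expand to an exact 24-chain tetrahedral assembly", {
  top <- cached_dock(7)[[1]]
  cage <- expand_pose(top)
  expect_equal(length(unique(cage$atoms$chain)), 24L)
  for (ent in c("A", "B")) {
    chains <- names(cage$entities)[cage$entities == ent]
    expect_length(chains, 12L)
    ref <- atom_coords(structure_subset(cage, cage$atoms$chain == chains[1]))
    for (ch in chains[-1]) {
      X <- atom_coords(structure_subset(cage, cage$atoms$chain == ch))
      expect_lt(kabsch_superpose(X, ref)$rmsd, 1e-6)
    }
  }
})

test_that("raising match_value never increases the pose count", {
  scen <- cached_scenario(7)
  poses_05 <- cached_dock(7)
  poses_09 <- dock(scen$oligA, scen$oligB, scen$db, scen$entry,
                   dock_params(rot_step = 4, trans_step = 0.5,
                               match_value = 0.9,
                               trans_range = scen$search$trans_range))
  expect_lte(length(poses_09), length(poses_05))
})

test_that("unsatisfiable minimum_matched yields an empty result", {
  scen <- cached_scenario(7)
  # more matches demanded than clusters planted
  poses <- dock(scen$oligA, scen$oligB, scen$db, scen$entry,
                dock_params(rot_step = 4, trans_step = 0.5,
                            minimum_matched = 10L,
                            trans_range = scen$search$trans_range))
  expect_length(poses, 0L)

  # component without typeable surface -> empty result with warning
  expect_warning(
    out <- dock(scen$oligA, scen$oligB, scen$db, scen$entry,
                dock_params(trans_range = c(20, 21), exposure_min = 2)),
    "no typeable|no ghost")
  expect_length(out, 0L)
})

test_that("pose clustering agrees with a direct binning oracle", {
  scen <- cached_scenario(7)
  mk <- function(dof) make_pose(scen$oligA, scen$oligB, scen$entry, dof)
  p1 <- mk(c(rot_a = 10, trans_a = 20, rot_b = 40, trans_b = 20))
  p2 <- mk(c(rot_a = 10.4, trans_a = 20.1, rot_b = 40.2, trans_b = 20.1))
  p3 <- mk(c(rot_a = 80, trans_a = 22, rot_b = 100, trans_b = 22))
  cl <- cluster_poses(list(p1, p2, p3), translation_bin = 1, angle_bin = 3)
  sizes <- sort(vapply(cl, function(x) length(x$members), 0L))
  expect_equal(sizes, c(1L, 2L))

  set.seed(71)
  poses <- lapply(1:60, function(i) {
    p <- mk(c(rot_a = stats::runif(1, 0, 120),
              trans_a = stats::runif(1, 19, 23),
              rot_b = stats::runif(1, 0, 120),
              trans_b = stats::runif(1, 19, 23)))
    p$id <- i
    p$score <- stats::runif(1)
    p
  })
  cl <- cluster_poses(poses, translation_bin = 2, angle_bin = 15)
  keys <- vapply(poses, function(p) {
    tf <- pose_transforms(p)
    rel <- compose_transforms(invert_transform(tf$B), tf$A)
    paste(transform_hash(rel, 2, 15), collapse = ",")
  }, "")
  expect_equal(length(cl), length(unique(keys)))
  for (grp in cl) {
    ids <- vapply(grp$members, `[[`, 0L, "id")
    expect_setequal(ids, which(keys == grp$key))
    # representative: highest score, ties by lowest id
    sc <- vapply(grp$members, `[[`, 0, "score")
    expect_equal(grp$representative$id, ids[order(-sc, ids)][1])
  }
})

test_that("grid optimization is monotone and honors its stopping rules", {
  scen <- cached_scenario(7)
  ctx <- cageforge:::dock_context(scen$oligA, scen$oligB, scen$db,
                                  scen$entry, dock_params(trans_range = c(0, 1)))
  planted <- make_pose(scen$oligA, scen$oligB, scen$entry, scen$planted$dof)
  opt <- optimize_pose(planted, ctx, step = c(rot = 2, trans = 0.25))
  # already at the global optimum: transform unchanged, trace monotone
  expect_equal(opt$dof, scen$planted$dof, tolerance = 1e-9)
  expect_true(all(diff(opt$trace) >= 0))

  # offset start converges back within the optimizer's resolution
  off <- scen$planted$dof + c(2, 0.25, -2, -0.25)
  names(off) <- names(scen$planted$dof)
  opt2 <- optimize_pose(make_pose(scen$oligA, scen$oligB, scen$entry, off),
                        ctx, step = c(rot = 2, trans = 0.25),
                        min_step = c(rot = 0.25, trans = 0.05))
  expect_true(all(diff(opt2$trace) >= 0))
  expect_lt(rot_delta(opt2$dof["rot_a"], scen$planted$dof["rot_a"]), 0.5)
  expect_lt(rot_delta(opt2$dof["rot_b"], scen$planted$dof["rot_b"]), 0.5)
  expect_lt(abs(opt2$dof["trans_a"] - scen$planted$dof["trans_a"]), 0.1)
  expect_lt(abs(opt2$dof["trans_b"] - scen$planted$dof["trans_b"]), 0.1)
  expect_gte(opt2$score, nanohedra_score(
    cageforge:::obs_table(cageforge:::eval_dof(off, ctx), ctx))$total)
})

test_that("dock output is invariant to chain order within each oligomer", {
  scen <- cached_scenario(7)
  # feed chains of component A in reversed order
  a <- scen$oligA
  ord <- order(match(a$atoms$chain, c("C", "B", "A")), a$atoms$resi)
  a2 <- new_structure(a$atoms[ord, , drop = FALSE], entities = a$entities)
  poses2 <- dock(a2, scen$oligB, scen$db, scen$entry,
                 dock_params(rot_step = 4, trans_step = 0.5,
                             trans_range = scen$search$trans_range))
  top <- cached_dock(7)[[1]]
  expect_equal(poses2[[1]]$dof, top$dof, tolerance = 1e-9)
  expect_equal(poses2[[1]]$score, top$score, tolerance = 1e-9)
})

test_that("pose filters count fragment residues and SS elements", {
  scen <- cached_scenario(7)
  poses <- cached_dock(7)
  top <- poses[[1]]
  n_res <- length(unique(c(paste("a", top$observations$chain_a,
                                 top$observations$resi_a),
                           paste("b", top$observations$chain_b,
                                 top$observations$resi_b))))
  expect_length(filter_poses(poses[1], min_interface_residues = n_res), 1L)
  expect_length(filter_poses(poses[1],
                             min_interface_residues = n_res + 1), 0L)
  # every fragment sits on a helix of each trimer
  expect_length(filter_poses(poses[1], per_component_ss_minimum = 1), 1L)
  kept <- filter_poses(poses[1], min_distinct_ss_elements = 100)
  expect_length(kept, 0L)

  # hand-counted SS elements on the top pose
  nA <- cageforge:::count_fragment_ss_elements(
    top$oligA, top$observations$chain_a, top$observations$resi_a)
  nB <- cageforge:::count_fragment_ss_elements(
    top$oligB, top$observations$chain_b, top$observations$resi_b)
  expect_length(filter_poses(poses[1],
                             min_distinct_ss_elements = nA + nB), 1L)
  expect_length(filter_poses(poses[1],
                             min_distinct_ss_elements = nA + nB + 1), 0L)
})
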