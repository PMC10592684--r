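# SASA/BSA, interface residue classes, composition similarity, secondary
# structure, hydrogen bonds, HCI, spike ratio and C-beta statistics.

test_that("shrake-rupley matches closed forms and a grid oracle", {
  one <- point_structure(matrix(0, 1, 3))
  expect_equal(shrake_rupley(one), 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.01)
  # doubling the point count changes the total by well under 0.5%
  two <- point_structure(rbind(c(0, 0, 0), c(2.5, 0, 0)))
  a960 <- sum(shrake_rupley(two, n_points = 960))
  a1920 <- sum(shrake_rupley(two, n_points = 1920))
  expect_lt(abs(a960 - a1920) / a1920, 0.005)

  # two-sphere overlap: analytic spherical-cap area
  # accessible sphere radius R = 1.7 + 1.4 = 3.1 for both atoms
  d <- 2.5; R <- 3.1
  h <- R - (d^2) / (2 * d)  # cap height for equal radii
  buried_each <- 2 * pi * R * h
  expect_equal(shrake_rupley(two, n_points = 1920),
               rep(4 * pi * R^2 - buried_each, 2), tolerance = 0.01)

  # independent random-quadrature oracle on an irregular cluster
  set.seed(91)
  xyz <- matrix(stats::rnorm(24, sd = 2), 8, 3)
  got <- shrake_rupley(point_structure(xyz), n_points = 960)
  oracle <- vapply(seq_len(8), function(i) {
    pts <- matrix(stats::rnorm(3 * 4000), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * 3.1
    pts <- sweep(pts, 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(pts))
    for (j in seq_len(8)[-i]) {
      free <- free & rowSums(sweep(pts, 2, xyz[j, ])^2) >= 3.1^2
    }
    4 * pi * 3.1^2 * mean(free)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 0.03)

  # an atom caged by tight neighbours has zero accessible area
  cage <- rbind(c(0, 0, 0),
                2.0 * rbind(diag(3), -diag(3),
                            c(1, 1, 1) / sqrt(3), -c(1, 1, 1) / sqrt(3),
                            c(1, -1, 1) / sqrt(3), c(-1, 1, 1) / sqrt(3),
                            c(1, 1, -1) / sqrt(3), c(-1, -1, 1) / sqrt(3),
                            c(1, -1, -1) / sqrt(3), c(-1, 1, -1) / sqrt(3)))
  expect_equal(shrake_rupley(point_structure(cage))[1], 0)
  expect_warning(shrake_rupley(point_structure(matrix(0, 1, 3),
                                               element = "ZZ")),
                 "unknown element")
})

test_that("interface BSA is the separated-minus-complex difference", {
  near <- point_structure(matrix(c(0, 0, 0), 1, 3), chain = "A")
  partner <- point_structure(matrix(c(2.5, 0, 0), 1, 3), chain = "B")
  bsa <- interface_bsa(list(near, partner))
  R <- 3.1; d <- 2.5
  buried_each <- 2 * pi * R * (R - d / 2)
  expect_equal(bsa$total, 2 * buried_each, tolerance = 0.02)
  expect_equal(bsa$polar + bsa$apolar, bsa$total, tolerance = 1e-9)

  # components 500 A apart bury nothing
  far <- point_structure(matrix(c(500, 0, 0), 1, 3), chain = "B")
  expect_equal(interface_bsa(list(near, far))$total, 0)

  # polarity split on a mixed pair: only the N atom is polar
  n_atom <- point_structure(matrix(0, 1, 3), name = "N", chain = "A")
  bsa2 <- interface_bsa(list(n_atom, partner))
  expect_equal(bsa2$polar + bsa2$apolar, bsa2$total, tolerance = 1e-9)
  expect_gt(bsa2$polar, 0)
  expect_gt(bsa2$apolar, 0)
})

test_that("core/rim/support classification matches rASA thresholding", {
  scen <- cached_scenario(7)
  pose <- make_pose(scen$oligA, scen$oligB, scen$entry,
                    scen$planted$dof - c(0, 1.5, 0, 1.5))
  pl <- place_pose(pose)
  cls <- classify_interface_residues(list(pl$A, pl$B), n_points = 240)
  expect_gt(nrow(cls$interface), 0)
  # cover + disjoint
  expect_equal(sum(cls$counts), nrow(cls$interface))
  # brute-force thresholding oracle
  for (i in seq_len(nrow(cls$interface))) {
    row <- cls$interface[i, ]
    want <- if (row$rasa_complex >= 0.25) "rim"
            else if (row$rasa_monomer >= 0.25) "core"
            else "support"
    expect_identical(row$class, want)
  }
  # composition similarity stays within [0, 1] here
  sim <- composition_similarity(cls$bsa$total, as.list(cls$counts))
  expect_gte(sim, 0); expect_lte(sim, 1)
})

test_that("composition similarity follows the printed linear fits", {
  # measured equal to expected at BSA = 2000 -> exactly 1
  expect_equal(composition_similarity(
    2000, list(core = 20.6, rim = 17.5, support = 17)), 1)
  # all-zero measurements -> 0
  expect_equal(composition_similarity(
    2000, list(core = 0, rim = 0, support = 0)), 0)
  # hand-evaluated value at counts (15, 10, 17)
  hand <- mean(c(1 - abs(20.6 - 15) / 20.6,
                 1 - abs(17.5 - 10) / 17.5,
                 1 - abs(17 - 17) / 17))
  expect_equal(composition_similarity(
    2000, list(core = 15, rim = 10, support = 17)), hand)
  # clamping: gross excess cannot drive the similarity negative
  expect_gte(composition_similarity(
    2000, list(core = 500, rim = 500, support = 500)), 0)
  # tiny interface: negative expected rim count is skipped
  expect_equal(composition_similarity(
    100, list(core = 1.6, rim = 0, support = 5.6)), 1)
  expect_error(composition_similarity(0, list(core = 1, rim = 1,
                                              support = 1)), "positive")
})

test_that("secondary structure separates helix, strand and coil", {
  hel <- cageforge:::build_ideal_helix(10)
  to_structure <- function(coords) {
    rows <- do.call(rbind, lapply(seq_along(coords), function(i) {
      cc <- coords[[i]]
      data.frame(name = c("N", "CA", "C", "O"),
                 resn = "ALA", chain = "A", resi = i,
                 x = c(cc$N[1], cc$CA[1], cc$C[1], cc$O[1]),
                 y = c(cc$N[2], cc$CA[2], cc$C[2], cc$O[2]),
                 z = c(cc$N[3], cc$CA[3], cc$C[3], cc$O[3]),
                 stringsAsFactors = FALSE)
    }))
    new_structure(rows)
  }
  ss_h <- assign_secondary_structure(to_structure(hel))
  expect_true(all(ss_h$ss[2:9] == "H"))
  ext <- cageforge:::build_ideal_helix(10, phi = -120, psi = 120)
  ss_e <- assign_secondary_structure(to_structure(ext))
  expect_true(all(ss_e$ss[2:9] == "E"))

  # an externally supplied assignment overrides verbatim
  override <- data.frame(chain = "A", resi = 1:10,
                         ss = rep(c("E", "C"), 5))
  got <- assign_secondary_structure(to_structure(hel), override = override)
  expect_identical(got$ss, override$ss)

  # stride ASG records parse to the same table
  path <- withr::local_tempfile()
  writeLines(sprintf("ASG  ALA A %4d %4d    %s   Helix", 1:4, 1:4,
                     c("H", "H", "E", "C")), path)
  st <- read_ss_file(path)
  expect_equal(st$resi, 1:4)
  expect_identical(st$ss, c("H", "H", "E", "C"))

  fr <- ss_fractions(ss_h, subset = data.frame(chain = "A", resi = 2:9))
  expect_equal(unname(fr["pct_helix"]), 100)
})

test_that("hydrogen bonds require distance and donor geometry", {
  # ideal N-H...O=C arrangement: previous C behind the N so the amide H
  # points straight at the acceptor 2.9 A away
  donor_res <- data.frame(
    name = c("N", "CA", "C"), resn = "ALA", chain = "A", resi = 2L,
    x = c(0, -0.9, 0.3), y = c(0, 1.2, 2.3), z = 0,
    stringsAsFactors = FALSE)
  prev_c <- data.frame(name = "C", resn = "ALA", chain = "A", resi = 1L,
                       x = -1.2, y = -0.6, z = 0, stringsAsFactors = FALSE)
  acceptor <- data.frame(name = c("O", "C"), resn = "ALA", chain = "B",
                         resi = 5L, x = c(2.8, 3.8), y = c(-0.7, -1.1),
                         z = 0, stringsAsFactors = FALSE)
  s <- suppressWarnings(new_structure(rbind(prev_c, donor_res, acceptor)))
  hb <- hydrogen_bonds(s)
  expect_equal(nrow(hb), 1L)
  expect_lt(hb$dist, 3.5)
  expect_gt(hb$angle, 120)

  # same geometry at 4.5 A -> no bond
  acceptor_far <- acceptor
  acceptor_far$x <- acceptor_far$x + 1.7
  s2 <- suppressWarnings(new_structure(rbind(prev_c, donor_res, acceptor_far)))
  expect_equal(nrow(hydrogen_bonds(s2)), 0L)
})

test_that("buried unsatisfied donors are counted per 1000 A^2 of BSA", {
  # a donor N enclosed by the partner component only in the complex
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  shell <- 2.8 * rbind(diag(3), -diag(3), corners)
  donor <- point_structure(matrix(0, 1, 3), name = "N", resn = "LYS",
                           chain = "A")
  donor$atoms$name <- "NZ"
  partner <- point_structure(shell, chain = "B")
  bu <- buried_unsat_density(list(donor, partner))
  expect_equal(bu$unsat_unbound, 0)
  expect_equal(bu$buried_unsat, 1)
  bsa <- interface_bsa(list(donor, partner), n_points = 240)$total
  expect_equal(bu$density, 1 / (bsa / 1000), tolerance = 1e-9)
})

test_that("hci flags new collapse sites only", {
  poly_l <- strrep("L", 30)
  poly_s <- strrep("S", 30)
  sites <- hci_new_sites(poly_l, poly_s)
  expect_true(all(3:28 %in% sites))
  expect_length(hci_new_sites(poly_l, poly_l), 0L)

  # hand-built 30-mer: windowed density computed independently
  des <- strsplit("SSSSSWLLLFSSSSSSSSSSSSSSSSSSSS", "")[[1]]
  ref <- strsplit("SSSSSWLLSSSSSSSSSSSSSSSSSSSSSS", "")[[1]]
  hand_hci <- function(aa) {
    h <- as.numeric(aa %in% c("F", "M", "I", "L", "Y", "V", "W"))
    vapply(seq_along(h), function(i) {
      w <- max(1, i - 4):min(length(h), i + 4)
      mean(h[w])
    }, numeric(1))
  }
  want <- which(hand_hci(des) > 0.48 & hand_hci(ref) <= 0.48)
  expect_identical(hci_new_sites(des, ref), want)
  expect_error(hci_new_sites("AAA", "AAAA"), "differ")
})

test_that("spike ratio follows the worked distance ratios", {
  expect_equal(spike_ratio(d_a = 3, d_b = 3), 0)
  expect_equal(spike_ratio(d_a = 5, d_b = 10), 0.5)
  expect_equal(spike_ratio(d_a = 8, d_b = 2), 0.75)
  expect_error(spike_ratio(d_a = 0, d_b = 0), "degenerate")

  # pose-derived value matches the direct distance computation and is
  # invariant to which component sits further out
  scen <- cached_scenario(7)
  dof <- scen$planted$dof
  dof["trans_b"] <- 2 * dof["trans_a"]
  pose <- make_pose(scen$oligA, scen$oligB, scen$entry, dof)
  pl <- place_pose(pose)
  ctr <- colMeans(atom_coords(expand_pose(pose)))
  dA <- sqrt(sum((colMeans(atom_coords(pl$A)) - ctr)^2))
  dB <- sqrt(sum((colMeans(atom_coords(pl$B)) - ctr)^2))
  expect_equal(spike_ratio(pose), 1 - min(dA, dB) / max(dA, dB))
  dof2 <- dof
  dof2["trans_a"] <- dof["trans_b"]; dof2["trans_b"] <- dof["trans_a"]
  pose2 <- make_pose(scen$oligA, scen$oligB, scen$entry, dof2)
  expect_equal(spike_ratio(pose2), spike_ratio(pose), tolerance = 1e-6)
})

test_that("c-beta separation percentages use the minimum cross distance", {
  mk_comp <- function(chain, xs) {
    rows <- do.call(rbind, lapply(seq_along(xs), function(i) {
      data.frame(name = c("N", "CA", "C", "CB"), resn = "ALA",
                 chain = chain, resi = i,
                 x = c(xs[i], xs[i], xs[i], xs[i]),
                 y = c(0, 0.5, 1, -1.5), z = c(0, 1, 2, 0),
                 stringsAsFactors = FALSE)
    }))
    new_structure(rows)
  }
  a <- mk_comp("A", c(0, 0))
  close_b <- mk_comp("B", c(5, 5))
  iface <- data.frame(chain = c("A", "A", "B", "B"), resi = c(1, 2, 1, 2),
                      component = c(1, 1, 2, 2))
  expect_equal(cbeta_separation_stats(list(a, close_b), iface), 0)
  far_b <- mk_comp("B", c(9, 9))
  expect_equal(cbeta_separation_stats(list(a, far_b), iface), 100)
})

test_that("pose metric records are complete and internally consistent", {
  top <- cached_dock(7)[[1]]
  met <- suppressWarnings(pose_metrics(top))
  expect_equal(met$bsa_polar + met$bsa_apolar, met$bsa_total,
               tolerance = 1e-9)
  expect_equal(met$pct_helix + met$pct_strand + met$pct_coil, 100,
               tolerance = 1e-9)
  expect_gte(met$nanohedra_normalized, 0)
  expect_lte(met$nanohedra_normalized, 2)
  expect_equal(met$n_observations, nrow(top$observations))
  expect_gte(met$spike_ratio, 0)
  expect_lt(met$spike_ratio, 1)
})
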