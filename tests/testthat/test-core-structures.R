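# Structure model, PDB I/O, symmetry expansion, superposition, LDDT,
# transform hashing and neighbor queries.

test_that("pdb round-trip preserves atoms, names and coordinates", {
  toy <- paste(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500  -1.250   0.125  1.00  0.00           C",
    sep = "\n")
  s <- suppressWarnings(read_pdb(toy))
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$name, c("N", "CA"))
  expect_equal(s$atoms$x, c(1, 2.5))
  expect_equal(s$atoms$element, c("N", "C"))

  tri <- make_helical_trimer(12, seed = 4)
  tri2 <- read_pdb(write_pdb(tri))
  expect_equal(nrow(tri2$atoms), nrow(tri$atoms))
  expect_equal(tri2$atoms$name, tri$atoms$name)
  expect_lt(max(abs(atom_coords(tri2) - atom_coords(tri))), 1e-3)
})

test_that("pdb parser reports format and backbone problems", {
  bad <- "ATOM      1  N   ALA A   1       xx.000   2.000   3.000  1.00  0.00"
  expect_error(read_pdb(bad), "format error.*line 1")
  # missing CA -> flagged-residue warning
  one <- "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N"
  expect_warning(read_pdb(one), "missing backbone")
})

test_that("altloc resolves to the highest-occupancy copy", {
  lines <- paste(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.30  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.70  0.00           N",
    sep = "\n")
  s <- suppressWarnings(read_pdb(lines))
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 9)
})

test_that("point-group expansion produces the expected copies", {
  tri <- make_helical_trimer(12, seed = 1)
  mono <- structure_subset(tri, tri$atoms$chain == "A")
  c3 <- expand_point_group(mono, symmetry_entry("C3"))
  expect_equal(length(unique(c3$atoms$chain)), 3L)
  # copies related by 120-degree rotation about z
  ch <- unique(c3$atoms$chain)
  X1 <- atom_coords(structure_subset(c3, c3$atoms$chain == ch[1]))
  X2 <- atom_coords(structure_subset(c3, c3$atoms$chain == ch[2]))
  expect_lt(max(abs(transform_points(X1, rigid_transform(rot_z(120))) - X2)),
            1e-9)

  # two-chain A-B asymmetric unit under T: 24 chains, 12 per entity
  chA <- structure_subset(tri, tri$atoms$chain == "A")
  triB <- make_helical_trimer(12, seed = 2, chains = c("D", "E", "F"))
  chB <- transform_structure(structure_subset(triB, triB$atoms$chain == "D"),
                             rigid_transform(diag(3), c(25, 0, 0)))
  chB$entities[] <- "E2"
  asu <- combine_structures(chA, chB)
  cage <- expand_point_group(asu, symmetry_entry("T"))
  expect_equal(length(unique(cage$atoms$chain)), 24L)
  expect_equal(unname(table(unname(cage$entities))), c(12L, 12L),
               ignore_attr = TRUE)
  # inverse generator returns each copy onto the asu exactly
  g <- symmetry_entry("T")$generators[[5]]
  moved <- transform_structure(asu, rigid_transform(g))
  back <- transform_structure(moved, invert_transform(rigid_transform(g)))
  expect_lt(max(abs(atom_coords(back) - atom_coords(asu))), 1e-9)

  # identity group leaves coordinates untouched
  id <- expand_point_group(mono, symmetry_entry("C1"))
  expect_identical(unname(atom_coords(id)), unname(atom_coords(mono)))

  # non-orthonormal generator is rejected
  broken <- symmetry_entry("C3")
  broken$generators[[2]] <- matrix(1, 3, 3)
  expect_error(expand_point_group(mono, broken), "orthonormal")
})

test_that("group closure: T generators give a 12-point orbit", {
  entry <- symmetry_entry("T")
  expect_equal(entry$order, 12L)
  pt <- c(1.3, -0.4, 2.9)
  orbit <- t(vapply(entry$generators, function(g) as.numeric(g %*% pt),
                    numeric(3)))
  expect_equal(nrow(unique(round(orbit, 6))), 12L)
})

test_that("kabsch recovers transforms and matches a numeric oracle", {
  set.seed(11)
  X <- matrix(stats::rnorm(60), 20, 3)
  expect_equal(kabsch_superpose(X, X)$rmsd, 0, tolerance = 1e-12)

  tf <- random_transform()
  Y <- transform_points(X, tf)
  fit <- kabsch_superpose(X, Y)
  expect_lt(fit$rmsd, 1e-9)
  roundtrip <- compose_transforms(invert_transform(fit$transform), tf)
  expect_lt(max(abs(roundtrip$R - diag(3))), 1e-9)
  expect_lt(max(abs(roundtrip$t)), 1e-9)

  # generators of the point group superpose exactly
  for (g in symmetry_entry("T")$generators[2:4]) {
    expect_lt(kabsch_superpose(X, transform_points(
      X, rigid_transform(g)))$rmsd, 1e-9)
  }

  # noisy pair: global minimum agrees with direct numeric minimization
  set.seed(12)
  X <- matrix(stats::rnorm(150), 50, 3)
  Y <- transform_points(X, random_transform()) +
    matrix(stats::rnorm(150, 0, 0.5), 50, 3)
  fit <- kabsch_superpose(X, Y)
  obj <- function(par) {
    R <- rot_z(par[1]) %*% rotation_about_axis(c(0, 1, 0), par[2]) %*%
      rot_z(par[3])
    sqrt(mean(rowSums((transform_points(
      X, rigid_transform(R, par[4:6])) - Y)^2)))
  }
  opt <- stats::optim(c(euler_zyz <- cageforge:::euler_zyz(fit$transform$R),
                        fit$transform$t), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$rmsd, opt$value, tolerance = 1e-5)
  expect_lte(fit$rmsd, opt$value + 1e-8)  # kabsch is the global minimum

  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("lddt matches hand enumeration and is superposition-free", {
  set.seed(3)
  ref <- point_structure(matrix(stats::rnorm(15, sd = 3), 5, 3))
  expect_equal(lddt(ref, ref), 1)

  # rigid motion of the model leaves the score at 1
  moved <- transform_structure(ref, random_transform())
  expect_equal(lddt(moved, ref), 1)

  # single atom displaced by 10 A: hand-enumerate preserved fractions
  model <- ref
  model$atoms$x[2] <- model$atoms$x[2] + 10
  R <- atom_coords(ref); M <- atom_coords(model)
  expected <- local({
    fr <- numeric(0)
    for (th in c(0.5, 1, 2, 4)) {
      kept <- tot <- 0
      for (i in 1:4) for (j in (i + 1):5) {
        dr <- sqrt(sum((R[i, ] - R[j, ])^2))
        if (dr > 15) next
        tot <- tot + 1
        dm <- sqrt(sum((M[i, ] - M[j, ])^2))
        if (abs(dm - dr) <= th) kept <- kept + 1
      }
      fr <- c(fr, kept / tot)
    }
    mean(fr)
  })
  expect_equal(lddt(model, ref), expected)

  # randomized coordinates of the same composition score low
  set.seed(4)
  big <- point_structure(matrix(stats::rnorm(90, sd = 10), 30, 3))
  scores <- vapply(1:8, function(i) {
    rnd <- point_structure(matrix(stats::rnorm(90, sd = 10), 30, 3))
    lddt(rnd, big)
  }, numeric(1))
  expect_lt(stats::median(scores), 0.2)

  expect_error(lddt(point_structure(matrix(1:9, 3, 3), chain = "Z"), ref),
               "correspondence")
})

test_that("transform hash bins agree with a direct 6-D binning oracle", {
  id <- rigid_transform()
  expect_identical(transform_hash(id), rep(0L, 6))

  # two transforms inside one bin share a key
  a <- rigid_transform(rot_z(10.1), c(0.2, 0.2, 0.2))
  b <- rigid_transform(rot_z(10.9), c(0.4, 0.1, 0.3))
  expect_identical(transform_hash(a, 1, 3), transform_hash(b, 1, 3))

  set.seed(21)
  for (i in 1:300) {
    tf <- random_transform()
    key <- transform_hash(tf, 1.5, 5)
    ang <- cageforge:::euler_zyz(tf$R)
    oracle <- as.integer(c(floor(tf$t / 1.5), floor(ang / 5)))
    expect_identical(key, oracle)
  }
  # deterministic across calls
  tf <- random_transform()
  expect_identical(transform_hash(tf), transform_hash(tf))
})

test_that("cbeta neighbors use the inclusive cutoff and glycine CA proxy", {
  mk <- function(resn, cbx, withcb = TRUE) {
    atoms <- data.frame(
      name = c("N", "CA", "C", if (withcb) "CB"),
      resn = resn, chain = "A", resi = 1L,
      x = c(0, 0, 0, if (withcb) cbx), y = 0, z = 0,
      stringsAsFactors = FALSE)
    atoms
  }
  a1 <- mk("ALA", 0)
  a2 <- mk("ALA", 7.9); a2$resi <- 2L; a2$chain <- "B"
  s <- new_structure(rbind(a1, a2))
  q <- data.frame(chain = "A", resi = 1L)
  t2 <- data.frame(chain = "B", resi = 2L)
  expect_equal(nrow(cbeta_neighbors(s, q, t2, cutoff = 8)), 1L)

  a2b <- a2; a2b$x[4] <- 8.1
  s2 <- new_structure(rbind(a1, a2b))
  expect_equal(nrow(cbeta_neighbors(s2, q, t2, cutoff = 8)), 0L)

  # glycine: distance measured from CA
  g <- mk("GLY", 0, withcb = FALSE)
  g$x[2] <- 0  # CA at origin
  a3 <- mk("ALA", 7.5); a3$resi <- 2L; a3$chain <- "B"
  a3$x[1:3] <- 20  # backbone far; CB at 7.5 from glycine CA
  s3 <- new_structure(rbind(g, a3))
  hit <- cbeta_neighbors(s3, q, t2, cutoff = 8)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$dist, 7.5)

  expect_equal(nrow(cbeta_neighbors(s3, data.frame(chain = character(),
                                                   resi = integer()),
                                    t2, 8)), 0L)
})
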