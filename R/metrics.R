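# Interface metrics: buried surface area, residue burial classes,
# composition similarity, hydrogen bonds, hydrophobic collapse, spike
# ratio and C-beta separation statistics.

#' Buried surface area of a two-component interface
#'
#' BSA = SASA of the separated components (no repacking) minus SASA of
#' the complex, reported positive. The polar/apolar split sums only atoms
#' of each polarity class (N/O/S polar, carbon apolar), so
#' polar + apolar = total exactly.
#'
#' @param components list of Structures (the complex is their union).
#' @param probe,n_points forwarded to [shrake_rupley()].
#' @return list: total, polar, apolar (Angstrom^2), and `per_atom` burial
#'   with the component index of each atom.
#' @export
interface_bsa <- function(components, probe = 1.4, n_points = 960) {
  complexed <- combine_structures(components)
  a_cplx <- shrake_rupley(complexed, probe, n_points)
  a_sep <- unlist(lapply(components, shrake_rupley, probe = probe,
                         n_points = n_points))
  burial <- a_sep - a_cplx
  polar <- complexed$atoms$polar
  total <- sum(burial)
  if (total < 0) {
    warning("negative total burial clamped to 0")
    total <- 0
  }
  list(total = total,
       polar = sum(burial[polar]), apolar = sum(burial[!polar]),
       per_atom = data.frame(
         component = rep(seq_along(components),
                         vapply(components, function(s) nrow(s$atoms), 0L)),
         chain = complexed$atoms$chain, resi = complexed$atoms$resi,
         name = complexed$atoms$name, polar = polar, burial = burial,
         stringsAsFactors = FALSE))
}

#' Classify interface residues as core, rim or support
#'
#' Interface residues are those with nonzero per-residue BSA. Classes
#' follow the Levy scheme on relative SASA (rASA, Tien et al. maxima) at
#' the 25% threshold: core residues are exposed in the isolated component
#' (rASA >= 0.25) but buried in the complex (rASA < 0.25); rim residues
#' remain exposed in the complex; support residues are already buried in
#' the isolated component. The three sets are disjoint and cover the
#' interface.
#'
#' @param components list of Structures.
#' @param probe,n_points forwarded to SASA.
#' @param rasa_threshold burial threshold (default 0.25).
#' @return list: `interface` (data frame with rASA values and class),
#'   `core`, `rim`, `support` (subsets), `counts` (named vector), `bsa`.
#' @export
classify_interface_residues <- function(components, probe = 1.4,
                                        n_points = 960,
                                        rasa_threshold = 0.25) {
  bsa <- interface_bsa(components, probe, n_points)
  complexed <- combine_structures(components)
  rs_cplx <- residue_sasa(complexed, probe = probe, n_points = n_points)
  rs_sep <- do.call(rbind, lapply(components, residue_sasa, probe = probe,
                                  n_points = n_points))
  res_burial <- tapply(bsa$per_atom$burial,
                       paste(bsa$per_atom$chain, bsa$per_atom$resi), sum)
  key <- paste(rs_cplx$chain, rs_cplx$resi)
  comp_of <- bsa$per_atom$component[!duplicated(paste(bsa$per_atom$chain,
                                                      bsa$per_atom$resi))]
  df <- data.frame(chain = rs_cplx$chain, resi = rs_cplx$resi,
                   resn = rs_cplx$resn, component = comp_of,
                   bsa = as.numeric(res_burial[key]),
                   rasa_complex = rs_cplx$rasa,
                   rasa_monomer = rs_sep$rasa[match(key, paste(rs_sep$chain,
                                                               rs_sep$resi))],
                   stringsAsFactors = FALSE)
  iface <- df[df$bsa > 1e-9, , drop = FALSE]
  cls <- ifelse(iface$rasa_complex >= rasa_threshold, "rim",
                ifelse(iface$rasa_monomer >= rasa_threshold, "core",
                       "support"))
  iface$class <- cls
  counts <- c(core = sum(cls == "core"), rim = sum(cls == "rim"),
              support = sum(cls == "support"))
  list(interface = iface,
       core = iface[cls == "core", , drop = FALSE],
       rim = iface[cls == "rim", , drop = FALSE],
       support = iface[cls == "support", , drop = FALSE],
       counts = counts, bsa = bsa)
}

#' Interface composition similarity
#'
#' Compares measured core/rim/support counts with the size-expected
#' counts from the Levy linear fits (`core = 0.01*BSA + 0.6`,
#' `rim = 0.01*BSA - 2.5`, `support = 0.006*BSA + 5`) and averages
#' `1 - |expected - measured| / expected` over the classes, each term
#' floored at 0. A value of 1 indicates exact similarity to the expected
#' composition, 0 no similarity. Classes whose expected count is
#' non-positive (tiny interfaces) are skipped.
#'
#' @param bsa buried surface area (Angstrom^2, > 0).
#' @param counts named vector or list with core, rim, support counts.
#' @return Similarity in \[0, 1\].
#' @export
composition_similarity <- function(bsa, counts) {
  if (bsa <= 0) stop("BSA must be positive")
  expected <- c(core = 0.01 * bsa + 0.6, rim = 0.01 * bsa - 2.5,
                support = 0.006 * bsa + 5)
  measured <- c(core = counts[["core"]], rim = counts[["rim"]],
                support = counts[["support"]])
  use <- expected > 0
  if (!any(use)) stop("all expected class counts are non-positive")
  terms <- pmax(0, 1 - abs(expected[use] - measured[use]) / expected[use])
  mean(terms)
}

# Donor and acceptor heavy atoms by residue chemistry; the backbone amide
# N (except proline) donates and the backbone carbonyl O accepts.
SC_DONORS <- list(ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
                  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG",
                  THR = "OG1", TRP = "NE1", TYR = "OH", CYS = "SG")
SC_ACCEPTORS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                     ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
                     SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG")

hbond_sites <- function(s) {
  a <- s$atoms
  rt_key <- paste(a$chain, a$resi, a$icode)
  don <- (a$name == "N" & a$resn != "PRO") |
    mapply(function(nm, rn) nm %in% (SC_DONORS[[rn]] %||% character(0)),
           a$name, a$resn)
  acc <- a$name == "O" |
    mapply(function(nm, rn) nm %in% (SC_ACCEPTORS[[rn]] %||% character(0)),
           a$name, a$resn)
  list(donors = which(don), acceptors = which(acc), key = rt_key)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Approximate amide H position for a backbone N: along the unit bisector
# opposite the CA and preceding C directions.
amide_h <- function(s, ni) {
  a <- s$atoms
  key <- paste(a$chain, a$resi, a$icode)
  this <- key == key[ni]
  ca <- which(this & a$name == "CA")
  prevres <- which(a$chain == a$chain[ni] & a$resi == a$resi[ni] - 1L &
                     a$name == "C")
  if (!length(ca) || !length(prevres)) return(NULL)
  N <- as.numeric(a[ni, c("x", "y", "z")])
  CA <- as.numeric(a[ca[1], c("x", "y", "z")])
  Cp <- as.numeric(a[prevres[1], c("x", "y", "z")])
  u <- (N - CA) / sqrt(sum((N - CA)^2)) + (N - Cp) / sqrt(sum((N - Cp)^2))
  if (sqrt(sum(u^2)) < 1e-9) return(NULL)
  N + u / sqrt(sum(u^2)) * 1.01
}

#' Geometric hydrogen-bond detection
#'
#' A donor-acceptor pair forms a hydrogen bond when the heavy-atom
#' distance is below `dist_max` and the donor-H...acceptor angle exceeds
#' `angle_min` degrees. Explicit hydrogens are used when present;
#' otherwise the backbone amide H is placed geometrically and side-chain
#' donors fall back to an antecedent-based angle check.
#'
#' @param s Structure.
#' @param dist_max donor-acceptor heavy-atom distance (default 3.5).
#' @param angle_min minimum donor-H-acceptor angle in degrees (default 120).
#' @return data frame of bonds: donor/acceptor atom indices, chains,
#'   residues, distance and angle.
#' @export
hydrogen_bonds <- function(s, dist_max = 3.5, angle_min = 120) {
  sites <- hbond_sites(s)
  a <- s$atoms
  xyz <- atom_coords(s)
  rows <- list()
  for (di in sites$donors) {
    D <- xyz[di, ]
    H <- if (a$name[di] == "N") amide_h(s, di) else NULL
    for (ai in sites$acceptors) {
      if (sites$key[di] == sites$key[ai]) next
      A <- xyz[ai, ]
      dd <- sqrt(sum((D - A)^2))
      if (dd > dist_max || dd < 1.5) next
      ang <- if (!is.null(H)) {
        v1 <- D - H; v2 <- A - H
        acos(min(1, max(-1, sum(v1 * v2) /
                          sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      } else NA_real_
      if (!is.na(ang) && ang < angle_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor = di, acceptor = ai,
        chain_d = a$chain[di], resi_d = a$resi[di],
        chain_a = a$chain[ai], resi_a = a$resi[ai],
        dist = dd, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(donor = integer(), acceptor = integer(),
                      chain_d = character(), resi_d = integer(),
                      chain_a = character(), resi_a = integer(),
                      dist = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Count buried polar sites (donors/acceptors with SASA below sasa_max)
# not engaged in any hydrogen bond within the given structure.
count_buried_unsat <- function(s, probe = 1.4, n_points = 240,
                               sasa_max = 0.1) {
  area <- shrake_rupley(s, probe, n_points)
  sites <- hbond_sites(s)
  hb <- hydrogen_bonds(s)
  bonded <- unique(c(hb$donor, hb$acceptor))
  polar_sites <- unique(c(sites$donors, sites$acceptors))
  sum(area[polar_sites] < sasa_max & !(polar_sites %in% bonded))
}

#' Buried unsatisfied hydrogen-bond density
#'
#' Counts buried polar donors/acceptors without a hydrogen-bond partner
#' in the complexed state, subtracts the count in the uncomplexed state
#' (no repacking), and normalizes per 1,000 Angstrom^2 of BSA.
#'
#' @param components list of Structures forming the complex.
#' @param bsa buried surface area; computed when missing.
#' @param probe,n_points forwarded to SASA.
#' @return list: `unsat_complex`, `unsat_unbound`, `buried_unsat`,
#'   `density` (per 1,000 Angstrom^2; NA when BSA is 0).
#' @export
buried_unsat_density <- function(components, bsa = NULL, probe = 1.4,
                                 n_points = 240) {
  if (is.null(bsa)) bsa <- interface_bsa(components, probe, n_points)$total
  complexed <- combine_structures(components)
  uc <- count_buried_unsat(complexed, probe, n_points)
  uu <- sum(vapply(components, count_buried_unsat, 0, probe = probe,
                   n_points = n_points))
  diffn <- uc - uu
  dens <- if (bsa > 0) diffn / (bsa / 1000) else NA_real_
  list(unsat_complex = uc, unsat_unbound = uu, buried_unsat = diffn,
       density = dens)
}

HCI_SET <- c("F", "M", "I", "L", "Y", "V", "W")
HCI_THRESHOLD <- 0.48

#' Hydrophobic collapse index
#'
#' Windowed density of the hydrophobic residue set FMILYVW (uniform
#' 9-residue centered window; truncated at the termini).
#'
#' @param sequence one-letter string or character vector.
#' @param window odd window size (default 9).
#' @param set hydrophobic residue set.
#' @return Numeric vector of per-position HCI values.
#' @export
hci <- function(sequence, window = 9, set = HCI_SET) {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  h <- as.numeric(aa %in% set)
  half <- (window - 1L) %/% 2L
  n <- length(h)
  vapply(seq_len(n), function(i) {
    mean(h[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' New hydrophobic collapse sites in a designed sequence
#'
#' Positions whose HCI exceeds the threshold (0.48) in the designed
#' sequence but not in the reference sequence from before design.
#'
#' @param designed,reference sequences of equal length.
#' @param threshold HCI threshold (default 0.48).
#' @param window HCI window (default 9).
#' @return Integer positions of new collapse sites.
#' @export
hci_new_sites <- function(designed, reference, threshold = HCI_THRESHOLD,
                          window = 9) {
  d <- hci(designed, window)
  r <- hci(reference, window)
  if (length(d) != length(r)) stop("sequence lengths differ")
  which(d > threshold & r <= threshold)
}

#' Spike ratio of a two-component cage
#'
#' One minus the ratio of the two components' center-of-mass distances
#' from the full-cage center of mass, the larger distance in the
#' denominator: equidistant components give 0; one component twice as far
#' out as the other gives 0.5.
#'
#' @param pose `cage_pose`, or NULL when distances are given directly.
#' @param d_a,d_b optional center-of-mass distances (Angstrom) overriding
#'   the pose-derived values.
#' @return Spike ratio in \[0, 1).
#' @export
spike_ratio <- function(pose = NULL, d_a = NULL, d_b = NULL) {
  if (is.null(d_a) || is.null(d_b)) {
    pl <- place_pose(pose)
    cage <- expand_pose(pose)
    ctr <- colMeans(atom_coords(cage))
    d_a <- sqrt(sum((colMeans(atom_coords(pl$A)) - ctr)^2))
    d_b <- sqrt(sum((colMeans(atom_coords(pl$B)) - ctr)^2))
  }
  mx <- max(d_a, d_b)
  if (mx <= 0) stop("degenerate geometry: both components at the cage center")
  1 - min(d_a, d_b) / mx
}

#' Percent of interface residues with large C-beta separation
#'
#' For every interface residue, the minimum C-beta (C-alpha for glycine)
#' distance to any residue across the interface; reported as the percent
#' of interface residues whose minimum exceeds `cutoff`.
#'
#' @param components list of two Structures (placed).
#' @param interface data frame chain, resi, component (e.g. from
#'   [classify_interface_residues()]); computed from BSA when missing.
#' @param cutoff separation cutoff (default 8 Angstrom).
#' @param n_points SASA points when the interface must be computed.
#' @return Percent in \[0, 100\], or NA when there are no interface
#'   residues.
#' @export
cbeta_separation_stats <- function(components, interface = NULL,
                                   cutoff = 8, n_points = 240) {
  if (is.null(interface)) {
    interface <- classify_interface_residues(components,
                                             n_points = n_points)$interface
  }
  if (!nrow(interface)) return(NA_real_)
  cbs <- lapply(components, cbeta_coords)
  dists <- vapply(seq_len(nrow(interface)), function(i) {
    comp <- interface$component[i]
    own <- cbs[[comp]]
    j <- which(own$res$chain == interface$chain[i] &
                 own$res$resi == interface$resi[i])
    if (!length(j)) return(NA_real_)
    p <- own$xyz[j[1], ]
    other <- do.call(rbind, lapply(seq_along(cbs)[-comp],
                                   function(k) cbs[[k]]$xyz))
    sqrt(min(rowSums(sweep(other, 2, p)^2)))
  }, numeric(1))
  100 * mean(dists > cutoff, na.rm = TRUE)
}

#' Full metric record for a pose
#'
#' Computes the interface metric suite on the placed A-B pair of a pose:
#' BSA and its polarity split, core/rim/support counts, composition
#' similarity, secondary-structure fractions of the interface, hydrogen
#' bonds and buried-unsat density, C-beta separation, spike ratio, and
#' the Nanohedra score of the attached observations.
#'
#' @param pose `cage_pose`.
#' @param n_points SASA quadrature points (a coarse default keeps the
#'   suite fast on synthetic structures).
#' @return Named list of metrics (one flat record).
#' @export
pose_metrics <- function(pose, n_points = 240) {
  pl <- place_pose(pose)
  comps <- list(pl$A, pl$B)
  cls <- classify_interface_residues(comps, n_points = n_points)
  bsa <- cls$bsa
  iface <- cls$interface
  comp_sim <- if (bsa$total > 0) {
    composition_similarity(bsa$total, as.list(cls$counts))
  } else NA_real_
  ssfr <- if (nrow(iface)) {
    ssA <- assign_secondary_structure(pl$A)
    ssB <- assign_secondary_structure(pl$B)
    ss_fractions(rbind(ssA, ssB), iface[, c("chain", "resi")])
  } else c(pct_helix = NA_real_, pct_strand = NA_real_,
           pct_coil = NA_real_)
  hb <- hydrogen_bonds(combine_structures(comps))
  bu <- buried_unsat_density(comps, bsa = bsa$total, n_points = n_points)
  ns <- nanohedra_score(pose$observations)
  list(bsa_total = bsa$total, bsa_polar = bsa$polar,
       bsa_apolar = bsa$apolar,
       pct_hydrophobic_bsa = if (bsa$total > 0) {
         100 * bsa$apolar / bsa$total
       } else NA_real_,
       n_interface_residues = nrow(iface),
       core = unname(cls$counts["core"]), rim = unname(cls$counts["rim"]),
       support = unname(cls$counts["support"]),
       composition_similarity = comp_sim,
       pct_helix = unname(ssfr["pct_helix"]),
       pct_strand = unname(ssfr["pct_strand"]),
       pct_coil = unname(ssfr["pct_coil"]),
       n_hbonds = nrow(hb),
       buried_unsat_density = bu$density,
       pct_cbeta_over_8 = cbeta_separation_stats(comps, iface,
                                                 n_points = n_points),
       spike_ratio = spike_ratio(pose),
       nanohedra_total = ns$total, nanohedra_normalized = ns$normalized,
       n_fragment_residues = ns$n_residues,
       n_observations = if (is.null(pose$observations)) 0L
                        else nrow(pose$observations))
}
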