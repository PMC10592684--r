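# Solvent accessible surface area by the Shrake-Rupley quadrature.

# Standard van der Waals radii (Angstrom).
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# Theoretical maximum accessible surface areas per residue type
# (Tien et al. 2013), used to normalize relative SASA.
TIEN_MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
                  GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
                  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
                  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# Near-uniform points on the unit sphere (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Quadrature over `n_points` test points per atom on the solvent-expanded
#' sphere of radius `r + probe`. A point is accessible when it lies outside
#' every neighbouring atom's expanded sphere. An isolated atom recovers the
#' closed form 4*pi*(r+probe)^2 up to quadrature error.
#'
#' @param s Structure.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (default 960).
#' @param radii named per-element van der Waals radii; unknown elements use
#'   the carbon radius with a warning.
#' @return Numeric vector of per-atom areas (Angstrom^2).
#' @export
shrake_rupley <- function(s, probe = 1.4, n_points = 960,
                          radii = VDW_RADII) {
  el <- s$atoms$element
  r <- radii[el]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ","),
            "; using carbon radius")
    r[is.na(r)] <- radii[["C"]]
  }
  r <- unname(r) + probe
  xyz <- atom_coords(s)
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  # neighbour lists: atoms whose expanded spheres can intersect
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    cut <- (r[i] + r)^2
    nb <- which(d2[i, ] < cut & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    nxyz <- xyz[nb, , drop = FALSE]
    pd2 <- outer(rowSums(p^2), rowSums(nxyz^2), "+") - 2 * p %*% t(nxyz)
    buried <- rowSums(pd2 < matrix(r[nb]^2, n_points, length(nb),
                                   byrow = TRUE)) > 0
    area[i] <- 4 * pi * r[i]^2 * mean(!buried)
  }
  area
}

#' Per-residue SASA summary
#'
#' Sums per-atom areas by residue and normalizes by the Tien et al.
#' theoretical maximum to give relative SASA (rASA). Side-chain exposure is
#' reported relative to the summed free-sphere areas of the residue's
#' side-chain atoms (C-alpha for glycine), a reference that remains
#' meaningful for reduced atom sets.
#'
#' @param s Structure.
#' @param area per-atom SASA from [shrake_rupley()] (computed if missing).
#' @param probe,n_points forwarded to [shrake_rupley()] when needed.
#' @return data frame: chain, resi, resn, sasa, rasa, sc_rel.
#' @export
residue_sasa <- function(s, area = NULL, probe = 1.4, n_points = 960) {
  if (is.null(area)) area <- shrake_rupley(s, probe, n_points)
  rt <- residue_table(s)
  keys <- residue_key(rt$chain, rt$resi, rt$icode)
  akey <- atom_residue_key(s)
  el <- s$atoms$element
  rad <- VDW_RADII[el]
  rad[is.na(rad)] <- VDW_RADII[["C"]]
  free <- 4 * pi * (unname(rad) + probe)^2
  is_sc <- !(s$atoms$name %in% c(BACKBONE_NAMES, "H", "HA"))
  tot <- sc <- scfree <- numeric(nrow(rt))
  for (i in seq_len(nrow(rt))) {
    in_res <- akey == keys[i]
    tot[i] <- sum(area[in_res])
    sc_sel <- in_res & if (rt$resn[i] == "GLY") s$atoms$name == "CA" else is_sc
    sc[i] <- sum(area[sc_sel])
    scfree[i] <- sum(free[sc_sel])
  }
  mx <- TIEN_MAX_ASA[rt$resn]
  mx[is.na(mx)] <- mean(TIEN_MAX_ASA)
  data.frame(chain = rt$chain, resi = rt$resi, resn = rt$resn,
             sasa = tot, rasa = tot / unname(mx),
             sc_rel = ifelse(scfree > 0, sc / scfree, 0),
             stringsAsFactors = FALSE)
}
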