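# Backbone dihedrals and three-state secondary structure assignment.

# Torsion angle (degrees) defined by four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi angles
#'
#' @param s Structure.
#' @return data frame chain, resi, phi, psi (degrees; NA at termini and
#'   across chain breaks, detected as C-N distances above 2.5 Angstrom).
#' @export
backbone_dihedrals <- function(s) {
  rt <- residue_table(s)
  keys <- residue_key(rt$chain, rt$resi, rt$icode)
  akey <- atom_residue_key(s)
  getat <- function(i, nm) {
    j <- which(akey == keys[i] & s$atoms$name == nm)
    if (!length(j)) return(NULL)
    as.numeric(s$atoms[j[1], c("x", "y", "z")])
  }
  n <- nrow(rt)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- getat(i, "N"); CAi <- getat(i, "CA"); Ci <- getat(i, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 1 && rt$chain[i - 1] == rt$chain[i]) {
      Cp <- getat(i - 1, "C")
      if (!is.null(Cp) && sqrt(sum((Cp - Ni)^2)) < 2.5) {
        phi[i] <- dihedral(Cp, Ni, CAi, Ci)
      }
    }
    if (i < n && rt$chain[i + 1] == rt$chain[i]) {
      Nn <- getat(i + 1, "N")
      if (!is.null(Nn) && sqrt(sum((Ci - Nn)^2)) < 2.5) {
        psi[i] <- dihedral(Ni, CAi, Ci, Nn)
      }
    }
  }
  data.frame(chain = rt$chain, resi = rt$resi, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' Three-state secondary structure from backbone dihedrals
#'
#' Assigns H (helix), E (strand) or C (loop/coil) from phi/psi windows:
#' helix for phi in (-100, -30) and psi in (-80, -5); strand for
#' phi in (-180, -40) and psi in (45, 180\] or below -160. Residues with
#' undefined dihedrals (termini, chain breaks) are assigned C. An
#' externally supplied assignment (e.g. a Stride file read with
#' [read_ss_file()]) can be passed through unchanged instead.
#'
#' @param s Structure.
#' @param override optional data frame chain, resi, ss that replaces the
#'   internal assignment verbatim.
#' @return data frame chain, resi, ss.
#' @export
assign_secondary_structure <- function(s, override = NULL) {
  dih <- backbone_dihedrals(s)
  if (!is.null(override)) {
    key <- paste(dih$chain, dih$resi)
    okey <- paste(override$chain, override$resi)
    m <- match(key, okey)
    ss <- ifelse(is.na(m), "C", override$ss[m])
    return(data.frame(chain = dih$chain, resi = dih$resi, ss = ss,
                      stringsAsFactors = FALSE))
  }
  ss <- rep("C", nrow(dih))
  ok <- !is.na(dih$phi) & !is.na(dih$psi)
  helix <- ok & dih$phi > -100 & dih$phi < -30 & dih$psi > -80 & dih$psi < -5
  strand <- ok & dih$phi > -180 & dih$phi < -40 &
    (dih$psi > 45 | dih$psi < -160)
  ss[strand] <- "E"
  ss[helix] <- "H"
  data.frame(chain = dih$chain, resi = dih$resi, ss = ss,
             stringsAsFactors = FALSE)
}

#' Read a secondary-structure assignment file
#'
#' Accepts Stride-style `ASG` records (`ASG  ALA A    1    1    H ...`)
#' or a plain whitespace/tab table with columns chain, resi, ss.
#'
#' @param path file path.
#' @return data frame chain, resi, ss.
#' @export
read_ss_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  asg <- grepl("^ASG", lines)
  if (any(asg)) {
    parts <- strsplit(trimws(lines[asg]), "\\s+")
    return(data.frame(chain = vapply(parts, `[`, "", 3),
                      resi = as.integer(vapply(parts, `[`, "", 4)),
                      ss = vapply(parts, `[`, "", 6),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chain", "resi", "ss")
  df$resi <- as.integer(df$resi)
  df[, c("chain", "resi", "ss")]
}

#' Secondary-structure fractions over a residue subset
#'
#' Percentages use the subset size as the denominator (the convention for
#' interface residues).
#'
#' @param ss data frame chain, resi, ss.
#' @param subset data frame chain, resi selecting the residues (default:
#'   all assigned residues).
#' @return named numeric: pct_helix, pct_strand, pct_coil.
#' @export
ss_fractions <- function(ss, subset = NULL) {
  if (!is.null(subset)) {
    m <- match(paste(subset$chain, subset$resi), paste(ss$chain, ss$resi))
    lab <- ss$ss[m[!is.na(m)]]
  } else {
    lab <- ss$ss
  }
  n <- length(lab)
  if (!n) return(c(pct_helix = NA_real_, pct_strand = NA_real_,
                   pct_coil = NA_real_))
  c(pct_helix = 100 * sum(lab == "H") / n,
    pct_strand = 100 * sum(lab == "E") / n,
    pct_coil = 100 * sum(lab == "C") / n)
}
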