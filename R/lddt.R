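# Superposition-free structure comparison: the local distance difference
# test (lDDT).

#' Local distance difference test
#'
#' Superposition-free agreement score in \[0, 1\]. All heavy-atom pairs from
#' different residues whose reference distance is below the inclusion
#' radius define the local environment; the score is the mean, over the
#' four tolerance thresholds, of the fraction of those distances preserved
#' within tolerance in the model. Atoms are matched between model and
#' reference by chain, residue number and atom name. For symmetric
#' assemblies the convention is to score a single chain.
#'
#' @param model,reference Structures with corresponding residue numbering.
#' @param inclusion_radius environment radius in Angstrom (default 15).
#' @param thresholds tolerance thresholds in Angstrom
#'   (default `c(0.5, 1, 2, 4)`, the original definition).
#' @return Score in \[0, 1\].
#' @export
lddt <- function(model, reference, inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4)) {
  mk <- paste(model$atoms$chain, model$atoms$resi, model$atoms$icode,
              model$atoms$name)
  rk <- paste(reference$atoms$chain, reference$atoms$resi,
              reference$atoms$icode, reference$atoms$name)
  common <- intersect(rk, mk)
  if (length(common) < 2L) stop("no atom correspondence between structures")
  mi <- match(common, mk); ri <- match(common, rk)
  M <- atom_coords(model)[mi, , drop = FALSE]
  R <- atom_coords(reference)[ri, , drop = FALSE]
  res_r <- paste(reference$atoms$chain, reference$atoms$resi,
                 reference$atoms$icode)[ri]
  dr <- as.matrix(stats::dist(R))
  dm <- as.matrix(stats::dist(M))
  diff_res <- outer(res_r, res_r, "!=")
  sel <- upper.tri(dr) & diff_res & dr <= inclusion_radius
  if (!any(sel)) stop("no reference distances within the inclusion radius")
  dd <- abs(dm[sel] - dr[sel])
  mean(vapply(thresholds, function(th) mean(dd <= th), numeric(1)))
}
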