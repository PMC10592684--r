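# Point-group symmetry: entries, generator closure, and assembly expansion.

# Chain-id pool for expanded assemblies (PDB has one-character chain ids).
CHAIN_POOL <- c(LETTERS, letters, as.character(0:9))

#' Define a point-group symmetry entry
#'
#' A `SymmetryEntry` carries the point-group label, the closed set of
#' rotation generators, and (for two-component architectures) the internal
#' symmetry axis assigned to each component. In the tetrahedral
#' T:{C3}{C3} architecture each component keeps four degrees of freedom:
#' rotation about and translation along its own 3-fold axis, which lies on
#' a body diagonal of a cube.
#'
#' @param group one of `"C1"`, `"C3"`, `"T"`.
#' @param axis symmetry axis for cyclic groups (default z).
#' @return Object of class `SymmetryEntry` with fields `group`, `order`,
#'   `generators` (list of 3x3 matrices) and `axes` (per-component unit
#'   axes; for `"T"`, component A on (1,1,1)/sqrt(3) and component B on
#'   (-1,-1,1)/sqrt(3), two distinct body-diagonal classes).
#' @export
symmetry_entry <- function(group = c("T", "C3", "C1"), axis = c(0, 0, 1)) {
  group <- match.arg(group)
  axis <- axis / sqrt(sum(axis^2))
  if (group == "C1") {
    gens <- list(diag(3))
    axes <- list(A = axis)
  } else if (group == "C3") {
    gens <- lapply(c(0, 120, 240), function(a) rotation_about_axis(axis, a))
    axes <- list(A = axis)
  } else {
    seed <- list(rotation_about_axis(c(1, 1, 1), 120),
                 diag(c(-1, -1, 1)))
    gens <- group_closure(seed)
    axes <- list(A = c(1, 1, 1) / sqrt(3), B = c(-1, -1, 1) / sqrt(3))
  }
  for (g in gens) {
    if (!is_rotation_matrix(g)) stop("generator is not a proper rotation")
  }
  expected <- c(C1 = 1L, C3 = 3L, T = 12L)[[group]]
  if (length(gens) != expected) {
    stop(sprintf("group %s closed to order %d, expected %d",
                 group, length(gens), expected))
  }
  structure(list(group = group, order = length(gens), generators = gens,
                 axes = axes), class = "SymmetryEntry")
}

#' @export
print.SymmetryEntry <- function(x, ...) {
  cat(sprintf("SymmetryEntry %s (order %d), %d component axis/axes\n",
              x$group, x$order, length(x$axes)))
  invisible(x)
}

# Close a generator seed set under matrix multiplication.
group_closure <- function(gens, max_order = 60) {
  key <- function(m) {
    v <- round(m, 6)
    v[v == 0] <- 0  # normalize negative zero
    paste(sprintf("%.6f", v), collapse = ",")
  }
  out <- list(diag(3))
  names(out) <- key(diag(3))
  repeat {
    added <- FALSE
    for (g in gens) {
      for (h in out) {
        m <- g %*% h
        k <- key(m)
        if (is.null(out[[k]])) {
          out[[k]] <- m
          added <- TRUE
        }
      }
    }
    if (!added) break
    if (length(out) > max_order) stop("group closure exceeded max order")
  }
  unname(out)
}

#' Expand an asymmetric unit under a point group
#'
#' Applies every group rotation to every chain of the asymmetric unit,
#' producing `order` copies of each chain. The first (identity) copy keeps
#' the original chain ids; further copies draw fresh ids from a pool.
#' Entity labels are propagated so copies of the same protein remain
#' grouped.
#'
#' @param asu Structure positioned consistently with the entry axes.
#' @param entry `SymmetryEntry`.
#' @return Expanded `Structure`.
#' @export
expand_point_group <- function(asu, entry) {
  gens <- entry$generators
  for (g in gens) {
    if (!is_rotation_matrix(g)) {
      stop("invalid symmetry entry: generator is not orthonormal with det +1")
    }
  }
  chains <- unique(asu$atoms$chain)
  used <- chains
  pool <- setdiff(CHAIN_POOL, used)
  out <- list()
  for (gi in seq_along(gens)) {
    tf <- rigid_transform(gens[[gi]], c(0, 0, 0))
    copy <- transform_structure(asu, tf)
    if (gi > 1L) {
      newids <- pool[seq_along(chains)]
      pool <- pool[-seq_along(chains)]
      map <- stats::setNames(newids, chains)
      copy$atoms$chain <- map[copy$atoms$chain]
      copy$entities <- stats::setNames(asu$entities[chains], newids)
    }
    out[[gi]] <- copy
  }
  combine_structures(out)
}
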