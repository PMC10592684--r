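# Metric normalization, weighted ranking and filter cascades for pose and
# design selection.

#' Built-in or custom weight scheme
#'
#' The two published schemes ship as built-ins:
#' `"t33fn_pose"` — fragment-residue shape complementarity (higher, 0.3),
#' interface composition similarity (higher, 0.4), percent of interface
#' with fragment observations (higher, 0.1), percent hydrophobic BSA
#' (lower, 0.2); and `"t33fn_design"` — interface energy (lower, 0.25),
#' bound-configuration energy (lower, 0.15), interface local density
#' (higher, 0.2), buried-unsat density (lower, 0.15), shape
#' complementarity (higher, 0.1), BSA/SASA ratio (lower, 0.15).
#'
#' @param name built-in name, or NULL when supplying `metrics` directly.
#' @param metrics data frame with columns metric, direction
#'   (`"higher"`/`"lower"`), weight.
#' @return Object of class `weight_scheme` (weights validated to sum 1).
#' @export
weight_scheme <- function(name = NULL, metrics = NULL) {
  builtins <- list(
    t33fn_pose = data.frame(
      metric = c("sc_fragment", "composition_similarity",
                 "pct_fragment_interface", "pct_hydrophobic_bsa"),
      direction = c("higher", "higher", "higher", "lower"),
      weight = c(0.3, 0.4, 0.1, 0.2), stringsAsFactors = FALSE),
    t33fn_design = data.frame(
      metric = c("interface_energy", "bound_configuration_energy",
                 "interface_local_density", "buried_unsat_density",
                 "shape_complementarity", "bsa_sasa_ratio"),
      direction = c("lower", "lower", "higher", "lower", "higher", "lower"),
      weight = c(0.25, 0.15, 0.2, 0.15, 0.1, 0.15),
      stringsAsFactors = FALSE))
  if (!is.null(name)) {
    if (!name %in% names(builtins)) {
      stop("unknown scheme '", name, "'; built-ins: ",
           paste(names(builtins), collapse = ", "))
    }
    metrics <- builtins[[name]]
  }
  if (is.null(metrics)) stop("supply a scheme name or a metrics table")
  if (!all(metrics$direction %in% c("higher", "lower"))) {
    stop("directions must be 'higher' or 'lower'")
  }
  if (abs(sum(metrics$weight) - 1) > 1e-9) {
    stop("scheme weights must sum to 1 (got ", sum(metrics$weight), ")")
  }
  structure(list(name = name, metrics = metrics), class = "weight_scheme")
}

#' Min-max normalize metric columns
#'
#' Each column is scaled to \[0, 1\] over the rows considered
#' (lower-is-better columns are flipped to `1 - x` after scaling so that
#' larger is always better). Constant columns — including any single-row
#' table — normalize to 0.5. Missing values receive the column median
#' before normalization and are flagged in the `imputed` attribute;
#' all-missing columns are dropped with a warning.
#'
#' @param table data frame of raw metrics.
#' @param directions optional named vector metric -> "higher"/"lower"
#'   (default: higher for all).
#' @return data frame of normalized columns (raw columns untouched).
#' @export
normalize_metrics <- function(table, directions = NULL) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  out <- table[, intersect(names(table), num), drop = FALSE]
  imputed <- list()
  for (cn in names(out)) {
    x <- out[[cn]]
    if (all(is.na(x))) {
      warning("column '", cn, "' is all-missing; excluded")
      out[[cn]] <- NULL
      next
    }
    if (anyNA(x)) {
      imputed[[cn]] <- which(is.na(x))
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    }
    rng <- range(x)
    y <- if (diff(rng) == 0) rep(0.5, length(x))
         else (x - rng[1]) / diff(rng)
    if (!is.null(directions) && cn %in% names(directions) &&
        directions[[cn]] == "lower") {
      y <- 1 - y
      if (diff(rng) == 0) y <- rep(0.5, length(x))
    }
    out[[cn]] <- y
  }
  attr(out, "imputed") <- imputed
  out
}

#' Weighted ranking of poses or designs
#'
#' Score = sum over scheme metrics of weight times the min-max normalized
#' value (direction applied); rows are returned best first with a
#' deterministic tie-break on row id.
#'
#' @param table data frame of raw metrics; a column `id` (or the row
#'   names) identifies rows.
#' @param scheme `weight_scheme`.
#' @return `table` with a `selection_score` column, ordered by descending
#'   score (ties: ascending id).
#' @export
weighted_rank <- function(table, scheme) {
  stopifnot(inherits(scheme, "weight_scheme"))
  need <- scheme$metrics$metric
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table lacks scheme metric(s): ",
                         paste(miss, collapse = ", "))
  dirs <- stats::setNames(scheme$metrics$direction, need)
  norm <- normalize_metrics(table[, need, drop = FALSE], dirs)
  score <- as.matrix(norm[, need, drop = FALSE]) %*% scheme$metrics$weight
  id <- if ("id" %in% names(table)) table$id else seq_len(nrow(table))
  out <- table
  out$selection_score <- as.numeric(score)
  out[order(-out$selection_score, id), , drop = FALSE]
}

#' Apply a filter cascade with attrition logging
#'
#' Filters are conjunctive; the attrition log reports, in order, how many
#' rows each filter removed from the survivors of the previous ones.
#' Missing metric values fail a filter (and are counted in its attrition).
#'
#' @param table data frame of metrics.
#' @param filters list of `list(metric=, op=, value=)` with op one of
#'   `<`, `<=`, `>`, `>=`, `==`.
#' @return list: `table` (surviving rows), `attrition` (data frame
#'   metric, op, value, removed, remaining).
#' @export
apply_filters <- function(table, filters) {
  log_rows <- list()
  for (f in filters) {
    if (!f$metric %in% names(table)) {
      stop("unknown metric in filter: '", f$metric, "'")
    }
    if (!f$op %in% c("<", "<=", ">", ">=", "==")) {
      stop("unknown comparator: ", f$op)
    }
    before <- nrow(table)
    keep <- do.call(f$op, list(table[[f$metric]], f$value))
    keep[is.na(keep)] <- FALSE
    table <- table[keep, , drop = FALSE]
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      metric = f$metric, op = f$op, value = f$value,
      removed = before - nrow(table), remaining = nrow(table),
      stringsAsFactors = FALSE)
  }
  attrition <- if (length(log_rows)) do.call(rbind, log_rows)
               else data.frame(metric = character(), op = character(),
                               value = numeric(), removed = integer(),
                               remaining = integer(),
                               stringsAsFactors = FALSE)
  list(table = table, attrition = attrition)
}

#' Read a filter specification file
#'
#' Flat key/op/value lines, e.g. `composition_similarity >= 0.65`, one
#' filter per line; `#` comments and blank lines are ignored.
#'
#' @param path file path.
#' @return list of filters for [apply_filters()].
#' @export
read_filter_spec <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != 3L) stop("bad filter line: '", ln, "'")
    list(metric = tok[1], op = tok[2], value = as.numeric(tok[3]))
  })
}
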