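# End-to-end pipeline: dock -> profile -> metrics -> select, with a
# manifest recording per-stage counts in the attrition-report style.

#' Pipeline configuration
#'
#' @param oligA,oligB component PDB paths, or NULL to generate the
#'   synthetic docking scenario from `seed`.
#' @param db fragment database directory (NULL with the synthetic
#'   scenario, which carries its own).
#' @param out output directory.
#' @param seed integer seed for every stochastic stage.
#' @param dock named list of [dock_params()] overrides.
#' @param scheme selection scheme name (see [weight_scheme()]) or NULL
#'   for the default Nanohedra-score ordering.
#' @param filters list of filters for [apply_filters()] (optional).
#' @return Configuration list.
#' @export
run_config <- function(oligA = NULL, oligB = NULL, db = NULL,
                       out = "cageforge_run", seed = 1, dock = list(),
                       scheme = NULL, filters = list()) {
  list(oligA = oligA, oligB = oligB, db = db, out = out, seed = seed,
       dock = dock, scheme = scheme, filters = filters)
}

#' Run the docking-to-selection pipeline
#'
#' Stages: (1) load or synthesize inputs; (2) dock; (3) fragment profile
#' of the top poses; (4) interface metrics per pose; (5) filter and rank.
#' Stage artifacts are written under the output directory (poses as PDB,
#' observations as TSV, profiles as TSV, metrics as TSV/JSON) together
#' with a manifest of per-stage counts and the serialized configuration;
#' re-running from the saved configuration reproduces the outputs.
#'
#' @param config list from [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config[c("oligA", "oligB", "db", "out", "seed",
                                "dock", "scheme")],
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(seed = config$seed, stages = list())
  if (is.null(config$oligA)) {
    scen <- make_docking_scenario(seed = config$seed)
    oligA <- scen$oligA; oligB <- scen$oligB
    db <- scen$db; entry <- scen$entry
    params <- dock_params(rot_step = 4, trans_step = 0.5,
                          trans_range = scen$search$trans_range)
  } else {
    for (p in c(config$oligA, config$oligB)) {
      if (!file.exists(p)) stop("missing input file: ", p)
    }
    oligA <- read_pdb(config$oligA)
    oligB <- read_pdb(config$oligB)
    db <- load_fragment_db(config$db)
    entry <- symmetry_entry("T")
    params <- dock_params(trans_range = c(5, 40))
  }
  params[names(config$dock)] <- config$dock
  poses <- dock(oligA, oligB, db, entry, params)
  manifest$stages$dock <- list(poses = length(poses))
  pose_dir <- file.path(out, "poses")
  dir.create(pose_dir, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    pl <- place_pose(p)
    write_pdb(combine_structures(pl$A, pl$B),
              file.path(pose_dir, sprintf("pose_%02d.pdb", i)))
    utils::write.table(p$observations,
                       file.path(pose_dir, sprintf("pose_%02d_obs.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_res <- max(residue_table(oligA)$resi)
    prof <- fragment_profile(p$observations, db, n_res, "a")
    write_profile_tsv(prof, file.path(pose_dir,
                                      sprintf("pose_%02d_profile_a.tsv", i)))
    met <- pose_metrics(p)
    jsonlite::write_json(met, file.path(pose_dir,
                                        sprintf("pose_%02d_metrics.json", i)),
                         auto_unbox = TRUE, digits = NA)
    rows[[i]] <- cbind(data.frame(id = i, rot_a = p$dof["rot_a"],
                                  trans_a = p$dof["trans_a"],
                                  rot_b = p$dof["rot_b"],
                                  trans_b = p$dof["trans_b"],
                                  row.names = NULL),
                       as.data.frame(met))
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else data.frame()
  utils::write.table(metrics, file.path(out, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$metrics <- list(rows = nrow(metrics))
  if (nrow(metrics)) {
    flt <- apply_filters(metrics, config$filters)
    selected <- flt$table
    manifest$stages$filter <- list(
      survivors = nrow(selected),
      attrition = flt$attrition)
    if (!is.null(config$scheme)) {
      selected <- weighted_rank(selected, weight_scheme(config$scheme))
    } else if (nrow(selected)) {
      selected <- selected[order(-selected$nanohedra_normalized,
                                 selected$id), , drop = FALSE]
    }
    utils::write.table(selected, file.path(out, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$select <- list(rows = nrow(selected),
                                   top_id = if (nrow(selected))
                                     selected$id[1] else NA)
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
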