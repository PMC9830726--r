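#' Assemble a pipeline configuration
#'
#' @param simulate A [cohort_config()] to generate the cohort, or `NULL` when
#'   reading from files.
#' @param phenotypes_csv,intensity_csvs Input paths when `simulate` is
#'   `NULL`; `intensity_csvs` is a named list
#'   `list(maternal = list(pos = path, neg = path), cord = ...)`.
#' @param vip_threshold,n_orth,k_folds,scaling Analysis settings (see
#'   [discover_shapes()]).
#' @param covariate_preset Model-2 covariate preset ([model2_covariates()]).
#' @param seed Root seed; every stage derives its randomness from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list, validated.
#' @export
pipeline_config <- function(simulate = NULL, phenotypes_csv = NULL,
                            intensity_csvs = NULL, vip_threshold = 1,
                            n_orth = 1L, k_folds = 7L, scaling = "uv",
                            covariate_preset = "table", seed = 1L,
                            out_dir = tempfile("dyadmet_run_")) {
  if (is.null(simulate)) {
    if (is.null(phenotypes_csv) || is.null(intensity_csvs))
      stop("config needs either a `simulate` block or input paths ",
           "(`phenotypes_csv` + `intensity_csvs`)", call. = FALSE)
    paths <- c(phenotypes_csv, unlist(intensity_csvs))
    miss <- paths[!file.exists(paths)]
    if (length(miss))
      stop("input file(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
  } else stopifnot(inherits(simulate, "cohort_config"))
  structure(list(simulate = simulate, phenotypes_csv = phenotypes_csv,
                 intensity_csvs = intensity_csvs,
                 vip_threshold = vip_threshold, n_orth = n_orth,
                 k_folds = k_folds, scaling = scaling,
                 covariate_preset = covariate_preset,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the complete analysis pipeline
#'
#' Executes cohort input (simulation or CSV), normalization, the four
#' OPLS-DA models with cross-validated Q2, DM intersection and shape
#' classification, maternal-cord correlations and clinical-panel
#' correlations (Models 1 and 2) for the classified metabolites, and the
#' group summary table. All outputs are written to `config$out_dir` as CSV
#' and JSON, together with `run_manifest.json`; given the same config and
#' seed the output tree is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (!is.null(config$simulate)) {
    generate_cohort(config$simulate)
  } else {
    mats <- lapply(names(config$intensity_csvs), function(comp) {
      ms <- config$intensity_csvs[[comp]]
      out <- lapply(names(ms), function(m)
        read_intensity_csv(ms[[m]], compartment = comp, mode = m))
      names(out) <- names(ms)
      out
    })
    names(mats) <- names(config$intensity_csvs)
    list(phenotypes = utils::read.csv(config$phenotypes_csv,
                                      stringsAsFactors = TRUE),
         matrices = mats, truth = NULL)
  }
  phen <- cohort$phenotypes
  groups <- factor(as.character(phen$group), levels = c("SGA", "AGA", "LGA"))

  disc <- discover_shapes(cohort$matrices, groups,
                          vip_threshold = config$vip_threshold,
                          n_orth = config$n_orth, scaling = config$scaling,
                          cv = TRUE, k_folds = config$k_folds,
                          cv_seed = config$seed)

  # Z-scored merged matrices ordered SGA/AGA/LGA for heatmap-style export
  merged_raw <- lapply(cohort$matrices, .merge_all)
  ord <- order(groups)
  z_export <- lapply(merged_raw, function(m) {
    z <- suppressWarnings(znormalize(impute_missing(m, "half-min")))
    z$values <- z$values[ord, , drop = FALSE]
    z
  })

  called <- disc$shapes$metabolite_id[!is.na(disc$shapes$label) &
                                        disc$shapes$label != "none"]
  mc_cor <- maternal_cord_correlation(merged_raw$maternal, merged_raw$cord,
                                      ids = if (length(called)) called else NULL)
  clin_vars <- c("prepreg_bmi", "weight_gain", "fbg", "hdl_c", "ldl_c",
                 "ffa", "leptin", "adiponectin", "hcy")
  clin_vars <- intersect(clin_vars, names(phen))
  assoc_tabs <- list()
  if (length(called) && length(clin_vars)) {
    for (mod in 1:2)
      assoc_tabs[[mod]] <- correlate_panel(
        impute_missing(merged_raw$maternal, "half-min"), phen,
        metabolite_ids = called, variables = clin_vars, model = mod,
        covariates = model2_covariates(config$covariate_preset))
  }
  assoc_tab <- if (length(assoc_tabs)) do.call(rbind, assoc_tabs) else NULL

  summary_tab <- summarize_cohort(phen)

  od <- config$out_dir
  if (!is.null(config$simulate)) write_cohort(cohort, file.path(od, "cohort"))
  jsonlite::write_json(
    c(disc$dm_sets, list(threshold = config$vip_threshold)),
    file.path(od, "dm_sets.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(disc$venn$regions, file.path(od, "venn_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(disc$fold_changes, file.path(od, "fold_changes.csv"),
                   row.names = FALSE)
  utils::write.csv(disc$shapes, file.path(od, "shape_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(disc$models, file.path(od, "model_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(mc_cor, file.path(od, "maternal_cord_correlations.csv"),
                   row.names = FALSE)
  if (!is.null(assoc_tab))
    utils::write.csv(assoc_tab, file.path(od, "clinical_correlations.csv"),
                     row.names = FALSE)
  utils::write.csv(summary_tab, file.path(od, "cohort_summary.csv"),
                   row.names = FALSE)
  for (comp in names(z_export))
    write_intensity_csv(z_export[[comp]],
                        file.path(od, sprintf("zscores_%s_ordered.csv", comp)))

  manifest <- list(
    package = "dyadmet",
    version = as.character(utils::packageVersion("dyadmet")),
    seed = config$seed,
    vip_threshold = config$vip_threshold, n_orth = config$n_orth,
    k_folds = config$k_folds, scaling = config$scaling,
    covariate_preset = config$covariate_preset,
    simulated = !is.null(config$simulate),
    n_dyads = nrow(phen),
    stage_counts = list(
      dm_per_comparison = as.list(disc$venn$sizes),
      four_way_intersection = length(disc$venn$intersection),
      shape_calls = as.list(table(disc$shapes$label)),
      assoc_records = if (is.null(assoc_tab)) 0L else nrow(assoc_tab),
      summary_rows = nrow(summary_tab)))
  jsonlite::write_json(manifest, file.path(od, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, discovery = disc, maternal_cord = mc_cor,
                 associations = assoc_tab, summary = summary_tab,
                 manifest = manifest, out_dir = od))
}
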