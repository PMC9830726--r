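# merge all modes of one compartment into a mode-tagged feature space;
# single-mode compartments still get tagged ids for a uniform id space
.merge_all <- function(comp) {
  if (length(comp) > 1L) return(Reduce(merge_modes, comp))
  m <- comp[[1L]]
  colnames(m$values) <- paste0(m$mode, ":", colnames(m$values))
  m$mode <- "merged"
  m
}

#' Run the full differential-metabolite shape-discovery chain
#'
#' Executes, per compartment, the two two-group OPLS-DA models (SGA vs AGA
#' and LGA vs AGA) on the mode-merged intensity matrix, selects differential
#' metabolites by VIP, intersects the four DM sets, computes the four fold
#' changes for the intersection, and classifies each candidate metabolite as
#' U-shaped, line-shaped or neither.
#'
#' Positive- and negative-mode features enter as independent, mode-tagged
#' variables; models are fit on unit-variance-scaled data (scaling applied
#' inside the fit, to the samples of each comparison); fold changes use the
#' raw intensities.
#'
#' @param matrices Nested list `matrices[[compartment]][[mode]]` of raw
#'   [intensity_matrix] objects, as produced by [generate_cohort()];
#'   compartments `maternal` and `cord`.
#' @param groups Factor of birthweight groups (levels SGA, AGA, LGA) aligned
#'   with the matrix rows.
#' @param vip_threshold VIP cut-off for DM selection (default 1).
#' @param n_orth Orthogonal components per OPLS-DA model (default 1).
#' @param scaling Column scaling inside the models (default `"uv"`).
#' @param concordance Compartment-agreement rule for [classify_shape()].
#' @param cv If `TRUE`, attach cross-validated `Q2` to each model
#'   (`k_folds`, `cv_seed`).
#' @param k_folds,cv_seed Cross-validation settings when `cv = TRUE`.
#' @return A list with `dm_sets` (the four id vectors), `venn`
#'   (from [intersect_dms()]), `fold_changes`, `shapes` (the
#'   [classify_shape()] table for the 4-way intersection), and `models`
#'   (per-comparison `R2X`, `R2Y`, `Q2`, number selected).
#' @export
discover_shapes <- function(matrices, groups, vip_threshold = 1, n_orth = 1L,
                            scaling = "uv", concordance = "both",
                            cv = FALSE, k_folds = 7L, cv_seed = 1L) {
  groups <- factor(as.character(groups), levels = c("SGA", "AGA", "LGA"))
  merged <- lapply(matrices, .merge_all)

  dm_sets <- list()
  model_summary <- list()
  for (comp in c("maternal", "cord")) {
    mm <- impute_missing(merged[[comp]], "half-min")
    for (cmp in c("SGAvAGA", "LGAvAGA")) {
      gpair <- if (cmp == "SGAvAGA") c("SGA", "AGA") else c("LGA", "AGA")
      sel <- groups %in% gpair
      ysub <- factor(as.character(groups[sel]), levels = gpair)
      Xsub <- mm$values[sel, , drop = FALSE]
      fit <- fit_oplsda(Xsub, ysub, n_orth = n_orth, scaling = scaling)
      if (cv) {
        cvres <- cross_validate(Xsub, ysub,
                                list(method = "oplsda", n_orth = n_orth,
                                     scaling = scaling),
                                k_folds = k_folds, seed = cv_seed)
        fit$Q2 <- cvres$Q2
      }
      ids <- select_dms(vip(fit), vip_threshold)
      key <- paste0(cmp, "_", comp)
      dm_sets[[key]] <- ids
      model_summary[[key]] <- data.frame(comparison = key, R2X = fit$R2X,
                                         R2Y = fit$R2Y, Q2 = fit$Q2,
                                         n_selected = length(ids),
                                         stringsAsFactors = FALSE)
    }
  }
  venn <- intersect_dms(dm_sets)
  raw_mat <- merged$maternal
  raw_crd <- merged$cord
  fc <- fold_change_table(raw_mat, raw_crd, groups, ids = venn$intersection)
  shapes <- classify_shape(fc, concordance = concordance)
  list(dm_sets = dm_sets, venn = venn, fold_changes = fc, shapes = shapes,
       models = do.call(rbind, c(model_summary, list(make.row.names = FALSE))),
       vip_threshold = vip_threshold)
}
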