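#' Select differential metabolites by VIP threshold
#'
#' Returns the metabolite ids whose VIP score strictly exceeds `threshold`
#' (default 1): the conventional differential-metabolite (DM) rule for
#' PLS/OPLS models.
#'
#' @param vip_table The `data.frame(metabolite_id, vip)` from [vip()], or a
#'   named numeric vector of VIP scores.
#' @param threshold Positive cut-off; strict inequality is applied.
#' @return Character vector of selected metabolite ids.
#' @export
select_dms <- function(vip_table, threshold = 1) {
  if (is.numeric(vip_table) && !is.null(names(vip_table)))
    vip_table <- data.frame(metabolite_id = names(vip_table),
                            vip = unname(vip_table), stringsAsFactors = FALSE)
  if (!is.data.frame(vip_table) || !all(c("metabolite_id", "vip") %in% names(vip_table)))
    stop("`vip_table` must have columns metabolite_id and vip", call. = FALSE)
  if (nrow(vip_table) == 0L) stop("empty VIP table", call. = FALSE)
  if (!(threshold > 0)) stop("`threshold` must be > 0", call. = FALSE)
  vip_table$metabolite_id[vip_table$vip > threshold]
}

#' The four standard two-group comparisons
#' @keywords internal
.dm_comparisons <- c("SGAvAGA_maternal", "SGAvAGA_cord",
                     "LGAvAGA_maternal", "LGAvAGA_cord")

#' Intersect differential-metabolite sets across the four comparisons
#'
#' Takes the DM sets of the four two-group models (SGA vs AGA and LGA vs AGA,
#' maternal and cord) and computes every region of their 4-set Venn diagram.
#' The 4-way intersection is the candidate set for fold-change shape
#' classification: metabolites perturbed in both the small- and
#' large-birthweight comparison, in both compartments.
#'
#' @param dm_sets Named list of character vectors; names must be
#'   `SGAvAGA_maternal`, `SGAvAGA_cord`, `LGAvAGA_maternal`, `LGAvAGA_cord`.
#' @return A list with `intersection` (ids in all four sets), `regions` (a
#'   `data.frame` with one row per nonempty membership pattern of the Venn
#'   diagram and its count), and `sizes` (per-comparison set sizes).
#' @export
intersect_dms <- function(dm_sets) {
  missing_cmp <- setdiff(.dm_comparisons, names(dm_sets))
  if (length(missing_cmp))
    stop("missing comparison set(s): ", paste(missing_cmp, collapse = ", "),
         call. = FALSE)
  dm_sets <- dm_sets[.dm_comparisons]
  ids <- sort(unique(unlist(dm_sets, use.names = FALSE)))
  member <- vapply(dm_sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, .dm_comparisons))
  pattern <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  all_patterns <- apply(expand.grid(rep(list(0:1), 4L))[-1, 4:1], 1L,
                        paste, collapse = "")
  counts <- table(factor(pattern, levels = all_patterns))
  regions <- data.frame(pattern = names(counts),
                        count = as.integer(counts), stringsAsFactors = FALSE)
  for (i in seq_along(.dm_comparisons))
    regions[[.dm_comparisons[i]]] <- substr(regions$pattern, i, i) == "1"
  inter <- if (length(ids)) ids[rowSums(member) == 4L] else character(0)
  list(intersection = inter, regions = regions,
       sizes = vapply(dm_sets, length, integer(1)))
}

#' Per-metabolite fold change between two groups
#'
#' Ratio of arithmetic group means of raw intensities (numerator over
#' denominator group), the scale on which U- and line-shapes are defined.
#' Missing intensities are excluded per metabolite; metabolites whose
#' denominator-group mean is zero (or either group fully missing) get `NA`
#' and are listed in the `"flagged"` attribute.
#'
#' @param raw_matrix A raw (un-normalized) [intensity_matrix].
#' @param groups Factor/character vector of group labels aligned with the
#'   matrix rows.
#' @param numerator_group,denominator_group Group labels to compare.
#' @return `data.frame(metabolite_id, fc)`.
#' @export
fold_change <- function(raw_matrix, groups, numerator_group, denominator_group) {
  stopifnot(inherits(raw_matrix, "intensity_matrix"))
  if (raw_matrix$normalized)
    stop("fold changes are defined on raw intensities, not Z scores", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != nrow(raw_matrix$values))
    stop("`groups` length must match the number of samples", call. = FALSE)
  for (g in c(numerator_group, denominator_group))
    if (sum(groups == g, na.rm = TRUE) < 2L)
      stop("group '", g, "' needs >= 2 samples", call. = FALSE)
  num <- colMeans(raw_matrix$values[groups == numerator_group, , drop = FALSE],
                  na.rm = TRUE)
  den <- colMeans(raw_matrix$values[groups == denominator_group, , drop = FALSE],
                  na.rm = TRUE)
  fc <- num / den
  bad <- !is.finite(fc) | is.nan(den) | den == 0
  fc[bad] <- NA_real_
  out <- data.frame(metabolite_id = colnames(raw_matrix$values), fc = unname(fc),
                    stringsAsFactors = FALSE)
  attr(out, "flagged") <- out$metabolite_id[bad]
  out
}

# per-compartment label from the (FC_SGA, FC_LGA) pair; any FC exactly 1
# (or missing) falls outside the strict inequalities and yields "none"
.shape_one <- function(fc_sga, fc_lga) {
  if (is.na(fc_sga) || is.na(fc_lga)) return(NA_character_)
  if (fc_sga > 1 && fc_lga > 1) return("U_up")
  if (fc_sga < 1 && fc_lga < 1) return("U_down")
  if (fc_sga < 1 && fc_lga > 1) return("line_up")
  if (fc_sga > 1 && fc_lga < 1) return("line_down")
  "none"
}

#' Classify metabolites as U-shaped or line-shaped
#'
#' Applies the fold-change shape rules per compartment and requires the
#' maternal and cord labels to agree:
#' * both `FC(SGA/AGA) > 1` and `FC(LGA/AGA) > 1` — `U_up` (elevated at both
#'   birthweight extremes);
#' * both `< 1` — `U_down`;
#' * `FC(SGA/AGA) < 1` and `FC(LGA/AGA) > 1` — `line_up` (monotone increase
#'   across SGA, AGA, LGA);
#' * `FC(SGA/AGA) > 1` and `FC(LGA/AGA) < 1` — `line_down`;
#' * any fold change exactly 1, or discordant compartments — `none`.
#'
#' Metabolites with a missing fold change cannot be classified and are
#' returned with `label = NA` and `classifiable = FALSE` rather than dropped.
#'
#' @param fc A `data.frame` with columns `metabolite_id`,
#'   `fc_sga_maternal`, `fc_lga_maternal`, `fc_sga_cord`, `fc_lga_cord`
#'   (see [fold_change_table()]).
#' @param concordance `"both"` (default) requires maternal and cord
#'   agreement; `"maternal"` uses the maternal label alone (sensitivity
#'   analysis).
#' @return `data.frame(metabolite_id, label, maternal_label, cord_label,
#'   classifiable)` plus the four input fold changes.
#' @export
classify_shape <- function(fc, concordance = c("both", "maternal")) {
  concordance <- match.arg(concordance)
  need <- c("metabolite_id", "fc_sga_maternal", "fc_lga_maternal",
            "fc_sga_cord", "fc_lga_cord")
  if (!all(need %in% names(fc)))
    stop("`fc` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  mat_lab <- mapply(.shape_one, fc$fc_sga_maternal, fc$fc_lga_maternal)
  crd_lab <- mapply(.shape_one, fc$fc_sga_cord, fc$fc_lga_cord)
  lab <- ifelse(is.na(mat_lab) | is.na(crd_lab), NA_character_,
                ifelse(mat_lab == crd_lab, mat_lab, "none"))
  if (concordance == "maternal") lab <- mat_lab
  data.frame(metabolite_id = fc$metabolite_id, label = lab,
             maternal_label = mat_lab, cord_label = crd_lab,
             classifiable = !is.na(lab),
             fc[, setdiff(need, "metabolite_id")],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the four fold changes needed for shape classification
#'
#' Convenience wrapper computing `FC(SGA/AGA)` and `FC(LGA/AGA)` in both
#' compartments for a set of metabolite ids.
#'
#' @param maternal,cord Raw merged [intensity_matrix] objects with identical
#'   sample (dyad) ids.
#' @param groups Group labels aligned with the matrix rows (levels SGA, AGA,
#'   LGA).
#' @param ids Metabolite ids to keep (default: all shared columns).
#' @return A `data.frame` suitable for [classify_shape()].
#' @export
fold_change_table <- function(maternal, cord, groups, ids = NULL) {
  fcs <- list(
    fc_sga_maternal = fold_change(maternal, groups, "SGA", "AGA"),
    fc_lga_maternal = fold_change(maternal, groups, "LGA", "AGA"),
    fc_sga_cord = fold_change(cord, groups, "SGA", "AGA"),
    fc_lga_cord = fold_change(cord, groups, "LGA", "AGA"))
  if (is.null(ids))
    ids <- intersect(fcs[[1]]$metabolite_id, fcs[[3]]$metabolite_id)
  out <- data.frame(metabolite_id = ids, stringsAsFactors = FALSE)
  for (nm in names(fcs))
    out[[nm]] <- fcs[[nm]]$fc[match(ids, fcs[[nm]]$metabolite_id)]
  out
}
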