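#' Spearman correlation with t-approximation p value
#'
#' Rank correlation on pairwise-complete observations, average ranks for
#' ties, two-sided p from the t approximation
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with \eqn{n - 2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p`, `n` (pairs used) and `flag`
#'   (`NA` or a reason the record is undefined, e.g. a constant vector).
#' @export
spearman_assoc <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L)
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "n < 4"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "constant vector"))
  r <- stats::cor(x, y, method = "spearman")
  p <- .t_pvalue(r, df = n - 2L)
  list(r = r, p = p, n = n, flag = NA_character_)
}

.t_pvalue <- function(r, df) {
  if (is.na(r) || df < 1L) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Nonparametric partial correlation: `x`, `y` and the numeric covariates are
#' rank-transformed (average ranks), the two rank vectors are residualized on
#' the covariate design by least squares (intercept included, factors
#' dummy-coded), and the
#' Pearson correlation of the residuals is returned with a two-sided p from
#' t on \eqn{n - 2 - k} degrees of freedom, `k` the number of covariate
#' columns retained. With no covariates this reduces exactly to
#' [spearman_assoc()]. Collinear covariate columns are dropped with a
#' warning. A Pearson variant (no rank transform) is available for
#' comparison.
#'
#' @param x,y Numeric vectors.
#' @param covariates `data.frame` (or matrix) of covariates, or `NULL`.
#' @param method `"spearman"` (rank residuals, default) or `"pearson"`.
#' @return List with `r`, `p`, `n`, `k` (covariate columns used) and `flag`.
#' @export
partial_spearman <- function(x, y, covariates = NULL,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.null(covariates) || (!is.null(ncol(covariates)) && ncol(covariates) == 0L)) {
    # degenerate adjustment: identical to the crude correlation
    out <- if (method == "spearman") spearman_assoc(x, y) else {
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < 4L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        list(r = NA_real_, p = NA_real_, n = n, flag = "degenerate")
      else {
        r <- stats::cor(x[ok], y[ok])
        list(r = r, p = .t_pvalue(r, n - 2L), n = n, flag = NA_character_)
      }
    }
    out$k <- 0L
    return(out)
  }
  covariates <- as.data.frame(covariates)
  ok <- stats::complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]
  covariates <- droplevels(covariates[ok, , drop = FALSE])
  n <- length(x)
  if (method == "spearman") {
    # numeric covariates enter on the rank scale as well, so the adjustment
    # lives entirely in rank space (a covariate equal to y removes it exactly)
    for (j in seq_along(covariates))
      if (is.numeric(covariates[[j]])) covariates[[j]] <- rank(covariates[[j]])
  }
  design <- stats::model.matrix(~ ., data = covariates)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    warning("dropping collinear covariate column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  k <- ncol(design) - 1L
  if (n < k + 4L)
    return(list(r = NA_real_, p = NA_real_, n = n, k = k,
                flag = sprintf("n = %d < k + 4 = %d", n, k + 4L)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, k = k, flag = "constant vector"))
  xr <- if (method == "spearman") rank(x) else x
  yr <- if (method == "spearman") rank(y) else y
  rx <- qr.resid(qrd, xr)
  ry <- qr.resid(qrd, yr)
  if (stats::sd(rx) < 1e-10 * stats::sd(xr) ||
      stats::sd(ry) < 1e-10 * stats::sd(yr))
    return(list(r = 0, p = 1, n = n, k = k,
                flag = "variable fully explained by covariates"))
  r <- stats::cor(rx, ry)
  list(r = r, p = .t_pvalue(r, df = n - 2L - k), n = n, k = k,
       flag = NA_character_)
}

#' Covariate presets for adjusted correlations
#'
#' `"table"` — maternal age, parity, GDM, gestational age, newborn sex (the
#' footnote preset); `"methods"` — the same without GDM. Both presets ship
#' because published descriptions of adjusted models commonly differ between
#' methods text and table footnotes; neither is privileged.
#'
#' @param preset `"table"` or `"methods"`.
#' @return Character vector of phenotype column names.
#' @export
model2_covariates <- function(preset = c("table", "methods")) {
  preset <- match.arg(preset)
  base <- c("maternal_age", "parity", "gestational_age", "newborn_sex")
  if (preset == "table") c(base[1:2], "gdm", base[3:4]) else base
}

#' Correlate metabolites with clinical variables
#'
#' One record per (metabolite, clinical variable): Model 1 is the crude
#' Spearman correlation; Model 2 is the covariate-adjusted partial Spearman
#' correlation with the configured covariate list. No multiple-testing
#' correction is applied (each record is its own two-sided test at
#' alpha = 0.05); a Benjamini-Hochberg FDR column is appended for
#' convenience.
#'
#' @param matrix An [intensity_matrix] whose sample ids are dyad ids.
#' @param phenotypes The dyad phenotype `data.frame` (column `dyad_id`).
#' @param metabolite_ids Metabolites to test (default: all columns).
#' @param variables Clinical variable names to test against.
#' @param model 1 (crude) or 2 (adjusted).
#' @param covariates Covariate names for Model 2 (default
#'   `model2_covariates("table")`).
#' @return `data.frame` with one row per record: `metabolite_id`, `variable`,
#'   `compartment`, `model`, `covariates`, `r`, `p`, `n`, `flag`, `fdr`.
#' @export
correlate_panel <- function(matrix, phenotypes, metabolite_ids = NULL,
                            variables, model = 1L,
                            covariates = model2_covariates("table")) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (is.null(metabolite_ids)) metabolite_ids <- colnames(matrix$values)
  bad_m <- setdiff(metabolite_ids, colnames(matrix$values))
  if (length(bad_m))
    stop("unknown metabolite id(s): ", paste(utils::head(bad_m, 5), collapse = ", "),
         call. = FALSE)
  bad_v <- setdiff(variables, names(phenotypes))
  if (length(bad_v))
    stop("unknown variable(s): ", paste(bad_v, collapse = ", "),
         "; valid names: ", paste(setdiff(names(phenotypes), c("dyad_id", "group")),
                                  collapse = ", "), call. = FALSE)
  if (model == 2L) {
    bad_c <- setdiff(covariates, names(phenotypes))
    if (length(bad_c))
      stop("unknown covariate(s): ", paste(bad_c, collapse = ", "), call. = FALSE)
  }
  idx <- match(rownames(matrix$values), phenotypes$dyad_id)
  if (anyNA(idx))
    stop("sample ids absent from the phenotype table: ",
         paste(utils::head(rownames(matrix$values)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  ph <- phenotypes[idx, , drop = FALSE]
  rows <- vector("list", length(metabolite_ids) * length(variables))
  i <- 0L
  for (m in metabolite_ids) {
    xv <- matrix$values[, m]
    for (v in variables) {
      yv <- as.numeric(ph[[v]])
      res <- if (model == 1L) {
        r1 <- spearman_assoc(xv, yv); r1$k <- 0L; r1
      } else partial_spearman(xv, yv, ph[, covariates, drop = FALSE])
      i <- i + 1L
      rows[[i]] <- data.frame(metabolite_id = m, variable = v,
                              compartment = matrix$compartment,
                              model = model,
                              covariates = if (model == 2L)
                                paste(covariates, collapse = "+") else "",
                              r = res$r, p = res$p, n = res$n,
                              flag = res$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Maternal-cord correlation of metabolite abundance
#'
#' Per-metabolite Spearman correlation between the maternal and cord
#' abundance across dyads — the "placental transfer" association.
#'
#' @param maternal,cord Raw [intensity_matrix] objects whose sample ids are
#'   the dyad ids; the dyad sets must match.
#' @param ids Metabolite ids (default: columns shared by both matrices).
#' @return `data.frame(metabolite_id, r, p, n, flag)`.
#' @export
maternal_cord_correlation <- function(maternal, cord, ids = NULL) {
  stopifnot(inherits(maternal, "intensity_matrix"),
            inherits(cord, "intensity_matrix"))
  dm <- rownames(maternal$values); dc <- rownames(cord$values)
  if (!setequal(dm, dc) || length(dm) != length(dc))
    stop("unmatched dyads between compartments: ",
         paste(c(setdiff(dm, dc), setdiff(dc, dm)), collapse = ", "),
         call. = FALSE)
  cord_v <- cord$values[dm, , drop = FALSE]
  if (is.null(ids))
    ids <- intersect(colnames(maternal$values), colnames(cord_v))
  rows <- lapply(ids, function(m) {
    res <- spearman_assoc(maternal$values[, m], cord_v[, m])
    data.frame(metabolite_id = m, r = res$r, p = res$p, n = res$n,
               flag = res$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
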