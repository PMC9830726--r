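#' Classical one-way ANOVA
#'
#' Fixed-effects one-way analysis of variance across two or more groups,
#' with the p value from the F distribution on (k - 1, N - k) degrees of
#' freedom. Wraps `stats::oneway.test(var.equal = TRUE)`.
#'
#' @param groups List of numeric vectors, one per group (each n >= 2).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  ns <- vapply(groups, function(g) sum(!is.na(g)), integer(1))
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), times = lengths(groups)))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df_between = unname(fit$parameter[1L]),
       df_within = unname(fit$parameter[2L]))
}

#' One-way ANOVA from printed summary statistics
#'
#' Reconstructs the F test from per-group means, SDs and sizes — the only
#' route available when a publication prints "mean (SD)" but the raw data
#' are unavailable. Between-group sum of squares is rebuilt from the means
#' and sizes, within-group from \eqn{\sum (n_i - 1) sd_i^2}. With
#' full-precision summaries of actual data this reproduces [anova_oneway()]
#' exactly; with printed 1-decimal summaries, third-decimal shifts in p are
#' expected.
#'
#' @param means,sds,ns Equal-length numeric vectors of per-group mean, SD and
#'   size (each `ns >= 2`, each `sds > 0`).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @examples
#' # prepregnancy BMI example: p rounds to 0.03
#' anova_from_summary(c(22.4, 23.4, 25.1), c(3.4, 3.5, 2.6), c(16, 28, 23))
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (length(sds) != k || length(ns) != k || k < 2L)
    stop("`means`, `sds`, `ns` must be equal-length vectors (k >= 2)", call. = FALSE)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (any(sds <= 0)) stop("every group SD must be > 0", call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df1 <- k - 1L; df2 <- N - k
  Fv <- (ss_between / df1) / (ss_within / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}

# enumerate all nonnegative integer tables with the given margins, calling
# `visit(cells)` for each; aborts via error once `budget` tables are exceeded
.enumerate_tables <- function(row_sums, col_sums, budget, visit) {
  r <- length(row_sums); cc <- length(col_sums)
  count <- 0L
  cells <- integer(r * cc)
  rec <- function(i, j, row_rem, col_rem) {
    if (i == r) {
      # last row forced by the column remainders
      if (any(col_rem < 0L)) return(invisible())
      cells[((r - 1L) * cc + 1L):(r * cc)] <<- col_rem
      count <<- count + 1L
      if (count > budget)
        stop("enumeration budget exceeded; use monte_carlo = TRUE", call. = FALSE)
      visit(cells)
      return(invisible())
    }
    if (j == cc) {
      # last cell of the row forced by the row remainder
      v <- row_rem
      if (v < 0L || v > col_rem[cc]) return(invisible())
      cells[(i - 1L) * cc + cc] <<- v
      col_rem[cc] <- col_rem[cc] - v
      rec(i + 1L, 1L, row_sums[i + 1L], col_rem)
      return(invisible())
    }
    for (v in 0:min(row_rem, col_rem[j])) {
      cells[(i - 1L) * cc + j] <<- v
      cr <- col_rem; cr[j] <- cr[j] - v
      rec(i, j + 1L, row_rem - v, cr)
    }
  }
  rec(1L, 1L, row_sums[1L], col_sums)
  invisible(count)
}

#' Fisher-Freeman-Halton exact test for an r x c table
#'
#' Exact conditional test of independence for a contingency table of any
#' dimension: under fixed margins, the p value is the total (multivariate
#' hypergeometric) probability of all tables whose probability does not
#' exceed that of the observed table, with a relative tolerance of 1e-12 for
#' probability ties. Probabilities are accumulated on the log scale
#' (log-factorials) to avoid overflow. On 2 x 2 tables this is the classical
#' two-sided Fisher test with the probability-ordering definition.
#'
#' Full enumeration is attempted up to `budget` candidate tables; beyond
#' that, set `monte_carlo = TRUE` to estimate the p value from seeded random
#' tables with the observed margins (Patefield's algorithm via
#' `stats::r2dtable`).
#'
#' @param table Matrix of nonnegative integer counts.
#' @param budget Maximum number of candidate tables to enumerate.
#' @param monte_carlo Use Monte-Carlo estimation instead of enumeration.
#' @param B Number of Monte-Carlo tables.
#' @param seed Seed for the Monte-Carlo mode.
#' @return The exact (or estimated) two-sided p value.
#' @examples
#' fisher_exact_rxc(matrix(c(3, 0, 0, 3), 2))  # = 0.1
#' @export
fisher_exact_rxc <- function(table, budget = 1e7, monte_carlo = FALSE,
                             B = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("`table` must hold nonnegative integer counts", call. = FALSE)
  storage.mode(table) <- "integer"
  rs <- rowSums(table); cs <- colSums(table)
  N <- sum(table)
  if (N == 0L) stop("empty table", call. = FALSE)
  # degenerate margins (a single nonempty row or column): only one table exists
  if (sum(rs > 0L) < 2L || sum(cs > 0L) < 2L) return(1)

  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  log_prob <- function(cells) log_const - sum(lgamma(cells + 1))
  lp_obs <- log_prob(as.integer(table))
  tol <- 1e-12 * abs(lp_obs) + 1e-12

  if (monte_carlo) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    sims <- stats::r2dtable(B, rs, cs)
    lp <- vapply(sims, function(tb) log_prob(as.integer(tb)), numeric(1))
    return(mean(lp <= lp_obs + tol))
  }

  acc <- new.env(parent = emptyenv())
  acc$lps <- numeric(0)
  .enumerate_tables(rs, cs, budget, function(cells) {
    lp <- log_prob(cells)
    if (lp <= lp_obs + tol) acc$lps <- c(acc$lps, lp)
  })
  # log-sum-exp over the extreme tables
  m <- max(acc$lps)
  p <- exp(m) * sum(exp(acc$lps - m))
  min(p, 1)
}

.fmt_p <- function(p) ifelse(p < 0.001, "< 0.001", sprintf("%.2f", p))

#' Group summary table with tests
#'
#' Builds a demographics-style summary of a dyad phenotype table: continuous
#' variables as "mean (SD)" per group compared by one-way ANOVA, categorical
#' variables as "n (%)" per level compared by the Fisher-Freeman-Halton
#' exact test. Display rounding: means/SDs and percentages to 1 decimal,
#' p values to 2 decimals with a "< 0.001" floor.
#'
#' @param phenotypes `data.frame` with a `group` column; all other columns
#'   except `dyad_id` are summarized.
#' @param group_col Name of the grouping column.
#' @return `data.frame` with one row per continuous variable or categorical
#'   level: `variable`, `level`, per-group display strings, `test`,
#'   `statistic`, `p`, `p_display`.
#' @export
summarize_cohort <- function(phenotypes, group_col = "group") {
  if (!group_col %in% names(phenotypes))
    stop("grouping column '", group_col, "' not found", call. = FALSE)
  grp <- droplevels(as.factor(phenotypes[[group_col]]))
  lvls <- levels(grp)
  vars <- setdiff(names(phenotypes), c("dyad_id", group_col))
  rows <- list()
  for (v in vars) {
    col <- phenotypes[[v]]
    if (is.numeric(col)) {
      by_g <- split(col, grp)
      disp <- vapply(by_g, function(x)
        sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE)),
        character(1))
      res <- anova_oneway(by_g)
      row <- data.frame(variable = v, level = "", t(disp), test = "anova",
                        statistic = res$F, p = res$p,
                        p_display = .fmt_p(res$p),
                        stringsAsFactors = FALSE, check.names = FALSE)
      rows[[length(rows) + 1L]] <- row
    } else if (is.factor(col) || is.character(col) || is.logical(col)) {
      col <- droplevels(as.factor(col))
      tab <- table(col, grp)
      p <- fisher_exact_rxc(unclass(tab))
      pct <- sweep(tab, 2L, colSums(tab), "/") * 100
      for (lv in rownames(tab)) {
        disp <- sprintf("%d (%.1f)", tab[lv, ], pct[lv, ])
        names(disp) <- lvls
        rows[[length(rows) + 1L]] <-
          data.frame(variable = v, level = lv, t(disp), test = "fisher",
                     statistic = NA_real_, p = p, p_display = .fmt_p(p),
                     stringsAsFactors = FALSE, check.names = FALSE)
      }
    } else {
      warning("skipping variable of unsupported type: ", v, call. = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
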