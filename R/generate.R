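# Per-group phenotype parameters for the default cohort preset.
# Continuous entries are mean/SD per group (SGA, AGA, LGA); categorical
# entries are the probability of the first level per group. Entries marked
# synthetic = TRUE are not part of the published demographic table and carry
# plausible third-trimester reference values instead.
.pheno_params <- function() {
  cont <- list(
    maternal_age     = list(mean = c(31.4, 33.7, 30.9),  sd = c(4.6, 6.7, 5.3),   synthetic = FALSE),
    gestational_age  = list(mean = c(38.7, 38.4, 39.0),  sd = c(1.1, 0.9, 1.1),   synthetic = FALSE),
    prepreg_bmi      = list(mean = c(22.4, 23.4, 25.1),  sd = c(3.4, 3.5, 2.6),   synthetic = FALSE),
    weight_gain      = list(mean = c(14.8, 14.2, 15.5),  sd = c(5.2, 6.0, 5.8),   synthetic = FALSE),
    mean_arterial_pressure = list(mean = c(89.5, 89.2, 89.6), sd = c(10.2, 9.2, 9.7), synthetic = FALSE),
    fbg              = list(mean = c(4.6, 4.7, 4.6),     sd = c(0.7, 0.6, 0.5),   synthetic = FALSE),
    c_peptide        = list(mean = c(2.7, 2.2, 2.3),     sd = c(2.3, 0.6, 0.7),   synthetic = FALSE),
    insulin          = list(mean = c(10.7, 11.8, 13.7),  sd = c(6.8, 3.8, 5.6),   synthetic = FALSE),
    leptin           = list(mean = c(644.9, 413.5, 518.5), sd = c(494.1, 311.1, 391.8), synthetic = FALSE),
    adiponectin      = list(mean = c(6135.8, 6908.0, 6641.8), sd = c(3230.1, 5258.9, 393.2), synthetic = FALSE),
    hba1c            = list(mean = c(5.3, 5.3, 5.4),     sd = c(0.4, 0.4, 0.4),   synthetic = TRUE),
    hdl_c            = list(mean = c(1.9, 1.9, 1.6),     sd = c(0.4, 0.4, 0.4),   synthetic = TRUE),
    ldl_c            = list(mean = c(3.5, 3.5, 3.5),     sd = c(0.9, 0.9, 0.9),   synthetic = TRUE),
    ffa              = list(mean = c(0.5, 0.5, 0.5),     sd = c(0.2, 0.2, 0.2),   synthetic = TRUE),
    hcy              = list(mean = c(6.5, 6.5, 6.5),     sd = c(1.8, 1.8, 1.8),   synthetic = TRUE),
    birthweight      = list(mean = c(2739.4, 3300.4, 4097.0), sd = c(250.7, 133.2, 238.2), synthetic = FALSE),
    cord_glucose     = list(mean = c(4.4, 4.5, 4.4),     sd = c(1.3, 1.6, 2.1),   synthetic = FALSE),
    cord_c_peptide   = list(mean = c(0.6, 1.1, 1.4),     sd = c(0.2, 1.3, 0.9),   synthetic = FALSE),
    cord_insulin     = list(mean = c(4.2, 6.9, 14.9),    sd = c(2.2, 3.9, 21.1),  synthetic = FALSE),
    cord_leptin      = list(mean = c(43.7, 118.7, 355.6), sd = c(42.8, 203.5, 531.5), synthetic = FALSE),
    cord_adiponectin = list(mean = c(26221.2, 27014.2, 28995.6), sd = c(8062.6, 10613.8, 9760.0), synthetic = FALSE)
  )
  cat_ <- list(
    parity      = list(levels = c("first", "subsequent"), p_first = c(11/16, 8/28, 14/23)),
    newborn_sex = list(levels = c("male", "female"),      p_first = c(12/16, 15/28, 14/23)),
    gdm         = list(levels = c("yes", "no"),           p_first = c(8/16, 18/28, 13/23))
  )
  list(continuous = cont, categorical = cat_)
}

.generate_phenotypes_impl <- function(config) {
  gs <- config$group_sizes
  n <- sum(gs)
  group <- factor(rep(c("SGA", "AGA", "LGA"), times = gs),
                  levels = c("SGA", "AGA", "LGA"))
  gi <- as.integer(group)  # 1 = SGA, 2 = AGA, 3 = LGA
  pp <- .pheno_params()
  out <- data.frame(dyad_id = sprintf("D%03d", seq_len(n)), group = group,
                    stringsAsFactors = FALSE)
  for (v in names(pp$categorical)) {
    par <- pp$categorical[[v]]
    first <- stats::rbinom(n, 1L, par$p_first[gi]) == 1L
    out[[v]] <- factor(ifelse(first, par$levels[1L], par$levels[2L]),
                       levels = par$levels)
  }
  for (v in names(pp$continuous)) {
    par <- pp$continuous[[v]]
    out[[v]] <- stats::rnorm(n, mean = par$mean[gi],
                             sd = par$sd[gi] * config$pheno_sd_scale)
  }
  out
}

#' Generate the phenotype table of a synthetic dyad cohort
#'
#' Draws one row per mother-offspring dyad: birthweight group, maternal
#' demographics and clinical chemistry, and newborn measurements. Continuous
#' variables are normal with group-specific means and SDs; categorical
#' variables are drawn with the group-specific proportions of the default
#' cohort preset. Phenotypes are mutually independent given the group.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with columns `dyad_id`, `group`, `parity`,
#'   `newborn_sex`, `gdm` and the continuous clinical panel.
#' @export
generate_phenotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  .generate_phenotypes_impl(config)
}

# effect of `class` in each group (SGA, AGA, LGA), natural-log units
.class_effects <- function(class, delta_u, delta_line) {
  switch(class,
         U_up      = c(delta_u, 0, delta_u),
         U_down    = c(-delta_u, 0, -delta_u),
         line_up   = delta_line * (c(0, 1, 2) - 1),
         line_down = -delta_line * (c(0, 1, 2) - 1),
         null      = c(0, 0, 0),
         stop("unknown metabolite class: ", class))
}

# realized signed effect size recorded in the ground truth (log units):
# the U deviation for U classes, the per-step slope for line classes
.class_effect_size <- function(class, delta_u, delta_line) {
  switch(class,
         U_up = delta_u, U_down = -delta_u,
         line_up = delta_line, line_down = -delta_line,
         null = 0)
}

#' Generate a complete synthetic dyad cohort
#'
#' Produces a phenotype table, paired maternal and cord intensity matrices
#' (one per requested ionization mode) and a ground-truth table recording the
#' planted class and effect size of every metabolite.
#'
#' The log intensity of metabolite \eqn{j} in dyad \eqn{i}, compartment
#' \eqn{c}, is
#' \deqn{\log I_{ijc} = b_j + e_j(g_i) + \lambda u_{ij} + \varepsilon_{ijc},}
#' with baseline \eqn{b_j \sim N(\mu_b, \sigma_b^2)}, group effect
#' \eqn{e_j(g)} determined by the planted class, a per-dyad latent
#' \eqn{u_{ij} \sim N(0,1)} shared between compartments with loading
#' \eqn{\lambda = \sigma\sqrt{\rho}}, and independent residuals with SD
#' \eqn{\sigma\sqrt{1-\rho}}. Exported intensities are
#' \eqn{\exp(\log I)}; missing cells are inserted completely at random at
#' `missing_rate`.
#'
#' @param config A [cohort_config()].
#' @return A list with components
#'   \describe{
#'     \item{phenotypes}{the dyad phenotype `data.frame`,}
#'     \item{matrices}{nested list `matrices[[compartment]][[mode]]` of
#'       [intensity_matrix] objects (`compartment` in `maternal`, `cord`),}
#'     \item{truth}{`data.frame(metabolite_id, class, effect, mode)` — the
#'       planted ground truth.}
#'   }
#' @examples
#' cfg <- cohort_config(n_metabolites_per_class = c(U_up = 5, null = 20),
#'                      seed = 7)
#' cohort <- generate_cohort(cfg)
#' dim(cohort$matrices$maternal$pos$values)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  phen <- .generate_phenotypes_impl(config)
  gs <- config$group_sizes
  n <- sum(gs)
  gi <- as.integer(phen$group)

  n_cls <- config$n_metabolites_per_class
  p <- sum(n_cls)
  classes <- rep(names(n_cls), times = n_cls)
  ids <- sprintf("M%04d", seq_len(p))
  mode_of <- rep(config$modes, length.out = p)  # alternate across modes

  effects <- vapply(classes, .class_effects, numeric(3),
                    delta_u = config$delta_u, delta_line = config$delta_line)
  # discordance: flip the cord effect of a deterministic subset of planted ids
  planted <- which(classes != "null")
  n_flip <- floor(config$discord_frac * length(planted))
  flip <- if (n_flip > 0) planted[seq_len(n_flip)] else integer(0)
  cord_sign <- rep(1, p); cord_sign[flip] <- -1

  baseline <- stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd)
  sig <- config$noise_sigma
  lambda <- sig * sqrt(config$transfer_rho)
  eps_sd <- sig * sqrt(1 - config$transfer_rho)

  u <- matrix(stats::rnorm(n * p), n, p)
  e_mat <- matrix(stats::rnorm(n * p, sd = eps_sd), n, p)
  e_crd <- matrix(stats::rnorm(n * p, sd = eps_sd), n, p)

  eff_mat <- t(effects)[, gi, drop = FALSE]              # p x n
  log_mat <- sweep(t(eff_mat), 2, baseline, "+") + lambda * u + e_mat
  eff_crd <- eff_mat * cord_sign
  log_crd <- sweep(t(eff_crd), 2, baseline, "+") + lambda * u + e_crd

  if (!is.null(config$pheno_links)) {
    for (k in seq_len(nrow(config$pheno_links))) {
      lk <- config$pheno_links[k, ]
      j <- match(lk$metabolite_id, ids)
      if (is.na(j)) stop("pheno_links metabolite_id not found: ", lk$metabolite_id)
      v <- phen[[lk$variable]]
      if (is.null(v)) stop("pheno_links variable not found: ", lk$variable)
      z <- as.numeric(scale(as.numeric(v)))
      log_mat[, j] <- log_mat[, j] + lk$slope * z
      log_crd[, j] <- log_crd[, j] + lk$slope * z
    }
  }

  int_mat <- exp(log_mat)
  int_crd <- exp(log_crd)
  if (config$missing_rate > 0) {
    int_mat[stats::runif(n * p) < config$missing_rate] <- NA_real_
    int_crd[stats::runif(n * p) < config$missing_rate] <- NA_real_
  }
  dimnames(int_mat) <- dimnames(int_crd) <- list(phen$dyad_id, ids)

  matrices <- list()
  for (comp in c("maternal", "cord")) {
    vals <- if (comp == "maternal") int_mat else int_crd
    matrices[[comp]] <- list()
    for (m in config$modes) {
      sel <- mode_of == m
      matrices[[comp]][[m]] <- intensity_matrix(vals[, sel, drop = FALSE],
                                                compartment = comp, mode = m)
    }
  }

  truth <- data.frame(metabolite_id = ids, class = classes,
                      effect = vapply(classes, .class_effect_size, numeric(1),
                                      delta_u = config$delta_u,
                                      delta_line = config$delta_line),
                      mode = mode_of, stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(phenotypes = phen, matrices = matrices, truth = truth)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `phenotypes.csv`, one `intensity_<compartment>_<mode>.csv` per
#' matrix (first column the sample id, remaining columns metabolite ids, empty
#' cell = missing) and `truth.csv` into `dir`.
#'
#' @param cohort The list returned by [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  for (comp in names(cohort$matrices))
    for (m in names(cohort$matrices[[comp]]))
      write_intensity_csv(cohort$matrices[[comp]][[m]],
                          file.path(dir, sprintf("intensity_%s_%s.csv", comp, m)))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
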