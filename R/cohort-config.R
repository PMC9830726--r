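#' Configuration for a synthetic mother-offspring dyad cohort
#'
#' Bundles every parameter of the synthetic-cohort generator. The defaults
#' reproduce the design of the motivating cohort: 16 small-for-gestational-age
#' (SGA), 28 appropriate (AGA) and 23 large (LGA) dyads, with paired maternal
#' and cord-plasma metabolite intensities measured in positive and negative
#' ionization modes.
#'
#' Metabolites are planted in five classes. "U" classes deviate by
#' `delta_u` (natural-log units) in the same direction in both SGA and LGA
#' relative to AGA; "line" classes change monotonically across the
#' SGA -> AGA -> LGA ordering by `delta_line` per group step; "null"
#' metabolites carry no group effect. Effects are applied identically in the
#' maternal and cord compartments unless `discord_frac > 0`, in which case
#' that fraction of planted metabolites has its cord-compartment effect
#' sign-flipped (exercising the concordance requirement of the shape
#' classifier).
#'
#' Maternal-cord coupling ("placental transfer") is modelled through a shared
#' per-dyad, per-metabolite latent factor. The latent loading is
#' `noise_sigma * sqrt(transfer_rho)` and the compartment-specific residual SD
#' is `noise_sigma * sqrt(1 - transfer_rho)`, so the population Pearson
#' correlation of log intensities between compartments equals `transfer_rho`
#' while the marginal log-scale SD stays at `noise_sigma`.
#'
#' @param group_sizes Named integer vector `c(SGA, AGA, LGA)` of dyads per
#'   birthweight group.
#' @param n_metabolites_per_class Named integer vector with entries
#'   `U_up`, `U_down`, `line_up`, `line_down`, `null`.
#' @param delta_u Log-scale effect magnitude for U classes (natural-log
#'   units; `log(2)` means a two-fold change in SGA and LGA vs AGA).
#' @param delta_line Log-scale per-group-step effect for line classes.
#' @param transfer_rho Target maternal-cord Pearson correlation of log
#'   intensities, in `[0, 1)`.
#' @param noise_sigma Log-scale SD of a metabolite within a group (> 0).
#' @param modes Character subset of `c("pos", "neg")`; metabolites are split
#'   alternately across the requested ionization modes.
#' @param missing_rate Fraction of intensity cells set missing completely at
#'   random, in `[0, 1)`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param baseline_log_mean,baseline_log_sd Mean and SD of per-metabolite
#'   baseline log abundance (log-normal intensity model).
#' @param discord_frac Fraction of planted (non-null) metabolites whose cord
#'   effect is sign-flipped, in `[0, 1]`.
#' @param pheno_links Optional `data.frame(metabolite_id, variable, slope)`
#'   adding `slope * z(phenotype)` to the metabolite's log intensity in both
#'   compartments — used to plant metabolite-phenotype associations.
#' @param pheno_sd_scale Multiplier on all phenotype SDs (0 gives every dyad
#'   its group mean; useful for deterministic checks).
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [generate_phenotypes()]
#' @export
cohort_config <- function(group_sizes = c(SGA = 16L, AGA = 28L, LGA = 23L),
                          n_metabolites_per_class = c(U_up = 30L, U_down = 30L,
                                                      line_up = 30L, line_down = 30L,
                                                      null = 200L),
                          delta_u = log(2),
                          delta_line = log(2),
                          transfer_rho = 0.5,
                          noise_sigma = 0.4,
                          modes = c("pos", "neg"),
                          missing_rate = 0,
                          seed = 1L,
                          baseline_log_mean = 12,
                          baseline_log_sd = 1,
                          discord_frac = 0,
                          pheno_links = NULL,
                          pheno_sd_scale = 1) {
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != 3L)
    stop("`group_sizes` must be a triple (SGA, AGA, LGA)", call. = FALSE)
  names(group_sizes) <- c("SGA", "AGA", "LGA")

  classes <- c("U_up", "U_down", "line_up", "line_down", "null")
  if (is.null(names(n_metabolites_per_class)) ||
      !all(names(n_metabolites_per_class) %in% classes))
    stop("`n_metabolites_per_class` must be named with classes among: ",
         paste(classes, collapse = ", "), call. = FALSE)
  # accept partial maps; unmentioned classes default to zero
  n_cls <- rep(0L, 5L); names(n_cls) <- classes
  n_cls[names(n_metabolites_per_class)] <- as.integer(n_metabolites_per_class)

  if (any(n_cls < 0L)) stop("metabolite counts must be >= 0", call. = FALSE)
  if (sum(n_cls) == 0L) stop("cohort must contain at least one metabolite", call. = FALSE)
  if (any(group_sizes < 2L))
    stop("each birthweight group needs >= 2 dyads (group statistics undefined below that)",
         call. = FALSE)
  if (sum(group_sizes) < 6L) stop("total cohort size must be >= 6", call. = FALSE)
  if (!(noise_sigma > 0)) stop("`noise_sigma` must be > 0", call. = FALSE)
  if (!(abs(transfer_rho) < 1)) stop("`transfer_rho` must satisfy |rho| < 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  modes <- match.arg(modes, c("pos", "neg"), several.ok = TRUE)
  if (discord_frac < 0 || discord_frac > 1)
    stop("`discord_frac` must lie in [0, 1]", call. = FALSE)
  if (!is.null(pheno_links)) {
    need <- c("metabolite_id", "variable", "slope")
    if (!is.data.frame(pheno_links) || !all(need %in% names(pheno_links)))
      stop("`pheno_links` needs columns metabolite_id, variable, slope", call. = FALSE)
  }

  structure(list(group_sizes = group_sizes,
                 n_metabolites_per_class = n_cls,
                 delta_u = delta_u,
                 delta_line = delta_line,
                 transfer_rho = transfer_rho,
                 noise_sigma = noise_sigma,
                 modes = modes,
                 missing_rate = missing_rate,
                 seed = as.integer(seed),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 discord_frac = discord_frac,
                 pheno_links = pheno_links,
                 pheno_sd_scale = pheno_sd_scale),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic dyad cohort configuration\n")
  cat("  dyads: SGA", x$group_sizes["SGA"], "/ AGA", x$group_sizes["AGA"],
      "/ LGA", x$group_sizes["LGA"], "\n")
  cat("  metabolites:", paste(names(x$n_metabolites_per_class),
                              x$n_metabolites_per_class, collapse = ", "), "\n")
  cat("  delta_u =", signif(x$delta_u, 4), " delta_line =", signif(x$delta_line, 4),
      " sigma =", x$noise_sigma, " transfer rho =", x$transfer_rho, "\n")
  cat("  modes:", paste(x$modes, collapse = "+"),
      " missing rate:", x$missing_rate, " seed:", x$seed, "\n")
  invisible(x)
}
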