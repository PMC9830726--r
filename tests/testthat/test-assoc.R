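test_that("spearman correlation is rank-invariant and handles ties", {
  x <- c(0.2, 1.4, 2.1, 3.9, 5.0, 6.6, 7.1, 8.8)
  expect_equal(spearman_assoc(x, exp(x))$r, 1)
  expect_equal(spearman_assoc(1:5, 5:1)$r, -1)
  expect_equal(spearman_assoc(1:5, 5:1)$p, 0)
  # tie fixture: rank-then-Pearson oracle
  y <- c(3, 3, 1, 7, 5, 9, 2, 8)
  res <- spearman_assoc(x, y)
  expect_equal(res$r, cor(rank(x), rank(y)), tolerance = 1e-12)
  tstat <- res$r * sqrt((8 - 2) / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 6), tolerance = 1e-12)
  # degenerate inputs are flagged, not computed
  expect_equal(spearman_assoc(rep(1, 8), y)$flag, "constant vector")
  expect_equal(spearman_assoc(1:3, 3:1)$flag, "n < 4")
})

test_that("partial correlation reduces to crude with no covariates", {
  set.seed(30)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  crude <- spearman_assoc(x, y)
  part <- partial_spearman(x, y, NULL)
  expect_equal(part$r, crude$r, tolerance = 1e-12)
  expect_equal(part$p, crude$p, tolerance = 1e-12)
  expect_equal(part$k, 0L)
})

test_that("a response equal to a covariate is fully partialled out", {
  set.seed(31)
  z <- rnorm(30)
  x <- rnorm(30)
  res <- partial_spearman(x, z, data.frame(z = z))
  expect_lt(abs(res$r), 1e-8)
  expect_equal(res$flag, "variable fully explained by covariates")
})

test_that("one-covariate adjustment matches the closed-form partial correlation", {
  set.seed(32)
  z <- rnorm(20)
  x <- 0.6 * z + rnorm(20)
  y <- -0.4 * z + rnorm(20)
  res <- partial_spearman(x, y, data.frame(z = z))
  expect_equal(res$r, partial_cor_oracle(x, y, z), tolerance = 1e-10)
  expect_equal(res$k, 1L)
  # p from t on n - 2 - k df
  tstat <- res$r * sqrt((20 - 3) / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 20 - 3), tolerance = 1e-12)
})

test_that("partial correlation is invariant to monotone transforms", {
  set.seed(33)
  z <- rnorm(40); x <- z + rnorm(40); y <- z + rnorm(40)
  a <- partial_spearman(x, y, data.frame(z = z))
  b <- partial_spearman(exp(x), y^3 + 10 * y, data.frame(z = z))
  expect_equal(a$r, b$r, tolerance = 1e-12)
})

test_that("collinear covariates are dropped with a warning", {
  set.seed(34)
  z <- rnorm(25)
  covs <- data.frame(z1 = z, z2 = 2 * z)
  expect_warning(res <- partial_spearman(rnorm(25), rnorm(25), covs),
                 "collinear")
  expect_equal(res$k, 1L)
})

test_that("correlate_panel recovers a planted metabolite-phenotype link", {
  hits <- attn <- logical(10)
  for (s in 1:10) {
    links <- data.frame(metabolite_id = "M0001", variable = "prepreg_bmi",
                        slope = 0.6)
    co <- generate_cohort(cohort_config(
      n_metabolites_per_class = c(null = 5), pheno_links = links,
      modes = "pos", seed = 200 + s))
    m1 <- correlate_panel(co$matrices$maternal$pos, co$phenotypes,
                          metabolite_ids = "M0001",
                          variables = "prepreg_bmi", model = 1)
    hits[s] <- m1$r > 0 & m1$p < 0.05
    # a link routed entirely through a Model-2 covariate attenuates
    links2 <- data.frame(metabolite_id = "M0001", variable = "gestational_age",
                         slope = 0.6)
    co2 <- generate_cohort(cohort_config(
      n_metabolites_per_class = c(null = 5), pheno_links = links2,
      modes = "pos", seed = 300 + s))
    r1 <- correlate_panel(co2$matrices$maternal$pos, co2$phenotypes,
                          metabolite_ids = "M0001",
                          variables = "gestational_age", model = 1)$r
    r2 <- correlate_panel(co2$matrices$maternal$pos, co2$phenotypes,
                          metabolite_ids = "M0001",
                          variables = "gestational_age", model = 2)$r
    attn[s] <- abs(r2) < abs(r1)
  }
  expect_gte(sum(hits), 9)
  expect_true(all(attn))
})

test_that("correlate_panel validates names and reports n per record", {
  co <- tiny_cohort(seed = 40)
  m <- co$matrices$maternal$pos
  expect_error(correlate_panel(m, co$phenotypes, variables = "nonsense"),
               "valid names")
  expect_error(correlate_panel(m, co$phenotypes, metabolite_ids = "XX",
                               variables = "prepreg_bmi"), "unknown metabolite")
  tab <- correlate_panel(m, co$phenotypes,
                         metabolite_ids = colnames(m$values)[1:2],
                         variables = c("prepreg_bmi", "fbg"), model = 2)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$n == nrow(co$phenotypes)))
  expect_true(all(tab$covariates == paste(model2_covariates("table"),
                                          collapse = "+")))
  expect_true(all(abs(tab$r) <= 1, na.rm = TRUE))
})

test_that("maternal-cord correlation is 1 for a copied compartment", {
  m <- random_intensity(12, 4, seed = 41, compartment = "maternal")
  c_ <- intensity_matrix(m$values, "cord")
  res <- maternal_cord_correlation(m, c_)
  expect_true(all(res$r == 1))
  bad <- random_intensity(12, 4, seed = 42, compartment = "cord")
  rownames(bad$values)[1] <- "ZZZ"
  expect_error(maternal_cord_correlation(m, bad), "unmatched")
})

test_that("maternal-cord correlation recovers the planted transfer rho", {
  rs <- vapply(1:3, function(s) {
    co <- generate_cohort(cohort_config(
      n_metabolites_per_class = c(null = 200), transfer_rho = 0.7,
      modes = "pos", seed = 500 + s))
    mean(maternal_cord_correlation(co$matrices$maternal$pos,
                                   co$matrices$cord$pos)$r)
  }, numeric(1))
  expect_equal(mean(rs), 0.7, tolerance = 0.08)
  # independence at rho = 0: signed mean near 0 and mean |r| at its null
  # expectation E|r| ~ sqrt(2/pi)/sqrt(n - 1) (~0.098 at n = 67)
  co0 <- generate_cohort(cohort_config(
    n_metabolites_per_class = c(null = 1000), transfer_rho = 0,
    modes = "pos", seed = 600))
  res0 <- maternal_cord_correlation(co0$matrices$maternal$pos,
                                    co0$matrices$cord$pos)
  expect_lt(abs(mean(res0$r)), 0.02)
  expect_lt(mean(abs(res0$r)), sqrt(2 / pi) / sqrt(66) + 0.01)
})
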