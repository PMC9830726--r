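test_that("cohort generation is deterministic given the seed", {
  a <- tiny_cohort(seed = 42)
  b <- tiny_cohort(seed = 42)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$matrices$maternal$pos$values, b$matrices$maternal$pos$values)
  expect_identical(a$matrices$cord$neg$values, b$matrices$cord$neg$values)
  c_ <- tiny_cohort(seed = 43)
  expect_false(identical(a$matrices$maternal$pos$values,
                         c_$matrices$maternal$pos$values))
})

test_that("default preset reproduces the 16/28/23 design", {
  co <- generate_cohort(cohort_config(seed = 1))
  expect_equal(unname(table(co$phenotypes$group)[c("SGA", "AGA", "LGA")]),
               c(16L, 28L, 23L), ignore_attr = TRUE)
  expect_equal(nrow(co$phenotypes), 67L)
  expect_setequal(names(co$matrices), c("maternal", "cord"))
  expect_setequal(names(co$matrices$maternal), c("pos", "neg"))
  # one class label per metabolite, classes partition the id set
  expect_equal(anyDuplicated(co$truth$metabolite_id), 0L)
  expect_equal(sum(table(co$truth$class)), nrow(co$truth))
})

test_that("all-null effect-free cohort has equal group means up to noise", {
  co <- generate_cohort(cohort_config(
    group_sizes = c(200, 200, 200),
    n_metabolites_per_class = c(null = 40),
    delta_u = 0, delta_line = 0, transfer_rho = 0, modes = "pos", seed = 5))
  lv <- log(co$matrices$maternal$pos$values)
  gm <- apply(lv, 2, function(x) tapply(x, co$phenotypes$group, mean))
  spread <- apply(gm, 2, function(m) diff(range(m)))
  # group means of log intensity differ only by sampling error ~ sigma/sqrt(n)
  expect_lt(max(spread), 4 * 0.4 / sqrt(200) * 2)
})

test_that("planted U_up fold change converges to exp(delta)", {
  fcs <- sapply(1:3, function(s) {
    co <- generate_cohort(cohort_config(
      group_sizes = c(500, 500, 500),
      n_metabolites_per_class = c(U_up = 5, null = 5),
      delta_u = log(1.5), noise_sigma = 0.1, transfer_rho = 0,
      modes = "pos", seed = s))
    fc <- fold_change(co$matrices$maternal$pos, co$phenotypes$group,
                      "SGA", "AGA")
    up <- co$truth$metabolite_id[co$truth$class == "U_up"]
    mean(fc$fc[match(up, fc$metabolite_id)])
  })
  expect_true(all(abs(fcs - 1.5) / 1.5 < 0.02))
})

test_that("line classes step monotonically across SGA/AGA/LGA", {
  co <- generate_cohort(cohort_config(
    group_sizes = c(400, 400, 400),
    n_metabolites_per_class = c(line_up = 5, line_down = 5),
    delta_line = log(2), noise_sigma = 0.2, transfer_rho = 0,
    modes = "pos", seed = 2))
  lv <- log(co$matrices$cord$pos$values)
  gm <- apply(lv, 2, function(x) tapply(x, co$phenotypes$group, mean))
  gm <- gm[c("SGA", "AGA", "LGA"), ]
  up <- co$truth$class == "line_up"
  expect_true(all(diff(gm[, up]) > 0))
  expect_true(all(diff(gm[, !up]) < 0))
  # per-step log difference close to delta_line
  expect_equal(mean(diff(gm[, up])), log(2), tolerance = 0.05)
})

test_that("phenotypes track the preset group parameters", {
  co <- generate_cohort(cohort_config(
    group_sizes = c(2000, 2000, 2000), n_metabolites_per_class = c(null = 1),
    modes = "pos", seed = 9))
  ph <- co$phenotypes
  bw <- tapply(ph$birthweight, ph$group, mean)
  expect_equal(unname(bw["SGA"]), 2739.4, tolerance = 0.01)
  expect_equal(unname(bw["AGA"]), 3300.4, tolerance = 0.01)
  expect_equal(unname(bw["LGA"]), 4097.0, tolerance = 0.01)
  expect_true(bw["SGA"] < bw["AGA"] && bw["AGA"] < bw["LGA"])
  frac_first <- tapply(ph$parity == "first", ph$group, mean)
  expect_equal(unname(frac_first["SGA"]), 11 / 16, tolerance = 0.05)
})

test_that("zero-variance override pins phenotypes at the group mean", {
  co <- generate_cohort(cohort_config(pheno_sd_scale = 0,
                                      n_metabolites_per_class = c(null = 2),
                                      modes = "pos", seed = 3))
  ph <- co$phenotypes
  for (g in c("SGA", "AGA", "LGA"))
    expect_equal(stats::sd(ph$prepreg_bmi[ph$group == g]), 0)
  expect_equal(unique(ph$birthweight[ph$group == "SGA"]), 2739.4)
})

test_that("missingness is MCAR at the requested rate", {
  co <- generate_cohort(cohort_config(
    group_sizes = c(40, 40, 40),
    n_metabolites_per_class = c(null = 100),
    missing_rate = 0.05, modes = "pos", seed = 8))
  v <- co$matrices$maternal$pos$values
  expect_gt(length(v), 1e4)
  expect_lt(abs(mean(is.na(v)) - 0.05), 0.01)
})

test_that("maternal and cord log intensities correlate at transfer_rho", {
  co <- generate_cohort(cohort_config(
    n_metabolites_per_class = c(null = 300), transfer_rho = 0.7,
    modes = "pos", seed = 4))
  m <- log(co$matrices$maternal$pos$values)
  c_ <- log(co$matrices$cord$pos$values)
  rs <- vapply(seq_len(ncol(m)), function(j) cor(m[, j], c_[, j]), numeric(1))
  expect_equal(mean(rs), 0.7, tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_metabolites_per_class = c(null = 0)),
               "at least one metabolite")
  expect_error(cohort_config(group_sizes = c(1, 28, 23)), ">= 2 dyads")
  expect_error(cohort_config(noise_sigma = 0), "noise_sigma")
  expect_error(cohort_config(transfer_rho = 1), "transfer_rho")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
})

test_that("pheno_links plant a metabolite-phenotype association", {
  links <- data.frame(metabolite_id = "M0001", variable = "prepreg_bmi",
                      slope = 0.5)
  co <- generate_cohort(cohort_config(
    n_metabolites_per_class = c(null = 10), pheno_links = links,
    modes = "pos", transfer_rho = 0, seed = 6))
  x <- log(co$matrices$maternal$pos$values[, "M0001"])
  expect_gt(cor(x, co$phenotypes$prepreg_bmi), 0.5)
  x2 <- log(co$matrices$maternal$pos$values[, "M0002"])
  expect_lt(abs(cor(x2, co$phenotypes$prepreg_bmi)), 0.4)
})

test_that("discordant cord effects flip sign for the configured fraction", {
  co <- generate_cohort(cohort_config(
    group_sizes = c(300, 300, 300),
    n_metabolites_per_class = c(U_up = 10, null = 5),
    discord_frac = 0.5, noise_sigma = 0.2, transfer_rho = 0,
    modes = "pos", seed = 7))
  lv_c <- log(co$matrices$cord$pos$values)
  gm <- apply(lv_c, 2, function(x) tapply(x, co$phenotypes$group, mean))
  up <- which(co$truth$class == "U_up")
  dev <- gm["SGA", up] - gm["AGA", up]  # U deviation in cord blood
  expect_equal(sum(dev < 0), 5L)        # half flipped down
  expect_equal(sum(dev > 0), 5L)
})
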