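test_that("a perfect predictor column gives R2Y = 1 at one component", {
  y <- factor(rep(c("A", "B"), each = 10))
  X <- matrix(as.numeric(y == "B"), ncol = 1,
              dimnames = list(NULL, "code"))
  fit <- fit_plsda(X, y, n_components = 1)
  expect_equal(fit$R2Y[1], 1, tolerance = 1e-8)
})

test_that("NIPALS scores match the SVD-based PLS oracle up to sign", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(8:20, 1); p <- sample(5:50, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
    y <- factor(rep_len(c("A", "B", "C"), n))
    A <- 3
    fit <- fit_plsda(X, y, n_components = A)
    Y <- stats::model.matrix(~ y - 1)
    orc <- svd_pls_oracle(X, Y, A)
    for (a in seq_len(A))
      expect_lt(min(max(abs(fit$scores[, a] - orc[, a])),
                    max(abs(fit$scores[, a] + orc[, a]))), 1e-8)
  }
})

test_that("fits are reproducible bit-for-bit with a fixed sign convention", {
  set.seed(2)
  X <- matrix(rnorm(15 * 10), 15, 10, dimnames = list(NULL, paste0("V", 1:10)))
  y <- factor(rep_len(c("A", "B"), 15))
  f1 <- fit_plsda(X, y, 2); f2 <- fit_plsda(X, y, 2)
  expect_identical(f1$scores, f2$scores)
  # largest-magnitude loading element of every component is positive
  for (a in 1:2) expect_gt(f1$P[which.max(abs(f1$P[, a])), a], 0)
  o1 <- fit_oplsda(X, y, 1); o2 <- fit_oplsda(X, y, 1)
  expect_identical(o1$t_pred, o2$t_pred)
})

test_that("model-dimension and response contracts are enforced", {
  set.seed(3)
  X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("V", 1:4)))
  y2 <- factor(rep(c("A", "B"), 3))
  expect_error(fit_plsda(X, y2, n_components = 10), "rank")
  expect_error(fit_plsda(X, factor(rep("A", 6)), 1), "2 levels")
  expect_error(fit_oplsda(X, factor(rep_len(c("A", "B", "C"), 6))), "binary")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_plsda(Xna, y2, 1), "missing")
})

test_that("OPLS-DA with n_orth = 0 degenerates to single-component PLS", {
  set.seed(4)
  X <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(NULL, paste0("V", 1:12)))
  y <- factor(rep(c("A", "B"), each = 10))
  op <- fit_oplsda(X, y, n_orth = 0)
  pl <- fit_plsda(X, y, n_components = 1)
  t_o <- op$t_pred; t_p <- pl$scores[, 1]
  expect_lt(min(max(abs(t_o - t_p)), max(abs(t_o + t_p))), 1e-8)
})

test_that("orthogonal filtering removes a y-orthogonal structured direction", {
  set.seed(5)
  n <- 40; p <- 30
  y <- factor(rep(c("A", "B"), each = n / 2))
  yc <- as.numeric(y == "B") - 0.5
  t_conf <- rnorm(n)
  t_conf <- residuals(lm(t_conf ~ yc))   # exactly y-orthogonal confounder
  w1 <- rnorm(p); w2 <- rnorm(p)
  X <- 0.5 * yc %*% t(w1) + 2 * t_conf %*% t(w2) + matrix(rnorm(n * p, sd = 0.3), n, p)
  colnames(X) <- paste0("V", 1:p)
  fit <- fit_oplsda(X, y, n_orth = 1)
  expect_lt(abs(cor(fit$t_pred, t_conf)), 0.05)
  expect_equal(sum(fit$t_pred * fit$T_orth[, 1]), 0, tolerance = 1e-8)
})

test_that("widely separated groups give near-perfect R2Y", {
  set.seed(6)
  n <- 24
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("V", 1:10)))
  X[, 1:4] <- X[, 1:4] + 5 * (as.numeric(y) - 1)  # +5 sigma cloud separation
  fit <- fit_oplsda(X, y, n_orth = 1)
  expect_gt(fit$R2Y, 0.95)
})

test_that("VIP satisfies its normalization identity and formula", {
  # p = 1: normalization forces VIP = 1
  set.seed(7)
  X1 <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "V1"))
  y <- factor(rep(c("A", "B"), 5))
  expect_equal(vip(fit_oplsda(X1, y, 0))$vip, 1, tolerance = 1e-8)
  # p = 200: sum VIP^2 = 200
  X2 <- matrix(rnorm(20 * 200), 20, 200, dimnames = list(NULL, paste0("V", 1:200)))
  y2 <- factor(rep(c("A", "B"), 10))
  v2 <- vip(fit_oplsda(X2, y2, 1))
  expect_equal(sum(v2$vip^2), 200, tolerance = 1e-6)
  v3 <- vip(fit_plsda(X2, y2, 3))
  expect_equal(mean(v3$vip^2), 1, tolerance = 1e-8)
  # direct spreadsheet-style evaluation of the formula on a small fixture
  X4 <- matrix(c(1.2, 0.8, 2.1, 3.3, 0.5, 1.9,
                 2.2, 1.1, 0.3, 1.8, 2.9, 0.7,
                 0.9, 2.4, 1.5, 0.2, 1.1, 2.8,
                 1.7, 0.6, 2.0, 1.4, 0.8, 1.3), 6, 4)
  colnames(X4) <- paste0("V", 1:4)
  y4 <- factor(rep_len(c("A", "B"), 6))
  fit4 <- fit_plsda(X4, y4, 2)
  expect_equal(vip(fit4)$vip, vip_formula_oracle(fit4$W, fit4$ssy_comp),
               tolerance = 1e-10)
  expect_error(vip(list()), "fitted")
})

test_that("pure-noise models overfit in training but fail cross-validation", {
  q2s <- r2s <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    X <- matrix(rnorm(20 * 50), 20, 50, dimnames = list(NULL, paste0("V", 1:50)))
    y <- factor(rep(c("A", "B"), 10))
    cv <- cross_validate(X, y, list(method = "oplsda", n_orth = 1),
                         k_folds = 7, seed = s)
    r2s[s] <- cv$R2Y; q2s[s] <- cv$Q2
  }
  expect_gt(mean(r2s), 0.8)      # training fit is near-perfect on noise
  expect_lte(mean(q2s), 0.2)     # but predicts nothing
  expect_true(all(q2s <= r2s))   # Q2 never exceeds training R2Y here
})

test_that("cross-validation recognises separable data and is fold-deterministic", {
  set.seed(8)
  n <- 30
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("V", 1:8)))
  X[, 1:4] <- X[, 1:4] + 5 * (as.numeric(y) - 1)  # two clouds, 5 sigma apart
  cv1 <- cross_validate(X, y, list(method = "oplsda", n_orth = 1), 7, seed = 2)
  cv2 <- cross_validate(X, y, list(method = "oplsda", n_orth = 1), 7, seed = 2)
  expect_gt(cv1$Q2, 0.9)
  expect_identical(cv1, cv2)
  expect_false(identical(cv1$folds,
                         cross_validate(X, y, list(method = "oplsda", n_orth = 1),
                                        7, seed = 3)$folds))
})

test_that("leave-one-out Q2 equals an explicit LOO loop", {
  set.seed(9)
  n <- 14
  y <- factor(rep(c("A", "B"), each = 7))
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("V", 1:6)))
  X[, 1] <- X[, 1] + 1.5 * (as.numeric(y) - 1)
  cv <- cross_validate(X, y, list(method = "oplsda", n_orth = 1),
                       k_folds = n, seed = 1)
  yn <- as.numeric(y == "B")
  press <- 0
  for (i in seq_len(n)) {
    m <- fit_oplsda(X[-i, ], y[-i], n_orth = 1)
    press <- press + (yn[i] - as.numeric(predict(m, X[i, , drop = FALSE])))^2
  }
  q2_loo <- 1 - press / sum((yn - mean(yn))^2)
  expect_equal(cv$Q2, unname(q2_loo), tolerance = 1e-10)
})

test_that("permuted labels yield non-positive mean Q2", {
  set.seed(10)
  X <- matrix(rnorm(20 * 30), 20, 30, dimnames = list(NULL, paste0("V", 1:30)))
  y <- factor(rep(c("A", "B"), 10))
  q2s <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    yp <- sample(y)
    cross_validate(X, yp, list(method = "oplsda", n_orth = 1), 7, seed = s)$Q2
  }, numeric(1))
  expect_lte(mean(q2s), 0)
})
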