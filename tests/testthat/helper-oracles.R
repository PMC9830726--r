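# Independent oracles used across the suite. Each is a deliberately
# different computational route from the implementation it checks.

# PLS2 via SVD of the cross-product matrix: the component weight is the first
# left singular vector of X'Y (NIPALS converges to the same dominant
# direction iteratively). Returns scores per component.
svd_pls_oracle <- function(X, Y, n_components) {
  X <- scale(X); Y <- scale(Y, scale = FALSE)
  scores <- matrix(0, nrow(X), n_components)
  for (a in seq_len(n_components)) {
    sv <- svd(crossprod(X, Y))
    w <- sv$u[, 1L]
    t_ <- drop(X %*% w)
    p_ <- drop(crossprod(X, t_)) / sum(t_^2)
    q_ <- drop(crossprod(Y, t_)) / sum(t_^2)
    X <- X - tcrossprod(t_, p_)
    Y <- Y - tcrossprod(t_, q_)
    scores[, a] <- t_
  }
  scores
}

# direct elementwise evaluation of the VIP formula from stored weights,
# written as an explicit double loop (spreadsheet style)
vip_formula_oracle <- function(W, ssy) {
  p <- nrow(W); A <- ncol(W)
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(A)) {
      wnorm <- sqrt(sum(W[, a]^2))
      acc <- acc + ssy[a] * (W[j, a] / wnorm)^2
    }
    out[j] <- sqrt(p * acc / sum(ssy))
  }
  out
}

# textbook first-order partial correlation r_xy.z from the three pairwise
# Pearson correlations of the rank-transformed triple
partial_cor_oracle <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); rzy <- cor(rz, ry)
  (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
}

# brute-force one-way ANOVA from explicit sums of squares
anova_ss_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1L
  df2 <- length(all_v) - length(groups)
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

# truth table for the per-compartment shape rule, written as an explicit
# lookup over the sign pattern of (FC_SGA - 1, FC_LGA - 1)
shape_truth_oracle <- function(fc_sga, fc_lga) {
  s1 <- sign(fc_sga - 1); s2 <- sign(fc_lga - 1)
  key <- paste(s1, s2)
  switch(key,
         "1 1" = "U_up", "-1 -1" = "U_down",
         "-1 1" = "line_up", "1 -1" = "line_down",
         "none")
}

# small reproducible cohort for cross-module tests
tiny_cohort <- function(seed = 11, ...) {
  generate_cohort(cohort_config(
    group_sizes = c(SGA = 8, AGA = 10, LGA = 9),
    n_metabolites_per_class = c(U_up = 4, U_down = 4, line_up = 4,
                                line_down = 4, null = 20),
    seed = seed, ...))
}

random_intensity <- function(n, p, seed = 1, compartment = "maternal",
                             mode = "pos", missing_rate = 0) {
  set.seed(seed)
  v <- matrix(exp(rnorm(n * p, 10, 1)), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("M%03d", 1:p)))
  if (missing_rate > 0) v[runif(n * p) < missing_rate] <- NA
  intensity_matrix(v, compartment = compartment, mode = mode)
}
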