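# Shared helpers for the latent-variable models -------------------------------

.as_matrix_x <- function(X) {
  if (inherits(X, "intensity_matrix")) X <- X$values
  X <- as.matrix(X)
  if (anyNA(X))
    stop("X contains missing values; impute (see impute_missing) before fitting",
         call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

# center + scale columns; uv = unit variance, pareto = sqrt(SD)
.scale_x <- function(X, scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  ctr <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0] <- 1  # constant columns stay at zero after centering
  fac <- switch(scaling, uv = sds, pareto = sqrt(sds), none = rep(1, ncol(X)))
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, fac, "/")
  list(X = Xs, center = ctr, scale = fac, scaling = scaling)
}

.dummy_y <- function(y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("y must have at least 2 levels", call. = FALSE)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  list(Y = Y, levels = levels(y), y = y)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Multi-class partial least squares discriminant analysis: the class factor
#' is dummy-coded and a PLS2 model is fit by the NIPALS algorithm. Components
#' use a deterministic sign convention (the largest-magnitude X-loading
#' element of each component is positive), so fits are bit-for-bit
#' reproducible.
#'
#' @param X Numeric sample-by-variable matrix or an [intensity_matrix]
#'   (no missing values).
#' @param y Class factor with >= 2 levels.
#' @param n_components Number of latent components (must not exceed the rank
#'   of the centered, scaled X).
#' @param scaling Column scaling applied before fitting: `"uv"` (unit
#'   variance, default), `"pareto"`, or `"none"` (centering only).
#' @param max_iter,tol NIPALS iteration cap and relative convergence
#'   tolerance on the score vector.
#' @return An object of class `plsda_model` with weights `W`, X-loadings `P`,
#'   Y-loadings `C`, scores `T`, cumulative `R2X`/`R2Y`, and the per-component
#'   explained Y sum of squares used by [vip()].
#' @export
fit_plsda <- function(X, y, n_components = 2L,
                      scaling = c("uv", "pareto", "none"),
                      max_iter = 500L, tol = 1e-10) {
  X <- .as_matrix_x(X)
  dy <- .dummy_y(y)
  if (nrow(X) != nrow(dy$Y)) stop("X and y dimensions disagree", call. = FALSE)
  sc <- .scale_x(X, scaling)
  Xw <- sc$X
  Yw <- scale(dy$Y, center = TRUE, scale = FALSE)
  ymean <- attr(Yw, "scaled:center"); attr(Yw, "scaled:center") <- NULL

  rk <- qr(Xw)$rank
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds rank(X) = ", rk, call. = FALSE)

  n <- nrow(Xw); p <- ncol(Xw); g <- ncol(Yw)
  ssx0 <- sum(Xw^2); ssy0 <- sum(Yw^2)
  W <- P <- matrix(0, p, n_components)
  C <- matrix(0, g, n_components)
  Tm <- U <- matrix(0, n, n_components)
  r2x <- r2y <- ssy_comp <- numeric(n_components)
  ssy_prev <- ssy0

  for (a in seq_len(n_components)) {
    u <- Yw[, which.max(apply(Yw, 2L, stats::var))]
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xw, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t_ <- drop(Xw %*% w)
      q <- drop(crossprod(Yw, t_)) / sum(t_^2)
      u <- drop(Yw %*% q) / sum(q^2)
      if (sqrt(sum((t_ - t_old)^2)) < tol * max(sqrt(sum(t_^2)), 1e-300)) break
      t_old <- t_
    }
    p_ <- drop(crossprod(Xw, t_)) / sum(t_^2)
    i_max <- which.max(abs(p_))
    if (p_[i_max] < 0) { w <- -w; t_ <- -t_; p_ <- -p_; q <- -q; u <- -u }
    Xw <- Xw - tcrossprod(t_, p_)
    Yw <- Yw - tcrossprod(t_, q)
    W[, a] <- w; P[, a] <- p_; C[, a] <- q; Tm[, a] <- t_; U[, a] <- u
    ssy_now <- sum(Yw^2)
    ssy_comp[a] <- ssy_prev - ssy_now
    ssy_prev <- ssy_now
    r2x[a] <- 1 - sum(Xw^2) / ssx0
    r2y[a] <- 1 - ssy_now / ssy0
  }
  rownames(W) <- rownames(P) <- colnames(X)
  structure(list(method = "plsda", W = W, P = P, C = C, scores = Tm, U = U,
                 n_components = n_components,
                 center = sc$center, scale = sc$scale, scaling = sc$scaling,
                 ymean = ymean, levels = dy$levels, y = dy$y,
                 ssy_comp = ssy_comp, ssy0 = ssy0,
                 R2X = r2x, R2Y = r2y),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA (NIPALS): %d classes, %d component(s)\n",
              length(x$levels), x$n_components))
  cat("  cumulative R2X:", paste(signif(x$R2X, 3), collapse = " "), "\n")
  cat("  cumulative R2Y:", paste(signif(x$R2Y, 3), collapse = " "), "\n")
  invisible(x)
}

#' Predict from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Matrix (or [intensity_matrix]) with the training variables.
#' @param ... Unused.
#' @return Matrix of predicted class-indicator values (one column per class,
#'   on the 0/1 dummy scale); the attribute `"class"` holds the arg-max class.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  X <- .as_matrix_x(newdata)
  X <- X[, rownames(object$W), drop = FALSE]
  Xs <- sweep(sweep(X, 2L, object$center, "-"), 2L, object$scale, "/")
  Wstar <- object$W %*% solve(crossprod(object$P, object$W))
  Yhat <- Xs %*% Wstar %*% t(object$C)
  Yhat <- sweep(Yhat, 2L, object$ymean, "+")
  colnames(Yhat) <- object$levels
  attr(Yhat, "class_pred") <- object$levels[max.col(Yhat)]
  Yhat
}
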