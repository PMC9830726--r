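#' Fit a two-class OPLS-DA model
#'
#' Orthogonal PLS-DA for a binary class factor: variation orthogonal to the
#' class response is estimated and removed component by component, then a
#' single predictive PLS component is fit on the filtered matrix. Because the
#' filtered matrix is exactly orthogonal to every removed score, the
#' predictive score is orthogonal to all orthogonal scores by construction.
#'
#' With `n_orth = 0` the model degenerates to ordinary single-component PLS1
#' on the dummy-coded response.
#'
#' @param X Numeric sample-by-variable matrix or [intensity_matrix] (no
#'   missing values).
#' @param y Binary class factor (exactly 2 levels after dropping unused
#'   ones); the second level is coded 1.
#' @param n_orth Number of orthogonal components to remove (>= 0).
#' @param scaling Column scaling, as in [fit_plsda()].
#' @return An object of class `oplsda_model` holding the predictive weight
#'   vector `w_pred`, score `t_pred`, loading `p_pred` and y-loading `c_pred`;
#'   orthogonal weights/scores/loadings (`W_orth`, `T_orth`, `P_orth`); the
#'   scaling used; `R2X` (total, with predictive and orthogonal parts) and
#'   `R2Y`. `Q2` is `NA` until filled in from [cross_validate()].
#' @export
fit_oplsda <- function(X, y, n_orth = 1L, scaling = c("uv", "pareto", "none")) {
  X <- .as_matrix_x(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L)
    stop("OPLS-DA requires a binary y (got ", nlevels(y), " level(s))",
         call. = FALSE)
  if (n_orth < 0L) stop("n_orth must be >= 0", call. = FALSE)
  yn <- as.numeric(y == levels(y)[2L])
  ymean <- mean(yn)
  yc <- yn - ymean
  sc <- .scale_x(X, scaling)
  Xw <- sc$X
  n <- nrow(Xw); p <- ncol(Xw)
  ssx0 <- sum(Xw^2); ssy0 <- sum(yc^2)

  w <- drop(crossprod(Xw, yc)) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  W_o <- P_o <- matrix(0, p, 0L)
  T_o <- matrix(0, n, 0L)
  r2x_orth <- numeric(0)
  for (a in seq_len(n_orth)) {
    t_ <- drop(Xw %*% w)
    p_ <- drop(crossprod(Xw, t_)) / sum(t_^2)
    w_o <- p_ - drop(crossprod(w, p_)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break  # no y-orthogonal variation left
    w_o <- w_o / nrm
    t_o <- drop(Xw %*% w_o)
    p_o <- drop(crossprod(Xw, t_o)) / sum(t_o^2)
    i_max <- which.max(abs(p_o))
    if (p_o[i_max] < 0) { w_o <- -w_o; t_o <- -t_o; p_o <- -p_o }
    Xw <- Xw - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
    r2x_orth <- c(r2x_orth, sum(t_o^2) * sum(p_o^2) / ssx0)
    # re-estimate the predictive weight on the filtered matrix
    w <- drop(crossprod(Xw, yc)) / sum(yc^2)
    w <- w / sqrt(sum(w^2))
  }
  t_p <- drop(Xw %*% w)
  p_p <- drop(crossprod(Xw, t_p)) / sum(t_p^2)
  c_p <- sum(yc * t_p) / sum(t_p^2)
  i_max <- which.max(abs(p_p))
  if (p_p[i_max] < 0) { w <- -w; t_p <- -t_p; p_p <- -p_p; c_p <- -c_p }
  resid_y <- yc - t_p * c_p
  r2y <- 1 - sum(resid_y^2) / ssy0
  r2x_pred <- sum(t_p^2) * sum(p_p^2) / ssx0

  names(w) <- names(p_p) <- colnames(X)
  structure(list(method = "oplsda",
                 w_pred = w, t_pred = t_p, p_pred = p_p, c_pred = c_p,
                 W_orth = W_o, T_orth = T_o, P_orth = P_o,
                 n_orth = ncol(W_o),
                 center = sc$center, scale = sc$scale, scaling = sc$scaling,
                 ymean = ymean, levels = levels(y), y = y,
                 ssy_comp = r2y * ssy0, ssy0 = ssy0,
                 R2X = r2x_pred + sum(r2x_orth),
                 R2X_pred = r2x_pred, R2X_orth = r2x_orth,
                 R2Y = r2y, Q2 = NA_real_),
            class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("OPLS-DA (%s vs %s): 1 predictive + %d orthogonal component(s)\n",
              x$levels[1L], x$levels[2L], x$n_orth))
  cat(sprintf("  R2X = %.3f (pred %.3f)  R2Y = %.3f  Q2 = %s\n",
              x$R2X, x$R2X_pred, x$R2Y,
              if (is.na(x$Q2)) "not cross-validated" else sprintf("%.3f", x$Q2)))
  invisible(x)
}

#' Predict from an OPLS-DA model
#'
#' Applies the training scaling, removes the orthogonal components, and
#' projects on the predictive component.
#'
#' @param object An `oplsda_model`.
#' @param newdata Matrix (or [intensity_matrix]) with the training variables.
#' @param ... Unused.
#' @return Numeric vector of predicted responses on the 0/1 dummy scale;
#'   attribute `"class_pred"` holds the thresholded class label.
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  X <- .as_matrix_x(newdata)
  X <- X[, names(object$w_pred), drop = FALSE]
  Xs <- sweep(sweep(X, 2L, object$center, "-"), 2L, object$scale, "/")
  for (a in seq_len(object$n_orth)) {
    t_o <- drop(Xs %*% object$W_orth[, a])
    Xs <- Xs - tcrossprod(t_o, object$P_orth[, a])
  }
  t_new <- drop(Xs %*% object$w_pred)
  yhat <- t_new * object$c_pred + object$ymean
  attr(yhat, "class_pred") <- object$levels[(yhat >= 0.5) + 1L]
  yhat
}
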