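# Stratified "venetian blind" fold assignment: within each class the samples
# are shuffled (seed-deterministic) and dealt cyclically over the k folds, so
# every fold mirrors the class balance as closely as integer counts allow.
.stratified_folds <- function(y, k_folds, seed) {
  y <- as.factor(y)
  n <- length(y)
  if (k_folds < 2L || k_folds > n)
    stop("k_folds must lie in [2, n]", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k_folds) + 1L
    offset <- offset + length(idx)  # continue dealing where the last class stopped
  }
  fold
}

#' Cross-validated R2Y and Q2 for a PLS-DA or OPLS-DA specification
#'
#' Refits the model on each training fold and predicts the held-out samples;
#' \eqn{Q^2 = 1 - PRESS/SSY} with SSY the total (mean-corrected) sum of
#' squares of the dummy-coded response. Folds are stratified by class with a
#' deterministic, seed-controlled venetian-blind assignment; `k_folds = n`
#' gives leave-one-out. `Q2 <= 0` means the model predicts left-out samples no
#' better than the class mean.
#'
#' @param X Sample-by-variable matrix or [intensity_matrix] (no missing
#'   values).
#' @param y Class factor (binary for `method = "oplsda"`).
#' @param model_spec List with `method` (`"plsda"` or `"oplsda"`) and the
#'   fit arguments `n_components` / `n_orth`, optionally `scaling`.
#' @param k_folds Number of folds (default 7).
#' @param seed Integer seed controlling the fold assignment.
#' @return List with `R2Y` (training, full fit), `Q2`, and the integer fold
#'   vector used.
#' @export
cross_validate <- function(X, y, model_spec = list(method = "oplsda", n_orth = 1L),
                           k_folds = 7L, seed = 1L) {
  X <- .as_matrix_x(X)
  y <- droplevels(as.factor(y))
  method <- match.arg(model_spec$method, c("plsda", "oplsda"))
  scaling <- if (is.null(model_spec$scaling)) "uv" else model_spec$scaling
  fold <- .stratified_folds(y, k_folds, seed)

  for (f in sort(unique(fold))) {
    if (nlevels(droplevels(y[fold != f])) < 2L)
      stop("training split for fold ", f, " contains a single class; ",
           "reduce k_folds or rebalance the classes", call. = FALSE)
  }

  if (method == "oplsda") {
    if (nlevels(y) != 2L) stop("oplsda cross-validation needs binary y", call. = FALSE)
    n_orth <- if (is.null(model_spec$n_orth)) 1L else model_spec$n_orth
    yn <- as.numeric(y == levels(y)[2L])
    full <- fit_oplsda(X, y, n_orth = n_orth, scaling = scaling)
    press <- 0
    for (f in sort(unique(fold))) {
      tr <- fold != f
      m <- fit_oplsda(X[tr, , drop = FALSE], y[tr], n_orth = n_orth,
                      scaling = scaling)
      yhat <- predict(m, X[!tr, , drop = FALSE])
      press <- press + sum((yn[!tr] - yhat)^2)
    }
    ssy <- sum((yn - mean(yn))^2)
    return(list(R2Y = full$R2Y, Q2 = 1 - press / ssy, folds = fold))
  }

  n_comp <- if (is.null(model_spec$n_components)) 2L else model_spec$n_components
  Y <- stats::model.matrix(~ y - 1)
  full <- fit_plsda(X, y, n_components = n_comp, scaling = scaling)
  press <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f
    m <- fit_plsda(X[tr, , drop = FALSE], y[tr], n_components = n_comp,
                   scaling = scaling)
    yhat <- predict(m, X[!tr, , drop = FALSE])
    # a class absent from the training fold predicts 0 on the dummy scale
    yhat_full <- matrix(0, nrow(yhat), nlevels(y),
                        dimnames = list(NULL, levels(y)))
    yhat_full[, colnames(yhat)] <- yhat
    press <- press + sum((Y[!tr, , drop = FALSE] - yhat_full)^2)
  }
  ssy <- sum(sweep(Y, 2L, colMeans(Y))^2)
  list(R2Y = full$R2Y[n_comp], Q2 = 1 - press / ssy, folds = fold)
}
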