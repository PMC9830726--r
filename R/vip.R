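#' Variable importance in projection (VIP)
#'
#' Computes per-variable VIP scores from a fitted [fit_plsda()] or
#' [fit_oplsda()] model:
#' \deqn{VIP_j = \sqrt{p \; \sum_a SSY_a (w_{ja}/\|w_a\|)^2 \; / \; \sum_a SSY_a}}
#' where \eqn{p} is the number of variables, \eqn{w_a} the component weight
#' vectors and \eqn{SSY_a} the Y sum of squares explained by component
#' \eqn{a}. By construction the mean squared VIP equals 1, so VIP > 1 marks a
#' variable contributing more than average — the usual differential-metabolite
#' cut-off.
#'
#' For OPLS-DA models the default (`variant = "pred"`) uses the predictive
#' component only; `variant = "all"` additionally includes the orthogonal
#' components, weighted by the (typically negligible) Y sum of squares each of
#' their scores explains.
#'
#' @param model A fitted `plsda_model` or `oplsda_model`.
#' @param variant `"pred"` (default) or `"all"`; ignored for PLS-DA models,
#'   whose components are all predictive.
#' @return A `data.frame(metabolite_id, vip)`, one row per variable, in the
#'   column order of the training matrix.
#' @export
vip <- function(model, variant = c("pred", "all")) {
  variant <- match.arg(variant)
  if (inherits(model, "plsda_model")) {
    W <- model$W                     # columns already unit-norm
    ssy <- model$ssy_comp
    p <- nrow(W)
    v <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
    return(data.frame(metabolite_id = rownames(W), vip = unname(v),
                      stringsAsFactors = FALSE))
  }
  if (inherits(model, "oplsda_model")) {
    p <- length(model$w_pred)
    if (variant == "pred" || model$n_orth == 0L) {
      v <- sqrt(p) * abs(model$w_pred)
    } else {
      yc <- as.numeric(model$y == model$levels[2L]) - model$ymean
      W <- cbind(model$w_pred, model$W_orth)
      Tm <- cbind(model$t_pred, model$T_orth)
      ssy <- vapply(seq_len(ncol(Tm)), function(a) {
        t_ <- Tm[, a]; sum(t_ * yc)^2 / sum(t_^2)
      }, numeric(1))
      v <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
    }
    return(data.frame(metabolite_id = names(model$w_pred), vip = unname(v),
                      stringsAsFactors = FALSE))
  }
  stop("`model` must be a fitted plsda_model or oplsda_model", call. = FALSE)
}
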