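#' Column-wise Z-score normalization
#'
#' Centers and scales every metabolite column to mean 0 and sample SD 1
#' (denominator n - 1), the transformation applied to peak intensities before
#' heatmap/meta-analysis ordering. Missing entries are preserved; the column
#' statistics use the non-missing values only. Columns with zero variance or
#' fewer than two non-missing values have no defined Z score and are dropped
#' with a warning.
#'
#' @param matrix An [intensity_matrix] with `normalized = FALSE`.
#' @return A normalized [intensity_matrix]; dropped column ids are recorded in
#'   the `"dropped"` attribute.
#' @examples
#' m <- intensity_matrix(matrix(1:6, 3, 2,
#'        dimnames = list(c("a","b","c"), c("m1","m2"))), "maternal")
#' znormalize(m)$values
#' @export
znormalize <- function(matrix) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (matrix$normalized) stop("matrix is already Z-normalized", call. = FALSE)
  v <- matrix$values
  n_ok <- colSums(!is.na(v))
  sds <- apply(v, 2L, stats::sd, na.rm = TRUE)
  bad <- n_ok < 2L | is.na(sds) | sds == 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " constant or all-missing column(s): ",
            paste(utils::head(colnames(v)[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "", call. = FALSE)
    v <- v[, !bad, drop = FALSE]
    sds <- sds[!bad]
  }
  if (ncol(v) == 0L) stop("no columns left after dropping constant columns")
  z <- scale(v, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  out <- intensity_matrix(z, compartment = matrix$compartment,
                          mode = matrix$mode, normalized = TRUE)
  attr(out, "dropped") <- colnames(matrix$values)[bad]
  out
}

#' Merge positive- and negative-mode matrices
#'
#' Column-binds the two ionization modes of one compartment into a single
#' feature space; metabolite ids are prefixed by their mode (`pos:`/`neg:`) so
#' features detected in both modes stay distinct. No deduplication is
#' attempted.
#'
#' @param pos,neg [intensity_matrix] objects of the same compartment holding
#'   exactly the same samples.
#' @return A merged [intensity_matrix] with `mode = "merged"`, columns ordered
#'   positive-mode first.
#' @export
merge_modes <- function(pos, neg) {
  stopifnot(inherits(pos, "intensity_matrix"), inherits(neg, "intensity_matrix"))
  if (pos$compartment != neg$compartment)
    stop("cannot merge matrices from different compartments", call. = FALSE)
  sp <- rownames(pos$values); sn <- rownames(neg$values)
  if (!setequal(sp, sn) || length(sp) != length(sn)) {
    diff <- c(setdiff(sp, sn), setdiff(sn, sp))
    stop("sample sets differ between modes: ", paste(diff, collapse = ", "),
         call. = FALSE)
  }
  neg_v <- neg$values[sp, , drop = FALSE]  # align row order to pos
  m <- cbind(pos$values, neg_v)
  colnames(m) <- c(paste0("pos:", colnames(pos$values)),
                   paste0("neg:", colnames(neg$values)))
  intensity_matrix(m, compartment = pos$compartment, mode = "merged",
                   normalized = pos$normalized && neg$normalized)
}

#' Impute missing intensities
#'
#' `"half-min"` replaces the missing entries of each metabolite with half its
#' minimum observed intensity (the usual limit-of-detection surrogate);
#' `"none"` returns the matrix unchanged, leaving downstream statistics to
#' pairwise-complete observations.
#'
#' @param matrix A raw [intensity_matrix].
#' @param method `"half-min"` or `"none"`.
#' @return An [intensity_matrix].
#' @export
impute_missing <- function(matrix, method = c("half-min", "none")) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  method <- match.arg(method)
  if (method == "none" || !anyNA(matrix$values)) return(matrix)
  v <- matrix$values
  mins <- apply(v, 2L, function(col) suppressWarnings(min(col, na.rm = TRUE)))
  for (j in which(colSums(is.na(v)) > 0L)) {
    if (!is.finite(mins[j])) next  # all-missing column: nothing observed to impute from
    v[is.na(v[, j]), j] <- mins[j] / 2
  }
  intensity_matrix(v, compartment = matrix$compartment, mode = matrix$mode,
                   normalized = matrix$normalized)
}
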