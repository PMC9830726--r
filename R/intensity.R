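#' Sample-by-metabolite intensity matrix
#'
#' Lightweight container for the abundance matrix of one compartment and one
#' ionization mode. Rows are samples (dyads), columns are metabolites. Raw
#' matrices hold nonnegative peak intensities; after [znormalize()] the values
#' are unitless column Z scores and `normalized` is `TRUE`.
#'
#' @param values Numeric matrix with unique row (sample) and column
#'   (metabolite) names.
#' @param compartment `"maternal"` or `"cord"`.
#' @param mode `"pos"`, `"neg"`, or `"merged"` after [merge_modes()].
#' @param normalized Logical; `TRUE` once column Z-scored.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, compartment = c("maternal", "cord"),
                             mode = "pos", normalized = FALSE) {
  compartment <- match.arg(compartment)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample (row) and metabolite (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate metabolite ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (!normalized && any(values < 0, na.rm = TRUE))
    stop("raw intensities must be nonnegative", call. = FALSE)
  structure(list(values = values, compartment = compartment, mode = mode,
                 normalized = normalized),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d samples x %d metabolites [%s, %s, %s]\n",
              nrow(x$values), ncol(x$values), x$compartment, x$mode,
              if (x$normalized) "Z-normalized" else "raw"))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("  %d missing cells (%.1f%%)\n", n_na,
                            100 * n_na / length(x$values)))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Read an intensity CSV
#'
#' Expects the dialect written by [write_intensity_csv()]: a header row, first
#' column the sample id, remaining columns one metabolite each, empty cells
#' for missing values.
#'
#' @param path CSV file path.
#' @param compartment,mode Tags stored on the returned object.
#' @param normalized Whether the file holds Z scores rather than raw values.
#' @return An [intensity_matrix].
#' @export
read_intensity_csv <- function(path, compartment = "maternal", mode = "pos",
                               normalized = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("intensity CSV needs a sample-id column plus >= 1 metabolite")
  ids <- names(df)[-1L]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate metabolite column(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  vals <- df[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  for (j in bad) {
    suppressWarnings(num <- as.numeric(vals[[j]]))
    nn <- which(is.na(num) & !(is.na(vals[[j]]) | vals[[j]] == ""))
    if (length(nn))
      stop("non-numeric cell in column '", ids[j], "', data line ", nn[1L],
           call. = FALSE)
    vals[[j]] <- num
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(df[[1L]])
  intensity_matrix(m, compartment = compartment, mode = mode,
                   normalized = normalized)
}

#' Write an intensity matrix as CSV
#'
#' @param x An [intensity_matrix].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_intensity_csv <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
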