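#' Binarize a fold-change matrix at a 2-fold threshold
#'
#' Builds the binary matrix fed to the bicluster search: in the `"up"`
#' matrix a cell is 1 iff `log2FC >= threshold_log2`, in the `"down"` matrix
#' iff `log2FC <= -threshold_log2`. The default threshold of 1 log2 unit is
#' a 2-fold change. The threshold is inclusive, so for any positive
#' threshold the up and down matrices of the same input are elementwise
#' disjoint, and raising the threshold can only turn 1s into 0s.
#'
#' @param fc A [fold_change_matrix()] (or a plain numeric matrix with
#'   dimnames). Non-finite values (e.g. `NA` from a union merge) are a hard
#'   error.
#' @param direction `"up"` or `"down"`.
#' @param threshold_log2 Positive threshold in log2 fold-change units.
#' @return A `binary_matrix`: list with `values` (0/1 integer matrix),
#'   `direction` and `threshold_log2`.
#' @export
binarize <- function(fc, direction = c("up", "down"), threshold_log2 = 1) {
  direction <- rlang::arg_match(direction)
  threshold_log2 <- assert_number(threshold_log2, "threshold_log2",
                                  min = 0, strict = TRUE)
  values <- if (inherits(fc, "fold_change_matrix")) fc$values else fc
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`fc` must be a fold_change_matrix or numeric matrix")
  }
  if (any(!is.finite(values))) {
    abort("cannot binarize non-finite fold changes; resolve NAs first")
  }
  bin <- if (direction == "up") {
    values >= threshold_log2
  } else {
    values <= -threshold_log2
  }
  storage.mode(bin) <- "integer"
  structure(
    list(values = bin, direction = direction, threshold_log2 = threshold_log2),
    class = "binary_matrix"
  )
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf(
    "<binary_matrix> %s at |log2FC| >= %g: %d x %d, %d one(s)\n",
    x$direction, x$threshold_log2, nrow(x$values), ncol(x$values),
    sum(x$values)
  ))
  invisible(x)
}
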