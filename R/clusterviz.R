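#' Per-group median expression
#'
#' Collapses samples to group columns by the per-gene median, the first step
#' of the heatmap presentation (biological replicates averaged using the
#' median).
#'
#' @param exp A [dose_experiment()] or a numeric gene-by-sample matrix.
#' @param grouping Named character vector mapping sample name to group
#'   label; default for a `dose_experiment` is its dose labels. Every name
#'   must be a sample of the matrix.
#' @return Numeric gene-by-group matrix, group columns sorted
#'   lexicographically.
#' @export
group_medians <- function(exp, grouping = NULL) {
  v <- if (inherits(exp, "dose_experiment")) exp$values else exp
  if (!is.matrix(v) || !is.numeric(v)) abort("`exp` must be a numeric matrix")
  if (is.null(grouping)) {
    if (!inherits(exp, "dose_experiment")) {
      abort("`grouping` is required for a bare matrix")
    }
    grouping <- exp$doses
  }
  unknown <- setdiff(names(grouping), colnames(v))
  if (length(unknown)) {
    abort(sprintf(
      "unknown sample(s) in grouping: %s", paste(unknown, collapse = ", ")
    ))
  }
  groups <- split(names(grouping), as.character(grouping))
  groups <- groups[order(names(groups))]
  out <- vapply(
    groups,
    function(smp) apply(v[, smp, drop = FALSE], 1, median),
    numeric(nrow(v))
  )
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(v))
  dimnames(out) <- list(rownames(v), names(groups))
  out
}

#' Average-linkage clustering on 1 - Spearman correlation
#'
#' Orders the rows or columns of a matrix by agglomerative clustering with
#' average (UPGMA) linkage on the dissimilarity `d(i, j) = 1 - rho(i, j)`,
#' where rho is the Spearman rank correlation (midranks for ties). Spearman
#' invariance means any strictly increasing transform of an item leaves the
#' result unchanged. Items are pre-sorted lexicographically by label so the
#' merge order, and hence tie-breaking, is deterministic.
#'
#' @param m Numeric matrix with dimnames (e.g. from [group_medians()]).
#' @param axis Cluster `"cols"` (default) or `"rows"`.
#' @return An object of class `spearman_linkage`: list with `hclust` (the
#'   [stats::hclust] tree), `labels`, `leaf_order` (labels in dendrogram
#'   order) and `dissimilarity` (the full matrix of `1 - rho`).
#' @export
spearman_average_linkage <- function(m, axis = c("cols", "rows")) {
  axis <- rlang::arg_match(axis)
  if (!is.matrix(m) || !is.numeric(m)) abort("`m` must be a numeric matrix")
  if (axis == "rows") m <- t(m)
  if (ncol(m) < 2L) abort("need >= 2 items to cluster")
  if (is.null(colnames(m))) colnames(m) <- sprintf("item%d", seq_len(ncol(m)))
  m <- m[, order(colnames(m)), drop = FALSE]
  constant <- apply(m, 2, function(v) all(v == v[1L]))
  if (any(constant)) {
    abort(sprintf(
      "constant item(s) have undefined Spearman correlation: %s",
      paste(colnames(m)[constant], collapse = ", ")
    ))
  }
  rho <- cor(m, method = "spearman")
  d <- 1 - rho
  hc <- hclust(as.dist(d), method = "average")
  structure(
    list(
      hclust = hc,
      labels = colnames(m),
      leaf_order = colnames(m)[hc$order],
      dissimilarity = d
    ),
    class = "spearman_linkage"
  )
}

#' @export
print.spearman_linkage <- function(x, ...) {
  cat(sprintf(
    "<spearman_linkage> %d items, leaf order: %s\n",
    length(x$labels), paste(x$leaf_order, collapse = ", ")
  ))
  invisible(x)
}

#' @rdname spearman_average_linkage
#' @param x A `spearman_linkage`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of the merge history, one row per
#'   agglomeration step with the two merged clusters (negative = leaf index,
#'   positive = earlier step) and the merge `height`.
#' @export
tidy.spearman_linkage <- function(x, ...) {
  tibble(
    step = seq_len(nrow(x$hclust$merge)),
    cluster_a = x$hclust$merge[, 1L],
    cluster_b = x$hclust$merge[, 2L],
    height = x$hclust$height
  )
}

#' Ordered heatmap matrix for a gene set
#'
#' Reproduces the heatmap presentation for one bicluster/gene set: group
#' medians restricted to the set's genes, with columns (and rows when
#' possible) reordered by Spearman average-linkage clustering.
#'
#' @param exp A [dose_experiment()] or gene-by-sample matrix.
#' @param genes Gene symbols to display (members absent from the matrix are
#'   dropped).
#' @param grouping Passed to [group_medians()].
#' @return A list with `values` (ordered median matrix), `col_linkage` and
#'   `row_linkage` (`spearman_linkage` or `NULL` when an axis has < 2
#'   clusterable items).
#' @export
ordered_heatmap_matrix <- function(exp, genes = NULL, grouping = NULL) {
  med <- group_medians(exp, grouping)
  if (!is.null(genes)) {
    keep <- intersect(rownames(med), genes)
    if (length(keep) == 0L) abort("none of `genes` found in the matrix")
    med <- med[keep, , drop = FALSE]
  }
  col_l <- if (ncol(med) >= 2L) spearman_average_linkage(med, "cols") else NULL
  row_l <- if (nrow(med) >= 2L) {
    tryCatch(spearman_average_linkage(med, "rows"), error = function(e) NULL)
  } else {
    NULL
  }
  ord_r <- if (is.null(row_l)) rownames(med) else row_l$leaf_order
  ord_c <- if (is.null(col_l)) colnames(med) else col_l$leaf_order
  list(
    values = med[ord_r, ord_c, drop = FALSE],
    row_linkage = row_l,
    col_linkage = col_l
  )
}
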