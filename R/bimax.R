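#' Enumerate inclusion-maximal all-ones biclusters (the Bimax model)
#'
#' Finds every submatrix of a binary matrix that is all ones and
#' inclusion-maximal — no further row or column can be added without
#' breaking the all-ones property — and then applies the size constraints:
#' at least `min_rows` genes, between `min_cols` and `max_cols` conditions.
#' Maximality is judged on the unconstrained matrix; biclusters wider than
#' `max_cols` are discarded, not truncated.
#'
#' The search enumerates closed column sets by divide and conquer over the
#' column index with a canonicity test (Close-by-One), so every maximal
#' bicluster is produced exactly once, duplicates are impossible by
#' construction and the recursion depth is bounded by the number of columns.
#' Overlapping biclusters are an inherent part of the model and are all
#' reported.
#'
#' @param x A `binary_matrix` from [binarize()], or a 0/1 numeric/logical
#'   matrix with dimnames.
#' @param min_rows Minimum number of rows (genes); default 15.
#' @param min_cols,max_cols Column (condition) count bounds; defaults 5
#'   and 15.
#' @param max_biclusters Guard against combinatorial blow-up: enumerating
#'   more than this many maximal biclusters (before size filtering) is a
#'   hard error, never a silent truncation.
#' @return A tibble with one row per bicluster, ordered by area
#'   (`n_genes * n_conditions`) descending with lexicographic tie-breaks on
#'   the sorted row then column labels. Columns: `bicluster` (rank id),
#'   `direction` (`NA` for a bare matrix), `n_genes`, `n_conditions`,
#'   `genes` and `conditions` (list-columns of sorted labels).
#' @export
bimax <- function(x, min_rows = 15L, min_cols = 5L, max_cols = 15L,
                  max_biclusters = 100000L) {
  direction <- NA_character_
  if (inherits(x, "binary_matrix")) {
    direction <- x$direction
    x <- x$values
  }
  if (!is.matrix(x)) abort("`x` must be a matrix")
  if (is.logical(x)) storage.mode(x) <- "integer"
  if (!all(x %in% c(0L, 1L))) abort("matrix entries must all be 0 or 1")
  if (nrow(x) == 0L || ncol(x) == 0L) abort("matrix must be non-empty")
  min_rows <- assert_count(min_rows, "min_rows")
  min_cols <- assert_count(min_cols, "min_cols")
  max_cols <- assert_count(max_cols, "max_cols")
  if (min_cols > max_cols) abort("`min_cols` must be <= `max_cols`")
  max_biclusters <- assert_count(max_biclusters, "max_biclusters")
  if (is.null(rownames(x))) rownames(x) <- sprintf("r%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("c%d", seq_len(ncol(x)))

  concepts <- enumerate_maximal_biclusters(x == 1L, max_biclusters)
  keep <- vapply(
    concepts,
    function(cc) {
      length(cc$rows) >= min_rows &&
        length(cc$cols) >= min_cols && length(cc$cols) <= max_cols
    },
    logical(1L)
  )
  concepts <- concepts[keep]
  bicluster_tibble(concepts, x, direction)
}

# Close-by-One enumeration of all closed (extent, intent) pairs with
# non-empty extent and non-empty intent. M is a logical matrix.
enumerate_maximal_biclusters <- function(M, max_biclusters) {
  n_col <- ncol(M)
  n_row <- nrow(M)
  out <- vector("list", 256L)
  count <- 0L
  emit <- function(rmask, cmask) {
    if (!any(cmask)) return(invisible())
    count <<- count + 1L
    if (count > max_biclusters) {
      abort(sprintf(
        "more than %d maximal biclusters; raise `max_biclusters` or tighten the binarization threshold",
        max_biclusters
      ))
    }
    if (count > length(out)) length(out) <<- 2L * count
    out[[count]] <<- list(rows = which(rmask), cols = which(cmask))
  }
  closure_cols <- function(rmask) {
    nr <- sum(rmask)
    colSums(M[rmask, , drop = FALSE]) == nr
  }
  recurse <- function(rmask, intent, from) {
    emit(rmask, intent)
    if (from > n_col) return(invisible())
    for (k in from:n_col) {
      if (intent[k]) next
      r2 <- rmask & M[, k]
      if (!any(r2)) next
      cl <- closure_cols(r2)
      # canonicity: the closure must not add any column before k that the
      # current intent lacks, otherwise this concept is generated elsewhere
      if (k > 1L && any(cl[seq_len(k - 1L)] & !intent[seq_len(k - 1L)])) next
      recurse(r2, cl, k + 1L)
    }
  }
  if (n_col >= 1L) {
    top_r <- rep(TRUE, n_row)
    recurse(top_r, closure_cols(top_r), 1L)
  }
  out[seq_len(count)]
}

bicluster_tibble <- function(concepts, x, direction) {
  if (length(concepts) == 0L) {
    return(tibble(
      bicluster = integer(), direction = character(),
      n_genes = integer(), n_conditions = integer(),
      genes = list(), conditions = list()
    ))
  }
  genes <- lapply(concepts, function(cc) sort(rownames(x)[cc$rows]))
  conds <- lapply(concepts, function(cc) sort(colnames(x)[cc$cols]))
  area <- vapply(concepts, function(cc) length(cc$rows) * length(cc$cols), 0)
  gkey <- vapply(genes, paste, "", collapse = "\r")
  ckey <- vapply(conds, paste, "", collapse = "\r")
  ord <- order(-area, gkey, ckey)
  tibble(
    bicluster = seq_along(ord),
    direction = rep(direction, length(ord)),
    n_genes = vapply(genes, length, 0L)[ord],
    n_conditions = vapply(conds, length, 0L)[ord],
    genes = genes[ord],
    conditions = conds[ord]
  )
}

#' Run the discovery phase: binarize both directions and bicluster each
#'
#' Builds the 2-fold up- and down-regulated binary matrices from a
#' fold-change compendium, runs the maximal-bicluster search on each
#' independently, and concatenates the results with a `direction` tag. Each
#' bicluster's gene list can then be exported for functional annotation
#' (see [write_gene_lists()]).
#'
#' @inheritParams bimax
#' @param fc A [fold_change_matrix()].
#' @param threshold_log2 Binarization threshold (log2 units; 1 = 2-fold).
#' @return A bicluster tibble as in [bimax()], up-direction biclusters
#'   first, `bicluster` renumbered over the concatenation.
#' @export
run_discovery <- function(fc, min_rows = 15L, min_cols = 5L, max_cols = 15L,
                          threshold_log2 = 1, max_biclusters = 100000L) {
  res <- purrr::map_dfr(c("up", "down"), function(dir) {
    bimax(
      binarize(fc, dir, threshold_log2),
      min_rows = min_rows, min_cols = min_cols, max_cols = max_cols,
      max_biclusters = max_biclusters
    )
  })
  res$bicluster <- seq_len(nrow(res))
  res
}
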