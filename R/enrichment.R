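#' Per-gene one-way ANOVA F statistics for the dose effect
#'
#' For every gene, the overall F statistic of a one-way ANOVA with dose
#' group as an unordered factor:
#' `F = (SSB / df_between) / (SSW / df_within)` with
#' `df_between = k - 1` and `df_within = N - k` for `k` dose groups and `N`
#' samples. Large F indicates a strong dose effect. Genes with zero
#' within-group variance get `F = Inf`; `log2F = log2(F)` is finite only for
#' finite positive F, and downstream enrichment excludes the rest.
#'
#' The computation is vectorized over genes; with exactly two dose groups it
#' reduces to the square of the pooled-variance two-sample t statistic.
#'
#' @param exp A [dose_experiment()].
#' @return A tibble of class `gene_f_stats` with columns `gene`, `F`,
#'   `log2F`, and attributes `df_between`, `df_within` (see
#'   [glance.gene_f_stats()]).
#' @export
dose_f_statistics <- function(exp) {
  stopifnot(inherits(exp, "dose_experiment"))
  v <- exp$values
  groups <- split(seq_len(ncol(v)), exp$doses)
  k <- length(groups)
  n <- ncol(v)
  if (any(lengths(groups) < 2L)) {
    abort("every dose group needs >= 2 samples")
  }
  group_means <- vapply(
    groups, function(idx) rowMeans(v[, idx, drop = FALSE]),
    numeric(nrow(v))
  )
  if (is.null(dim(group_means))) group_means <- matrix(group_means, nrow = nrow(v))
  grand <- rowMeans(v)
  n_j <- lengths(groups)
  ssb <- as.vector((group_means - grand)^2 %*% n_j)
  ssw <- numeric(nrow(v))
  for (j in seq_len(k)) {
    idx <- groups[[j]]
    ssw <- ssw + rowSums((v[, idx, drop = FALSE] - group_means[, j])^2)
  }
  df_b <- k - 1L
  df_w <- n - k
  # ssb == 0 (no between-group signal) dominates: a fully constant gene has
  # F = 0, not 0/0; ssw == 0 with signal is a perfect dose separation, F = Inf
  f <- ifelse(ssb == 0, 0, ifelse(ssw == 0, Inf, (ssb / df_b) / (ssw / df_w)))
  log2f <- ifelse(is.finite(f) & f > 0, log2(f), NA_real_)
  out <- tibble(gene = rownames(v), F = f, log2F = log2f)
  structure(
    out,
    df_between = df_b, df_within = df_w,
    class = c("gene_f_stats", class(out))
  )
}

#' @rdname dose_f_statistics
#' @param x A `gene_f_stats` tibble.
#' @param ... Unused.
#' @export
glance.gene_f_stats <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    df_between = attr(x, "df_between"),
    df_within = attr(x, "df_within"),
    n_nonfinite_log2F = sum(!is.finite(x$log2F) | is.na(x$log2F))
  )
}

# Welch two-sample t-test from summary pieces; authored closed form so the
# enrichment statistic is self-contained (stats::t.test is the oracle in the
# test suite).
welch_t <- function(a, b, alternative = c("greater", "two.sided")) {
  alternative <- rlang::arg_match(alternative)
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) abort("Welch t-test needs >= 2 values per group")
  va <- stats::var(a)
  vb <- stats::var(b)
  se2 <- va / na + vb / nb
  t_stat <- if (se2 == 0) 0 else (mean(a) - mean(b)) / sqrt(se2)
  df <- if (se2 == 0) {
    na + nb - 2
  } else {
    se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- switch(alternative,
    greater = pt(t_stat, df, lower.tail = FALSE),
    two.sided = 2 * pt(-abs(t_stat), df)
  )
  list(t = t_stat, df = df, p = p)
}

#' Competitive gene-set enrichment of the dose effect
#'
#' Tests whether the dose-effect F statistics of a gene set are skewed
#' towards larger values than those of the gene population: a Welch
#' two-sample t-test (unequal variances, Welch–Satterthwaite degrees of
#' freedom) compares the mean log2 F within the set to the mean log2 F of
#' all measured genes. By default the background is all genes including the
#' set members and the alternative is one-sided "greater", i.e. enrichment
#' means larger F. Genes whose F is non-finite or zero have no finite
#' log2 F; they are excluded from both groups and counted.
#'
#' @param stats A `gene_f_stats` tibble from [dose_f_statistics()].
#' @param set Character vector of member gene symbols. Members absent from
#'   the experiment are intersected away with a warning.
#' @param set_name Label for the output row.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param background `"all"` (default: all measured genes, set included) or
#'   `"rest"` (set members removed from the background).
#' @return A one-row tibble: `set_name`, `t_statistic`, `df`, `p_value`,
#'   `mean_in_set`, `mean_background`, `n_in_set`, `n_background`,
#'   `n_excluded_nonfinite`.
#' @export
gene_set_enrichment <- function(stats, set, set_name = "set",
                                alternative = c("greater", "two.sided"),
                                background = c("all", "rest")) {
  stopifnot(inherits(stats, "gene_f_stats"))
  alternative <- rlang::arg_match(alternative)
  background <- rlang::arg_match(background)
  set <- unique(as.character(set))
  missing <- setdiff(set, stats$gene)
  if (length(missing)) {
    warn(sprintf(
      "%d gene(s) of set '%s' not measured in the experiment",
      length(missing), set_name
    ))
    set <- intersect(set, stats$gene)
  }
  usable <- is.finite(stats$log2F)
  n_excluded <- sum(!usable)
  in_set <- stats$gene %in% set
  a <- stats$log2F[usable & in_set]
  b <- if (background == "all") {
    stats$log2F[usable]
  } else {
    stats$log2F[usable & !in_set]
  }
  if (length(a) < 2L) {
    abort(sprintf("set '%s' has < 2 usable genes with finite log2 F", set_name))
  }
  w <- welch_t(a, b, alternative)
  tibble(
    set_name = set_name,
    t_statistic = w$t, df = w$df, p_value = w$p,
    mean_in_set = mean(a), mean_background = mean(b),
    n_in_set = length(a), n_background = length(b),
    n_excluded_nonfinite = n_excluded
  )
}

#' Enrichment report across gene sets
#'
#' Computes [dose_f_statistics()] once for the experiment, then scores each
#' gene set with [gene_set_enrichment()]. Rows are sorted by p-value
#' ascending. Raw p-values are reported; set `adjust = TRUE` for an
#' additional Benjamini-Hochberg `p_adjusted` column.
#'
#' @param exp A [dose_experiment()].
#' @param sets Named list of gene symbol vectors, or a gene-set tibble as
#'   returned by [read_gmt()] (columns `set`, `genes`).
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column.
#' @inheritParams gene_set_enrichment
#' @return A tibble of class `enrichment_tbl`, one row per gene set.
#' @export
enrichment_report <- function(exp, sets,
                              alternative = c("greater", "two.sided"),
                              background = c("all", "rest"),
                              adjust = FALSE) {
  alternative <- rlang::arg_match(alternative)
  background <- rlang::arg_match(background)
  sets <- as_gene_set_list(sets)
  empty <- tibble(
    set_name = character(), t_statistic = double(), df = double(),
    p_value = double(), mean_in_set = double(), mean_background = double(),
    n_in_set = integer(), n_background = integer(),
    n_excluded_nonfinite = integer()
  )
  if (length(sets) == 0L) {
    return(structure(empty, class = c("enrichment_tbl", class(empty))))
  }
  fstats <- dose_f_statistics(exp)
  out <- purrr::imap_dfr(sets, function(genes, nm) {
    gene_set_enrichment(fstats, genes, nm,
                        alternative = alternative, background = background)
  })
  out <- dplyr::arrange(out, .data$p_value)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  structure(out, class = c("enrichment_tbl", class(out)))
}

# Accept either a named list of character vectors or a tibble with
# `set`/`genes` columns (the read_gmt() shape).
as_gene_set_list <- function(sets) {
  if (is.data.frame(sets)) {
    if (!all(c("set", "genes") %in% names(sets))) {
      abort("gene-set data frame needs columns `set` and `genes`")
    }
    return(setNames(lapply(sets$genes, as.character), sets$set))
  }
  if (!is.list(sets)) abort("`sets` must be a named list or gene-set tibble")
  if (length(sets) && is.null(names(sets))) abort("`sets` must be named")
  sets
}
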