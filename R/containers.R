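#' Expression study container
#'
#' Bundles a probe/gene-by-sample matrix of log2 intensities with per-sample
#' metadata and an optional probe-to-gene map. This is the unit of
#' preprocessing: technical replicates are collapsed by median, biological
#' replicates by median, and conditions are standardized to their matched
#' controls to give log2 fold changes.
#'
#' @param values Numeric matrix, probes (or genes) in rows, samples in
#'   columns; rownames and colnames required. Values are log2 intensities.
#' @param samples Data frame of per-sample metadata with at least columns
#'   `sample` and `condition`; recognised optional columns are `study`,
#'   `dose`, `timepoint`, `is_control` (logical) and `replicate`. Every
#'   sample in the matrix must appear exactly once and vice versa.
#' @param probe_to_gene Optional data frame with columns `probe`, `gene`
#'   mapping row ids to gene symbols. A probe may map to several symbols
#'   (multi-mapping probes are assigned to each symbol before the per-gene
#'   median collapse). `NULL` means rows are already gene symbols.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, samples, probe_to_gene = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have rownames (probes/genes) and colnames (samples)")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` contains missing or non-finite entries; impute or drop before ingestion")
  }
  assert_unique(rownames(values), "row ids")
  assert_unique(colnames(values), "sample ids")
  samples <- as_tibble(samples)
  if (!all(c("sample", "condition") %in% names(samples))) {
    abort("`samples` needs columns `sample` and `condition`")
  }
  for (col in c("study", "dose", "timepoint", "replicate")) {
    if (!col %in% names(samples)) samples[[col]] <- NA
  }
  if (!"is_control" %in% names(samples)) samples$is_control <- FALSE
  samples$is_control <- as.logical(samples$is_control)
  if (anyNA(samples$is_control)) abort("`is_control` must be TRUE/FALSE")
  if (!setequal(samples$sample, colnames(values)) ||
      nrow(samples) != ncol(values)) {
    abort("sample metadata and matrix columns must match one-to-one")
  }
  samples <- samples[match(colnames(values), samples$sample), ]
  if (!is.null(probe_to_gene)) {
    probe_to_gene <- as_tibble(probe_to_gene)
    if (!all(c("probe", "gene") %in% names(probe_to_gene))) {
      abort("`probe_to_gene` needs columns `probe` and `gene`")
    }
  }
  structure(
    list(values = values, samples = samples, probe_to_gene = probe_to_gene),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %d rows x %d samples (%d control)\n",
    nrow(x$values), ncol(x$values), sum(x$samples$is_control)
  ))
  cat(sprintf(
    "  conditions: %s\n",
    paste(utils::head(unique(x$samples$condition), 6L), collapse = ", ")
  ))
  invisible(x)
}

#' Fold-change matrix container
#'
#' Gene-by-condition log2 fold changes versus matched controls: the substrate
#' of the discovery phase. Control conditions are never present. Column names
#' are `study|condition` so that conditions from different studies stay
#' distinct after a merge.
#'
#' @param values Numeric matrix of log2 fold changes, genes in rows,
#'   conditions in columns.
#' @param conditions Data frame with columns `condition_id` (matching
#'   colnames), `study`, `condition`.
#' @return Object of class `fold_change_matrix`.
#' @export
fold_change_matrix <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (any(is.nan(values)) || any(is.infinite(values))) {
    abort("fold changes must be finite (NA allowed only for union merges)")
  }
  assert_unique(rownames(values), "gene symbols")
  assert_unique(colnames(values), "condition ids")
  conditions <- as_tibble(conditions)
  if (!all(c("condition_id", "study", "condition") %in% names(conditions))) {
    abort("`conditions` needs columns `condition_id`, `study`, `condition`")
  }
  if (!identical(sort(conditions$condition_id), sort(colnames(values)))) {
    abort("`conditions$condition_id` must match matrix columns")
  }
  conditions <- conditions[match(colnames(values), conditions$condition_id), ]
  structure(
    list(values = values, conditions = conditions),
    class = "fold_change_matrix"
  )
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat(sprintf(
    "<fold_change_matrix> %d genes x %d conditions from %d study(ies)\n",
    nrow(x$values), ncol(x$values), length(unique(x$conditions$study))
  ))
  invisible(x)
}

#' @rdname fold_change_matrix
#' @param x A `fold_change_matrix`.
#' @param ... Unused.
#' @export
tidy.fold_change_matrix <- function(x, ...) {
  out <- matrix_to_long(x$values, "condition_id")
  names(out)[names(out) == "value"] <- "log2fc"
  dplyr::left_join(out, x$conditions, by = "condition_id")
}

#' Dose-response experiment container
#'
#' A gene-by-sample log2 expression matrix with a dose group label per
#' sample, the substrate of the enrichment phase. Doses are treated as
#' unordered groups (the dose effect is tested with an overall one-way
#' ANOVA F, not a trend test), so labels may be any strings.
#'
#' @param values Numeric gene-by-sample matrix (log2 scale), dimnames
#'   required.
#' @param doses Either a named character vector (names = samples) or a data
#'   frame with columns `sample`, `dose`.
#' @return Object of class `dose_experiment`.
#' @export
dose_experiment <- function(values, doses) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames")
  }
  if (anyNA(values)) abort("`values` contains missing entries")
  assert_unique(rownames(values), "gene symbols")
  if (is.data.frame(doses)) {
    if (!all(c("sample", "dose") %in% names(doses))) {
      abort("`doses` data frame needs columns `sample` and `dose`")
    }
    doses <- setNames(as.character(doses$dose), doses$sample)
  }
  if (is.null(names(doses)) || !setequal(names(doses), colnames(values))) {
    abort("`doses` must be named by the matrix sample names")
  }
  doses <- as.character(doses[colnames(values)])
  tab <- table(doses)
  if (length(tab) < 2L) abort("need at least 2 distinct dose groups")
  if (any(tab < 2L)) {
    abort(sprintf(
      "every dose group needs >= 2 samples (offending: %s)",
      paste(names(tab)[tab < 2L], collapse = ", ")
    ))
  }
  structure(
    list(values = values, doses = setNames(doses, colnames(values))),
    class = "dose_experiment"
  )
}

#' @export
print.dose_experiment <- function(x, ...) {
  tab <- table(x$doses)
  cat(sprintf(
    "<dose_experiment> %d genes x %d samples; doses: %s\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", ")
  ))
  invisible(x)
}
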