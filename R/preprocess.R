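#' Collapse probes to gene symbols by median
#'
#' Replicate probes mapping to the same gene symbol are collapsed to a single
#' gene row by taking the per-sample median across them (for an even number
#' of probes, the mean of the two middle values). Probes with no gene symbol
#' in the map are dropped and counted; probes mapping to several gene symbols
#' contribute their value to each symbol before the per-gene median, and the
#' multi-mapping count is reported.
#'
#' @param study An [expression_study()] with a non-`NULL` `probe_to_gene`
#'   map. A study whose rows are already gene symbols (map `NULL`) is
#'   returned unchanged.
#' @param quiet Suppress the dropped/multi-mapped probe messages.
#' @return An [expression_study()] with one row per gene symbol and
#'   `probe_to_gene = NULL`.
#' @export
collapse_technical_replicates <- function(study, quiet = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  map <- study$probe_to_gene
  if (is.null(map)) {
    return(study)
  }
  map <- map[!is.na(map$gene) & map$gene != "", , drop = FALSE]
  map <- dplyr::distinct(map, .data$probe, .data$gene)
  probes <- rownames(study$values)
  unmapped <- setdiff(probes, map$probe)
  if (length(unmapped) && !quiet) {
    inform(sprintf("dropping %d probe(s) with no gene symbol", length(unmapped)))
  }
  map <- map[map$probe %in% probes, , drop = FALSE]
  if (nrow(map) == 0L) abort("no probe maps to a gene symbol")
  multi <- sum(table(map$probe) > 1L)
  if (multi > 0L && !quiet) {
    inform(sprintf("%d probe(s) map to multiple gene symbols", multi))
  }
  genes <- sort(unique(map$gene))
  rows_by_gene <- split(map$probe, map$gene)
  collapsed <- vapply(
    genes,
    function(g) apply(study$values[rows_by_gene[[g]], , drop = FALSE], 2, median),
    numeric(ncol(study$values))
  )
  # vapply drops to a vector for a single-sample study
  if (is.null(dim(collapsed))) collapsed <- matrix(collapsed, nrow = 1L)
  collapsed <- t(collapsed)
  dimnames(collapsed) <- list(genes, colnames(study$values))
  expression_study(collapsed, study$samples, probe_to_gene = NULL)
}

#' Collapse biological replicates by median
#'
#' Samples sharing a (study, condition) label are collapsed to one column
#' holding the per-gene median. A condition must be homogeneous in its
#' control flag.
#'
#' @param study An [expression_study()].
#' @return An [expression_study()] with one sample per (study, condition).
#' @export
collapse_biological_replicates <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  s <- study$samples
  key <- paste(s$study, s$condition, sep = "\r")
  groups <- split(seq_len(nrow(s)), key)
  groups <- groups[order(names(groups))] # lexicographic (study, condition)
  first <- function(x) x[1L]
  meta <- purrr::map_dfr(groups, function(idx) {
    ctl <- unique(s$is_control[idx])
    if (length(ctl) != 1L) {
      abort(sprintf(
        "condition '%s' mixes control and non-control samples",
        s$condition[idx[1L]]
      ))
    }
    tibble(
      sample = paste(s$study[idx[1L]], s$condition[idx[1L]], sep = "|"),
      study = s$study[idx[1L]],
      condition = s$condition[idx[1L]],
      dose = first(s$dose[idx]),
      timepoint = first(s$timepoint[idx]),
      is_control = ctl,
      replicate = NA_integer_
    )
  })
  vals <- vapply(
    groups,
    function(idx) apply(study$values[, idx, drop = FALSE], 1, median),
    numeric(nrow(study$values))
  )
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(study$values))
  dimnames(vals) <- list(rownames(study$values), meta$sample)
  expression_study(vals, meta, probe_to_gene = study$probe_to_gene)
}

#' Log2 fold change of each condition versus its matched control
#'
#' Collapses replicates (probes by median, then biological replicates by
#' median), subtracts the matched control condition's per-gene median from
#' each experimental condition's median, and drops the control columns:
#' `value(g, c) = median_log2(g, c) - median_log2(g, control(c))`.
#'
#' @param study An [expression_study()]; may still carry probe rows and
#'   replicate samples, which are collapsed first.
#' @param control_map Named character vector mapping condition label to the
#'   control condition label within the same study. Default `NULL`: each
#'   study must have exactly one control condition (per its `is_control`
#'   flags), which is matched to all of its experimental conditions. A
#'   condition without a resolvable control is a hard error naming it.
#' @param quiet Passed to [collapse_technical_replicates()].
#' @return A [fold_change_matrix()] with condition ids `study|condition`.
#' @export
fold_change_vs_control <- function(study, control_map = NULL, quiet = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  study <- collapse_technical_replicates(study, quiet = quiet)
  study <- collapse_biological_replicates(study)
  s <- study$samples
  out_cols <- which(!s$is_control)
  if (length(out_cols) == 0L) abort("no experimental (non-control) conditions")
  ctrl_of <- character(length(out_cols))
  for (i in seq_along(out_cols)) {
    row <- s[out_cols[i], ]
    if (!is.null(control_map) && row$condition %in% names(control_map)) {
      ctrl_cond <- unname(control_map[[row$condition]])
    } else {
      in_study_ctrl <- s$condition[s$is_control & s$study == row$study]
      if (length(in_study_ctrl) != 1L) {
        abort(sprintf(
          "condition '%s' (study '%s') has no unambiguous control; supply `control_map`",
          row$condition, row$study
        ))
      }
      ctrl_cond <- in_study_ctrl
    }
    j <- which(s$study == row$study & s$condition == ctrl_cond)
    if (length(j) != 1L) {
      abort(sprintf(
        "control condition '%s' for condition '%s' not found in study '%s'",
        ctrl_cond, row$condition, row$study
      ))
    }
    ctrl_of[i] <- s$sample[j]
  }
  fc <- study$values[, s$sample[out_cols], drop = FALSE] -
    study$values[, ctrl_of, drop = FALSE]
  conds <- tibble(
    condition_id = paste(s$study[out_cols], s$condition[out_cols], sep = "|"),
    study = s$study[out_cols],
    condition = s$condition[out_cols]
  )
  colnames(fc) <- conds$condition_id
  fold_change_matrix(fc, conds)
}

#' Merge fold-change matrices from several studies on gene symbol
#'
#' The merged gene universe is the intersection of the studies' gene symbols
#' (set `genes = "union"` to keep every symbol; conditions that did not
#' measure a gene then carry `NA`). Columns are the union of all conditions,
#' tagged with study provenance and sorted lexicographically by
#' (study, condition) so downstream binarization is reproducible. Gene
#' symbols are matched case-sensitively unless `fold_case = TRUE` uppercases
#' them first.
#'
#' @param studies List of [fold_change_matrix()] objects (>= 1).
#' @param genes `"intersect"` (default) or `"union"`.
#' @param fold_case Uppercase gene symbols before matching.
#' @param quiet Suppress the merged-gene-count message.
#' @return A [fold_change_matrix()].
#' @export
merge_studies <- function(studies, genes = c("intersect", "union"),
                          fold_case = FALSE, quiet = FALSE) {
  genes <- rlang::arg_match(genes)
  if (inherits(studies, "fold_change_matrix")) studies <- list(studies)
  if (length(studies) == 0L) abort("need at least one study")
  stopifnot(all(vapply(studies, inherits, TRUE, "fold_change_matrix")))
  gene_sets <- lapply(studies, function(x) {
    g <- rownames(x$values)
    if (fold_case) toupper(g) else g
  })
  universe <- if (genes == "intersect") {
    Reduce(intersect, gene_sets)
  } else {
    Reduce(union, gene_sets)
  }
  if (length(universe) == 0L) abort("no gene symbol shared by all studies")
  universe <- sort(universe)
  pieces <- lapply(seq_along(studies), function(i) {
    v <- studies[[i]]$values
    if (fold_case) rownames(v) <- toupper(rownames(v))
    out <- matrix(NA_real_, length(universe), ncol(v),
                  dimnames = list(universe, colnames(v)))
    shared <- intersect(universe, rownames(v))
    out[shared, ] <- v[shared, , drop = FALSE]
    out
  })
  vals <- do.call(cbind, pieces)
  conds <- dplyr::bind_rows(lapply(studies, `[[`, "conditions"))
  ord <- order(conds$study, conds$condition)
  vals <- vals[, ord, drop = FALSE]
  conds <- conds[ord, ]
  conds$condition_id <- make.unique(conds$condition_id, sep = "#")
  colnames(vals) <- conds$condition_id
  if (!quiet) {
    inform(sprintf(
      "merged %d study object(s): %d gene symbols, %d conditions",
      length(studies), length(universe), ncol(vals)
    ))
  }
  fold_change_matrix(vals, conds)
}
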