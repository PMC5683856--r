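# TSV / GMT / JSON readers and writers. Dialects: tab-separated UTF-8, no
# quoting of gene symbols, genes in rows with a leading "gene" column;
# symbols are case-sensitive throughout.

#' Read / write a gene-by-column expression or fold-change TSV
#'
#' The matrix dialect is tab-separated with genes in rows: the first column
#' is named `gene`, remaining columns are samples or conditions.
#'
#' @param path File path.
#' @return `read_matrix_tsv()`: a numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1L] != "gene") abort("first column of a matrix TSV must be `gene`")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("non-numeric values in %s", path))
  rownames(m) <- df$gene
  m
}

#' @rdname read_matrix_tsv
#' @param m Numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write sample metadata TSV
#'
#' Columns: `sample`, `study`, `condition`, `dose`, `timepoint`,
#' `is_control`, `replicate`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(), study = readr::col_character(),
      condition = readr::col_character(), dose = readr::col_character(),
      timepoint = readr::col_character(), is_control = readr::col_logical(),
      replicate = readr::col_integer()
    ),
    progress = FALSE
  )
  need <- c("sample", "condition")
  if (!all(need %in% names(df))) {
    abort("metadata TSV needs at least `sample` and `condition` columns")
  }
  df
}

#' @rdname read_sample_metadata
#' @param samples Data frame of sample metadata.
#' @export
write_sample_metadata <- function(samples, path) {
  readr::write_tsv(as_tibble(samples), path, progress = FALSE)
  invisible(path)
}

#' Read / write an expression study (matrix TSV + metadata TSV)
#'
#' @param expr_path,meta_path,probe_map_path Paths to the matrix TSV, the
#'   sample-metadata TSV and (optionally) a two-column probe-to-gene TSV
#'   (columns `probe`, `gene`).
#' @return An [expression_study()].
#' @export
read_expression_study <- function(expr_path, meta_path, probe_map_path = NULL) {
  values <- read_matrix_tsv(expr_path)
  samples <- read_sample_metadata(meta_path)
  map <- NULL
  if (!is.null(probe_map_path)) {
    map <- readr::read_tsv(probe_map_path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("probe", "gene") %in% names(map))) {
      abort("probe map TSV needs columns `probe` and `gene`")
    }
  }
  expression_study(values, samples, map)
}

#' @rdname read_expression_study
#' @param study An [expression_study()].
#' @export
write_expression_study <- function(study, expr_path, meta_path,
                                   probe_map_path = NULL) {
  write_matrix_tsv(study$values, expr_path)
  write_sample_metadata(study$samples, meta_path)
  if (!is.null(probe_map_path) && !is.null(study$probe_to_gene)) {
    readr::write_tsv(study$probe_to_gene, probe_map_path, progress = FALSE)
  }
  invisible(expr_path)
}

#' Read / write a fold-change matrix TSV
#'
#' Condition ids in the header follow the `study|condition` convention;
#' study provenance is recovered from the id.
#'
#' @param path File path.
#' @return A [fold_change_matrix()].
#' @export
read_fold_changes <- function(path) {
  m <- read_matrix_tsv(path)
  ids <- colnames(m)
  fold_change_matrix(m, tibble(
    condition_id = ids,
    study = sub("\\|.*$", "", ids),
    condition = sub("^[^|]*\\|", "", ids)
  ))
}

#' @rdname read_fold_changes
#' @param fc A [fold_change_matrix()].
#' @export
write_fold_changes <- function(fc, path) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  write_matrix_tsv(fc$values, path)
}

#' Read a GMT gene-set file
#'
#' Standard Gene Matrix Transposed format: one set per line with
#' tab-separated name, description, then member genes. Duplicate genes
#' within a set are removed with a warning; a line with fewer than three
#' fields is a hard error naming the line.
#'
#' @param path File path.
#' @return A tibble with columns `set`, `description` and `genes`
#'   (list-column of character vectors); zero rows for an empty file.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(set = character(), description = character(), genes = list()))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(sprintf(
        "GMT set '%s': %d duplicate gene(s) removed",
        fields[1L], sum(duplicated(genes))
      ))
      genes <- unique(genes)
    }
    list(set = fields[1L], description = fields[2L], genes = genes)
  })
  tibble(
    set = vapply(parsed, `[[`, "", "set"),
    description = vapply(parsed, `[[`, "", "description"),
    genes = lapply(parsed, `[[`, "genes")
  )
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors, or a tibble with `set`,
#'   `description` (optional) and `genes` columns.
#' @export
write_gmt <- function(sets, path) {
  if (is.data.frame(sets)) {
    nm <- sets$set
    desc <- if ("description" %in% names(sets)) sets$description else rep("na", nrow(sets))
    genes <- sets$genes
  } else {
    nm <- names(sets)
    desc <- rep("na", length(sets))
    genes <- sets
  }
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[[i]], desc[[i]], unique(as.character(genes[[i]]))), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Export biclusters as JSON, GMT and plain gene lists
#'
#' `write_biclusters_json()` writes the bicluster tibble as a JSON array of
#' `{bicluster, direction, rows, cols}` objects; `read_biclusters_json()`
#' reads it back. `write_gene_lists()` writes one plain-text file per
#' bicluster (one gene symbol per line), the paste-ready format expected by
#' functional-annotation web tools.
#'
#' @param biclusters A bicluster tibble from [bimax()]/[run_discovery()].
#' @param path,dir Output file / directory.
#' @return The path(s), invisibly.
#' @export
write_biclusters_json <- function(biclusters, path) {
  recs <- lapply(seq_len(nrow(biclusters)), function(i) {
    list(
      bicluster = biclusters$bicluster[[i]],
      direction = biclusters$direction[[i]],
      rows = as.character(biclusters$genes[[i]]),
      cols = as.character(biclusters$conditions[[i]])
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_biclusters_json
#' @export
read_biclusters_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  tibble(
    bicluster = vapply(recs, function(r) as.integer(r$bicluster), 0L),
    direction = vapply(recs, function(r) {
      if (is.null(r$direction)) NA_character_ else as.character(r$direction)
    }, ""),
    n_genes = vapply(recs, function(r) length(r$rows), 0L),
    n_conditions = vapply(recs, function(r) length(r$cols), 0L),
    genes = lapply(recs, function(r) as.character(unlist(r$rows))),
    conditions = lapply(recs, function(r) as.character(unlist(r$cols)))
  )
}

#' @rdname write_biclusters_json
#' @export
write_gene_lists <- function(biclusters, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_len(nrow(biclusters)), function(i) {
    dir_tag <- biclusters$direction[[i]]
    tag <- if (is.na(dir_tag)) "" else paste0("_", dir_tag)
    p <- file.path(dir, sprintf("bicluster_%02d%s.txt", biclusters$bicluster[[i]], tag))
    readr::write_lines(biclusters$genes[[i]], p)
    p
  }, "")
  invisible(paths)
}

#' Convert biclusters to a named gene-set list
#'
#' @param biclusters A bicluster tibble.
#' @return Named list of gene vectors (`bicluster_01_up`, ...), ready for
#'   [enrichment_report()] or [write_gmt()].
#' @export
biclusters_as_gene_sets <- function(biclusters) {
  if (nrow(biclusters) == 0L) return(list())
  nm <- sprintf(
    "bicluster_%02d%s", biclusters$bicluster,
    ifelse(is.na(biclusters$direction), "", paste0("_", biclusters$direction))
  )
  setNames(biclusters$genes, nm)
}

#' Read / write a dose experiment (matrix TSV + metadata with a dose column)
#'
#' @param expr_path,meta_path Paths to the matrix TSV and a metadata TSV
#'   containing `sample` and `dose` columns.
#' @return A [dose_experiment()].
#' @export
read_dose_experiment <- function(expr_path, meta_path) {
  values <- read_matrix_tsv(expr_path)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "dose") %in% names(meta))) {
    abort("dose metadata TSV needs `sample` and `dose` columns")
  }
  dose_experiment(values, setNames(as.character(meta$dose), meta$sample))
}

#' @rdname read_dose_experiment
#' @param exp A [dose_experiment()].
#' @export
write_dose_experiment <- function(exp, expr_path, meta_path) {
  write_matrix_tsv(exp$values, expr_path)
  readr::write_tsv(
    tibble(sample = names(exp$doses), dose = unname(exp$doses)),
    meta_path, progress = FALSE
  )
  invisible(expr_path)
}

#' Write an enrichment report TSV
#'
#' @param report An `enrichment_tbl` from [enrichment_report()].
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(report, path) {
  readr::write_tsv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}
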