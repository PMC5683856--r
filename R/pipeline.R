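#' Assemble a pipeline configuration
#'
#' Collects everything one end-to-end run needs: either a simulation recipe
#' (compendium with planted biclusters + a dose design) or paths to on-disk
#' inputs, plus bicluster-search parameters and enrichment flags. The
#' configuration is plain data, so it can be written to / read from YAML and
#' hashed for provenance.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param simulate `NULL`, or a list with `n_genes`, `n_conditions`,
#'   `noise_sd` and `planted` — a list of blocks, each
#'   `list(genes = <count>, conditions = <count>, direction = "up"|"down",
#'   effect_mean =, effect_sd =)`. Blocks are carved from disjoint
#'   consecutive label ranges.
#' @param dose `NULL`, or a list of [dose_design()] arguments (minus the
#'   seed, which is derived).
#' @param input `NULL`, or a list of paths: `expr`, `meta`, optional
#'   `probe_map` (discovery inputs) and/or `dose_expr`, `dose_meta`,
#'   optional `sets` GMT (application inputs).
#' @param min_rows,min_cols,max_cols Bicluster size constraints.
#' @param threshold_log2 Binarization threshold.
#' @param alternative,background,adjust Enrichment flags, see
#'   [enrichment_report()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            simulate = NULL, dose = NULL, input = NULL,
                            min_rows = 15L, min_cols = 5L, max_cols = 15L,
                            threshold_log2 = 1,
                            alternative = "greater", background = "all",
                            adjust = FALSE) {
  if (is.null(simulate) && is.null(input)) {
    abort("config needs either `simulate` or `input`")
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed),
      simulate = simulate, dose = dose, input = input,
      min_rows = as.integer(min_rows), min_cols = as.integer(min_cols),
      max_cols = as.integer(max_cols),
      threshold_log2 = as.numeric(threshold_log2),
      alternative = alternative, background = background,
      adjust = isTRUE(adjust)
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML file holding the fields above.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# Carve disjoint planted blocks out of consecutive gene/condition ranges.
planted_from_spec <- function(spec, n_genes, n_conditions) {
  g_at <- 0L
  c_at <- 0L
  genes <- default_genes(n_genes)
  conds <- default_conditions(n_conditions)
  lapply(spec, function(b) {
    ng <- assert_count(b$genes, "planted genes")
    nc <- assert_count(b$conditions, "planted conditions")
    if (g_at + ng > n_genes || c_at + nc > n_conditions) {
      abort("planted blocks exceed matrix dimensions")
    }
    pb <- planted_bicluster(
      genes = genes[(g_at + 1L):(g_at + ng)],
      conditions = conds[(c_at + 1L):(c_at + nc)],
      direction = b$direction %||% "up",
      effect_mean = b$effect_mean,
      effect_sd = b$effect_sd %||% 0.2
    )
    g_at <<- g_at + ng
    c_at <<- c_at + nc
    pb
  })
}

#' Run the two-phase pipeline end to end
#'
#' Discovery: obtain a fold-change compendium (simulated, or preprocessed
#' from on-disk study files), binarize up and down at the 2-fold threshold
#' and enumerate maximal biclusters. Application: obtain a dose experiment
#' (simulated with the first planted gene set responsive, or read from
#' disk), then score the discovered bicluster gene sets (plus the planted
#' truth set, when simulating) for dose-effect enrichment. All artifacts are
#' written under `config$out_dir` with a `provenance.json` sidecar carrying
#' the config hash, seed and package version; a rerun with an identical
#' config is byte-identical.
#'
#' @param config A [pipeline_config()] or the path to its YAML file.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory results (`fc`, `truth`,
#'   `biclusters`, `experiment`, `enrichment`) and `paths` of the written
#'   artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  paths <- list()
  truth <- NULL
  dose_truth <- NULL

  # --- discovery substrate -------------------------------------------------
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    planted <- planted_from_spec(
      sm$planted %||% list(), sm$n_genes, sm$n_conditions
    )
    cfg <- sim_config(
      n_genes = sm$n_genes, n_conditions = sm$n_conditions,
      noise_sd = sm$noise_sd %||% 0.2, planted = planted,
      seed = derive_seed(config$seed, 1L)
    )
    comp <- simulate_compendium(cfg)
    fc <- comp$fc
    truth <- comp$truth
    paths$truth <- file.path(config$out_dir, "planted_truth.json")
    write_biclusters_json(
      dplyr::mutate(
        truth,
        n_genes = lengths(.data$genes),
        n_conditions = lengths(.data$conditions)
      ),
      paths$truth
    )
    say("simulated compendium: %d genes x %d conditions, %d planted bicluster(s)",
        nrow(fc$values), ncol(fc$values), nrow(truth))
  } else {
    inp <- config$input
    if (!is.null(inp$expr)) {
      study <- read_expression_study(inp$expr, inp$meta, inp$probe_map)
      fc <- fold_change_vs_control(study, quiet = quiet)
    } else if (!is.null(inp$fc)) {
      fc <- read_fold_changes(inp$fc)
    } else {
      fc <- NULL
    }
  }

  biclusters <- NULL
  if (!is.null(fc)) {
    paths$fold_changes <- file.path(config$out_dir, "fold_changes.tsv")
    write_fold_changes(fc, paths$fold_changes)
    biclusters <- run_discovery(
      fc,
      min_rows = config$min_rows, min_cols = config$min_cols,
      max_cols = config$max_cols, threshold_log2 = config$threshold_log2
    )
    say("discovery: %d bicluster(s) (%d up, %d down)",
        nrow(biclusters), sum(biclusters$direction == "up"),
        sum(biclusters$direction == "down"))
    paths$biclusters <- file.path(config$out_dir, "biclusters.json")
    write_biclusters_json(biclusters, paths$biclusters)
    paths$gmt <- file.path(config$out_dir, "biclusters.gmt")
    write_gmt(biclusters_as_gene_sets(biclusters), paths$gmt)
    paths$gene_lists <- file.path(config$out_dir, "gene_lists")
    write_gene_lists(biclusters, paths$gene_lists)
  }

  # --- application phase ---------------------------------------------------
  experiment <- NULL
  enr <- NULL
  sets <- list()
  if (!is.null(biclusters) && nrow(biclusters) > 0L) {
    sets <- biclusters_as_gene_sets(biclusters)
  }
  if (!is.null(config$dose) && !is.null(config$simulate)) {
    dd <- do.call(dose_design, modifyList(
      config$dose %||% list(), list(seed = derive_seed(config$seed, 2L))
    ))
    responsive <- if (!is.null(truth) && nrow(truth) > 0L) {
      truth$genes[[1L]]
    } else {
      NULL
    }
    sim <- simulate_dose_experiment(
      n_genes = config$simulate$n_genes, design = dd,
      universe = rownames(fc$values), responsive_genes = responsive
    )
    experiment <- sim$experiment
    dose_truth <- sim$truth
    sets <- c(sets, setNames(dose_truth$genes, paste0("planted_", dose_truth$set)))
  } else if (!is.null(config$input$dose_expr)) {
    experiment <- read_dose_experiment(
      config$input$dose_expr, config$input$dose_meta
    )
    if (!is.null(config$input$sets)) {
      sets <- c(sets, as_gene_set_list(read_gmt(config$input$sets)))
    }
  }
  if (!is.null(experiment) && length(sets) > 0L) {
    paths$dose_expr <- file.path(config$out_dir, "dose_experiment.tsv")
    paths$dose_meta <- file.path(config$out_dir, "dose_metadata.tsv")
    write_dose_experiment(experiment, paths$dose_expr, paths$dose_meta)
    enr <- enrichment_report(
      experiment, sets,
      alternative = config$alternative, background = config$background,
      adjust = config$adjust
    )
    paths$enrichment <- file.path(config$out_dir, "enrichment.tsv")
    write_enrichment_tsv(enr, paths$enrichment)
    say("application: %d gene set(s) scored; top set '%s' (p = %.3g)",
        nrow(enr), enr$set_name[[1L]], enr$p_value[[1L]])
    # ordered heatmap matrix for the top-ranked set
    top_genes <- sets[[enr$set_name[[1L]]]]
    hm <- tryCatch(
      ordered_heatmap_matrix(experiment, top_genes),
      error = function(e) NULL
    )
    if (!is.null(hm)) {
      paths$heatmap_matrix <- file.path(config$out_dir, "heatmap_top_set.tsv")
      write_matrix_tsv(hm$values, paths$heatmap_matrix)
    }
  }

  # --- provenance sidecar --------------------------------------------------
  prov <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package = "biclustsig",
    version = as.character(utils::packageVersion("biclustsig")),
    artifacts = lapply(paths, basename)
  )
  paths$provenance <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    fc = fc, truth = truth, biclusters = biclusters,
    experiment = experiment, dose_truth = dose_truth, enrichment = enr,
    paths = paths
  ))
}
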