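#' Describe a planted bicluster
#'
#' A planted bicluster is a block of (gene, condition) cells whose log2 fold
#' changes are drawn around a common effect mean, emulating a coordinated
#' up- or down-regulation signature shared across exposure conditions. A
#' fixture is "recoverable" at the default 2-fold binarization threshold when
#' `|effect_mean| - 2 * effect_sd >= 1`, so planted cells clear the threshold
#' with high probability.
#'
#' @param genes Character vector of member gene symbols (unique, non-empty).
#' @param conditions Character vector of member condition ids (unique,
#'   non-empty).
#' @param direction `"up"` or `"down"`.
#' @param effect_mean Mean log2 fold change of planted cells; must be > 0 for
#'   `"up"`, < 0 for `"down"`. Defaults to +2 / -2 (a 4-fold effect, the
#'   recoverable regime used throughout the test fixtures).
#' @param effect_sd Standard deviation of planted cells (log2 units).
#' @return A `planted_bicluster` list.
#' @export
planted_bicluster <- function(genes, conditions,
                              direction = c("up", "down"),
                              effect_mean = NULL, effect_sd = 0.2) {
  direction <- rlang::arg_match(direction)
  if (length(genes) == 0L || length(conditions) == 0L) {
    abort("planted bicluster needs non-empty `genes` and `conditions`")
  }
  assert_unique(genes, "planted genes")
  assert_unique(conditions, "planted conditions")
  if (is.null(effect_mean)) effect_mean <- if (direction == "up") 2 else -2
  effect_mean <- assert_number(effect_mean, "effect_mean")
  effect_sd <- assert_number(effect_sd, "effect_sd", min = 0)
  if (direction == "up" && effect_mean <= 0) {
    abort("`effect_mean` must be > 0 for an up bicluster")
  }
  if (direction == "down" && effect_mean >= 0) {
    abort("`effect_mean` must be < 0 for a down bicluster")
  }
  structure(
    list(
      genes = as.character(genes), conditions = as.character(conditions),
      direction = direction, effect_mean = effect_mean, effect_sd = effect_sd
    ),
    class = "planted_bicluster"
  )
}

#' Simulation configuration for a fold-change compendium
#'
#' @param n_genes,n_conditions Matrix dimensions. Gene symbols are
#'   `g0001, ...`, condition ids `study1|cond01, ...` unless planted
#'   biclusters name others.
#' @param noise_sd Standard deviation of the Gaussian background on the log2
#'   fold-change scale (default 0.2; log-scale Gaussian noise is the standard
#'   model for array log intensities).
#' @param planted List of [planted_bicluster()] objects. Overlapping blocks
#'   are allowed; later entries overwrite earlier ones (last-writer-wins).
#' @param seed Integer seed; a fixed seed makes the output bit-reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes, n_conditions, noise_sd = 0.2,
                       planted = list(), seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_conditions <- assert_count(n_conditions, "n_conditions")
  noise_sd <- assert_number(noise_sd, "noise_sd", min = 0)
  if (!is.list(planted) || !all(vapply(planted, inherits, TRUE, "planted_bicluster"))) {
    abort("`planted` must be a list of planted_bicluster objects")
  }
  for (pb in planted) {
    if (length(pb$genes) > n_genes) abort("planted gene set larger than `n_genes`")
    if (length(pb$conditions) > n_conditions) {
      abort("planted condition set larger than `n_conditions`")
    }
  }
  structure(
    list(
      n_genes = n_genes, n_conditions = n_conditions, noise_sd = noise_sd,
      planted = planted, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

default_genes <- function(n) sprintf("g%04d", seq_len(n))
default_conditions <- function(n) sprintf("study1|cond%02d", seq_len(n))

# Resolve the gene/condition universes of a config: named planted members
# must exist, extra labels are generated.
sim_universe <- function(config) {
  genes <- unique(unlist(lapply(config$planted, `[[`, "genes")))
  conds <- unique(unlist(lapply(config$planted, `[[`, "conditions")))
  if (length(genes) > config$n_genes || length(conds) > config$n_conditions) {
    abort("planted labels exceed the configured matrix dimensions")
  }
  all_genes <- union(genes, setdiff(default_genes(config$n_genes), genes))
  all_genes <- sort(all_genes[seq_len(config$n_genes)])
  all_conds <- union(conds, setdiff(default_conditions(config$n_conditions), conds))
  all_conds <- sort(all_conds[seq_len(config$n_conditions)])
  assert_unique(all_genes, "gene labels")
  assert_unique(all_conds, "condition labels")
  list(genes = all_genes, conditions = all_conds)
}

#' Simulate a multi-study fold-change compendium with planted biclusters
#'
#' Background cells are Normal(0, noise_sd^2); each planted cell is
#' Normal(effect_mean, effect_sd^2). When planted blocks overlap, the last
#' entry in `config$planted` wins. The ground truth is returned alongside so
#' that downstream recovery (binarize + bimax) can be scored.
#'
#' @param config A [sim_config()].
#' @return A list with `fc` (a [fold_change_matrix()]) and `truth`, a tibble
#'   with one row per planted bicluster (columns `bicluster`, `direction`,
#'   `genes`, `conditions`; the last two are list-columns).
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  uni <- sim_universe(config)
  values <- local_seed(config$seed, {
    m <- matrix(
      stats::rnorm(config$n_genes * config$n_conditions, 0, config$noise_sd),
      nrow = config$n_genes,
      dimnames = list(uni$genes, uni$conditions)
    )
    for (pb in config$planted) {
      bad_g <- setdiff(pb$genes, uni$genes)
      bad_c <- setdiff(pb$conditions, uni$conditions)
      if (length(bad_g) || length(bad_c)) {
        abort("planted bicluster references labels outside the matrix universe")
      }
      block <- matrix(
        stats::rnorm(length(pb$genes) * length(pb$conditions),
                     pb$effect_mean, pb$effect_sd),
        nrow = length(pb$genes)
      )
      m[pb$genes, pb$conditions] <- block
    }
    m
  })
  conds <- tibble(
    condition_id = uni$conditions,
    study = sub("\\|.*$", "", uni$conditions),
    condition = sub("^[^|]*\\|", "", uni$conditions)
  )
  truth <- tibble(
    bicluster = seq_along(config$planted),
    direction = vapply(config$planted, `[[`, "", "direction"),
    genes = lapply(config$planted, function(p) sort(p$genes)),
    conditions = lapply(config$planted, function(p) sort(p$conditions))
  )
  list(fc = fold_change_matrix(values, conds), truth = truth)
}

#' Dose-experiment design
#'
#' Describes a multi-dose exposure experiment with replicate samples in which
#' one gene set carries a dose effect. Defaults mirror a typical
#' intratracheal-instillation design: vehicle control plus 18, 54 and 162 µg
#' doses, three replicate animals per dose. The default per-dose shifts
#' (0, 1, 2, 3 log2 units) with residual SD 0.5 are the package's power
#' fixture. Dose labels are categorical groups; shifts need not be monotone.
#'
#' @param dose_levels Ordered character/numeric vector of >= 2 dose labels.
#' @param replicates_per_dose Samples per dose group (>= 2, so within-group
#'   variance is defined).
#' @param per_dose_shift Mean log2 shift of responsive genes at each dose;
#'   one entry per dose level, first entry 0 (the control defines baseline).
#' @param residual_sd Residual standard deviation (log2 units, > 0).
#' @param responsive_set Name of the planted responsive gene set.
#' @param seed Integer seed.
#' @return A `dose_design` list.
#' @export
dose_design <- function(dose_levels = c("0", "18", "54", "162"),
                        replicates_per_dose = 3L,
                        per_dose_shift = c(0, 1, 2, 3),
                        residual_sd = 0.5,
                        responsive_set = "responsive",
                        seed = 1L) {
  dose_levels <- as.character(dose_levels)
  if (length(dose_levels) < 2L) abort("need >= 2 dose levels")
  assert_unique(dose_levels, "dose levels")
  replicates_per_dose <- assert_count(replicates_per_dose, "replicates_per_dose", min = 2L)
  if (length(per_dose_shift) != length(dose_levels)) {
    abort("`per_dose_shift` needs one entry per dose level")
  }
  if (per_dose_shift[1L] != 0) abort("first `per_dose_shift` entry must be 0")
  residual_sd <- assert_number(residual_sd, "residual_sd", min = 0, strict = TRUE)
  structure(
    list(
      dose_levels = dose_levels,
      replicates_per_dose = replicates_per_dose,
      per_dose_shift = as.numeric(per_dose_shift),
      residual_sd = residual_sd,
      responsive_set = as.character(responsive_set),
      seed = as.integer(seed)
    ),
    class = "dose_design"
  )
}

#' Simulate a multi-dose exposure experiment with a planted responsive set
#'
#' Each sample value for gene g at dose level d is
#' `per_dose_shift[d] * (g in responsive set) + Normal(0, residual_sd^2)`.
#' With all shifts zero no gene carries a dose effect, giving a null fixture
#' for type-I-error calibration.
#'
#' @param n_genes Number of genes when `universe` is not given.
#' @param design A [dose_design()].
#' @param universe Optional character vector of gene symbols (default
#'   `g0001...`).
#' @param responsive_genes Optional explicit member genes of the responsive
#'   set (must be a subset of the universe); default: the first 50 genes (or
#'   10% of the universe if smaller).
#' @return A list with `experiment` (a [dose_experiment()]) and `truth`, a
#'   one-row tibble naming the responsive set and its genes (list-column).
#' @export
simulate_dose_experiment <- function(n_genes, design, universe = NULL,
                                     responsive_genes = NULL) {
  stopifnot(inherits(design, "dose_design"))
  if (is.null(universe)) {
    n_genes <- assert_count(n_genes, "n_genes")
    universe <- default_genes(n_genes)
  }
  universe <- as.character(universe)
  assert_unique(universe, "gene symbols")
  if (is.null(responsive_genes)) {
    k <- min(50L, max(1L, floor(length(universe) / 10)))
    responsive_genes <- universe[seq_len(k)]
  }
  if (!all(responsive_genes %in% universe)) {
    abort("`responsive_genes` must be a subset of the gene universe")
  }
  n_dose <- length(design$dose_levels)
  n_samp <- n_dose * design$replicates_per_dose
  doses <- rep(design$dose_levels, each = design$replicates_per_dose)
  sample_ids <- sprintf(
    "d%s_r%d", rep(seq_len(n_dose), each = design$replicates_per_dose),
    rep(seq_len(design$replicates_per_dose), times = n_dose)
  )
  shift_row <- rep(design$per_dose_shift, each = design$replicates_per_dose)
  values <- local_seed(design$seed, {
    m <- matrix(
      stats::rnorm(length(universe) * n_samp, 0, design$residual_sd),
      nrow = length(universe),
      dimnames = list(universe, sample_ids)
    )
    m[responsive_genes, ] <-
      m[responsive_genes, , drop = FALSE] +
      matrix(shift_row, nrow = length(responsive_genes),
             ncol = n_samp, byrow = TRUE)
    m
  })
  truth <- tibble(
    set = design$responsive_set,
    genes = list(sort(as.character(responsive_genes)))
  )
  list(
    experiment = dose_experiment(values, setNames(doses, sample_ids)),
    truth = truth
  )
}

#' Simulate a raw expression study for exercising preprocessing
#'
#' Builds a probe-by-sample log2 intensity study whose preprocessed output
#' (median collapse of technical then biological replicates, fold change
#' versus control) reproduces [simulate_compendium()] for the same config up
#' to noise: every gene gets `tech_replicates` probes, every condition gets
#' `replicates` biological replicate samples, plus `controls` control
#' samples, around a flat baseline of 8 log2 units. At `noise_sd = 0` the
#' round trip is exact.
#'
#' @param config A [sim_config()]; its seed drives both the embedded fold
#'   changes (shared with [simulate_compendium()]) and the measurement noise.
#' @param replicates Biological replicates per condition (>= 1).
#' @param controls Number of control samples (>= 1).
#' @param tech_replicates Technical replicate probes per gene (>= 1).
#' @return An [expression_study()].
#' @export
simulate_raw_study <- function(config, replicates = 1L, controls = 1L,
                               tech_replicates = 1L) {
  stopifnot(inherits(config, "sim_config"))
  replicates <- assert_count(replicates, "replicates")
  controls <- assert_count(controls, "controls")
  tech_replicates <- assert_count(tech_replicates, "tech_replicates")
  comp <- simulate_compendium(config)
  delta <- comp$fc$values # gene x condition log2 fold changes to embed
  genes <- rownames(delta)
  cond <- comp$fc$conditions
  baseline <- 8
  studies <- unique(cond$study)
  treated <- tibble(
    study = rep(cond$study, each = replicates),
    condition = rep(cond$condition, each = replicates),
    condition_id = rep(cond$condition_id, each = replicates),
    is_control = FALSE,
    replicate = rep(seq_len(replicates), times = nrow(cond))
  )
  ctrl <- tibble(
    study = rep(studies, each = controls),
    condition = "control",
    condition_id = NA_character_,
    is_control = TRUE,
    replicate = rep(seq_len(controls), times = length(studies))
  )
  samp <- dplyr::bind_rows(ctrl, treated)
  samp$sample <- sprintf(
    "%s_%s_s%02d", gsub("[^A-Za-z0-9]", "_", samp$study),
    gsub("[^A-Za-z0-9]", "_", samp$condition), samp$replicate
  )
  samp$dose <- NA_character_
  samp$timepoint <- NA_character_
  probe_ids <- sprintf(
    "%s_p%d", rep(genes, each = tech_replicates),
    rep(seq_len(tech_replicates), times = length(genes))
  )
  probe_map <- tibble(probe = probe_ids, gene = rep(genes, each = tech_replicates))
  # gene-level target per sample: baseline (+ embedded fold change if treated)
  target <- matrix(baseline, nrow(delta), nrow(samp),
                   dimnames = list(genes, samp$sample))
  idx <- which(!samp$is_control)
  target[, idx] <- target[, idx, drop = FALSE] +
    delta[, samp$condition_id[idx], drop = FALSE]
  values <- local_seed(derive_seed(config$seed, 7L), {
    target[rep(seq_len(nrow(delta)), each = tech_replicates), , drop = FALSE] +
      matrix(
        stats::rnorm(length(probe_ids) * nrow(samp), 0, config$noise_sd),
        nrow = length(probe_ids)
      )
  })
  dimnames(values) <- list(probe_ids, samp$sample)
  samp$condition_id <- NULL
  expression_study(
    values,
    samp[, c("sample", "study", "condition", "dose", "timepoint",
             "is_control", "replicate")],
    probe_map
  )
}
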