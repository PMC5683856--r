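# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without touching the caller's RNG state.
# Every stochastic operation in the package routes through this, so a seed in
# a config fully determines the output and parallel test runs cannot interact.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic child seeds for multi-stage generators; keeps each stage's
# stream independent of the others while staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

assert_unique <- function(x, what) {
  if (anyDuplicated(x)) {
    dup <- unique(x[duplicated(x)])
    abort(sprintf(
      "duplicate %s: %s", what,
      paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  invisible(x)
}

assert_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", what, min))
  }
  as.integer(x)
}

assert_number <- function(x, what, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", what))
  }
  if (strict && x <= min) abort(sprintf("`%s` must be > %g", what, min))
  if (!strict && x < min) abort(sprintf("`%s` must be >= %g", what, min))
  as.numeric(x)
}

# Matrix with gene rownames -> long tibble (gene, <col_key>, value).
matrix_to_long <- function(m, col_key = "condition") {
  tibble(
    gene = rep(rownames(m), times = ncol(m)),
    !!col_key := rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
}
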