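# Independent oracles and fixture builders used across the suite.

# Brute-force maximal-bicluster enumeration by exhaustive column-subset
# search: for every nonempty column subset C take R(C) = rows all-ones on C
# and keep (R(C), C) iff C is exactly the set of columns all-ones on R(C).
# Deliberately naive and independent of the library's search.
brute_force_biclusters <- function(M, min_rows = 1L, min_cols = 1L,
                                   max_cols = ncol(M)) {
  stopifnot(ncol(M) <= 20L)
  res <- list()
  for (mask in seq_len(2^ncol(M) - 1L)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ncol(M)) - 1L)) != 0L)
    rows <- which(rowSums(M[, cols, drop = FALSE]) == length(cols))
    if (length(rows) == 0L) next
    closed <- unname(which(colSums(M[rows, , drop = FALSE]) == length(rows)))
    if (!identical(closed, cols)) next
    if (length(rows) >= min_rows && length(cols) >= min_cols &&
        length(cols) <= max_cols) {
      res[[length(res) + 1L]] <- list(rows = rows, cols = cols)
    }
  }
  res
}

# Canonical string form of a bicluster collection for set comparison.
bicluster_keys_from_list <- function(bcs, M) {
  sort(vapply(bcs, function(b) {
    paste(
      paste(sort(rownames(M)[b$rows]), collapse = ","),
      paste(sort(colnames(M)[b$cols]), collapse = ","),
      sep = " || "
    )
  }, ""))
}

bicluster_keys_from_tibble <- function(tb) {
  sort(vapply(seq_len(nrow(tb)), function(i) {
    paste(
      paste(tb$genes[[i]], collapse = ","),
      paste(tb$conditions[[i]], collapse = ","),
      sep = " || "
    )
  }, ""))
}

random_binary_matrix <- function(nrow, ncol, p = 0.5) {
  m <- matrix(as.integer(stats::runif(nrow * ncol) < p), nrow,
              dimnames = list(sprintf("r%02d", seq_len(nrow)),
                              sprintf("c%02d", seq_len(ncol))))
  m
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Best recovery score of a planted bicluster among found ones: the max over
# found biclusters of the smaller of the row-set and column-set Jaccard.
recovery_score <- function(truth_genes, truth_conds, found) {
  if (nrow(found) == 0L) return(0)
  max(vapply(seq_len(nrow(found)), function(i) {
    min(
      jaccard(truth_genes, found$genes[[i]]),
      jaccard(truth_conds, found$conditions[[i]])
    )
  }, 0))
}

# Standard recoverable-regime compendium used by the planted-recovery tests:
# two up blocks and one down block, disjoint, all clearing the 2-fold
# threshold by a wide margin.
recoverable_config <- function(seed, noise_sd = 0.2, effect_sd = 0.2) {
  genes <- sprintf("g%04d", 1:500)
  conds <- sprintf("study1|cond%02d", 1:20)
  planted <- list(
    planted_bicluster(genes[1:30], conds[1:8], "up",
                      effect_mean = 2, effect_sd = effect_sd),
    planted_bicluster(genes[31:50], conds[9:14], "up",
                      effect_mean = 2, effect_sd = effect_sd),
    planted_bicluster(genes[51:75], conds[15:19], "down",
                      effect_mean = -2, effect_sd = effect_sd)
  )
  sim_config(500, 20, noise_sd = noise_sd, planted = planted, seed = seed)
}

# Null and power dose fixtures (the generator defaults are the power
# fixture; the null zeroes every shift).
null_design <- function(seed) {
  dose_design(per_dose_shift = c(0, 0, 0, 0), seed = seed)
}
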