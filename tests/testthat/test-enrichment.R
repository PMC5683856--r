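make_two_group_exp <- function(values_by_group) {
  # values_by_group: list(dose_label = matrix genes x reps)
  v <- do.call(cbind, values_by_group)
  doses <- rep(names(values_by_group), vapply(values_by_group, ncol, 0L))
  colnames(v) <- sprintf("s%d", seq_len(ncol(v)))
  dose_experiment(v, stats::setNames(doses, colnames(v)))
}

test_that("the one-way F statistic matches the hand-worked example", {
  # groups {0, 2} and {3, 5}: SSB = 9, SSW = 4, df = (1, 2) -> F = 4.5
  exp <- make_two_group_exp(list(
    low = matrix(c(0, 2), 1, 2, dimnames = list("g1", NULL)),
    high = matrix(c(3, 5), 1, 2, dimnames = list("g1", NULL))
  ))
  fs <- dose_f_statistics(exp)
  expect_equal(fs$F, 4.5, tolerance = 1e-12)
  expect_identical(attr(fs, "df_between"), 1L)
  expect_identical(attr(fs, "df_within"), 2L)
  expect_equal(fs$log2F, log2(4.5), tolerance = 1e-12)
})

test_that("degenerate genes get F = 0 (flat) or F = Inf (perfect separation)", {
  v <- rbind(
    flat = c(2, 2, 2, 2),
    perfect = c(0, 0, 1, 1),
    normal = c(0, 1, 2, 4)
  )
  colnames(v) <- sprintf("s%d", 1:4)
  exp <- dose_experiment(v, stats::setNames(c("a", "a", "b", "b"), colnames(v)))
  fs <- dose_f_statistics(exp)
  expect_equal(fs$F[fs$gene == "flat"], 0)
  expect_identical(fs$F[fs$gene == "perfect"], Inf)
  expect_true(is.na(fs$log2F[fs$gene == "flat"]))
  expect_true(is.na(fs$log2F[fs$gene == "perfect"]))
  expect_equal(glance(fs)$n_nonfinite_log2F, 2L)
})

test_that("F is affine-invariant and equals t^2 in the two-group case", {
  withr::with_seed(11, {
    for (i in 1:25) {
      x <- rnorm(5)
      y <- rnorm(4, mean = 1)
      exp <- make_two_group_exp(list(
        a = matrix(x, 1, dimnames = list("g", NULL)),
        b = matrix(y, 1, dimnames = list("g", NULL))
      ))
      f <- dose_f_statistics(exp)$F
      # pooled-variance two-sample t
      tt <- stats::t.test(x, y, var.equal = TRUE)
      expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-10)
      # affine map leaves F unchanged
      a <- runif(1, 0.5, 3); b <- rnorm(1)
      exp2 <- make_two_group_exp(list(
        a = matrix(a * x + b, 1, dimnames = list("g", NULL)),
        b = matrix(a * y + b, 1, dimnames = list("g", NULL))
      ))
      expect_equal(dose_f_statistics(exp2)$F, f, tolerance = 1e-9)
    }
  })
})

test_that("vectorized F agrees with stats::oneway.test across genes and designs", {
  withr::with_seed(5, {
    for (k in 2:4) {
      n_rep <- sample(2:4, k, replace = TRUE)
      doses <- rep(sprintf("d%d", seq_len(k)), n_rep)
      v <- matrix(rnorm(30 * length(doses)), 30,
                  dimnames = list(sprintf("g%02d", 1:30),
                                  sprintf("s%d", seq_along(doses))))
      exp <- dose_experiment(v, stats::setNames(doses, colnames(v)))
      fs <- dose_f_statistics(exp)
      for (g in sample(rownames(v), 5)) {
        ref <- stats::oneway.test(v[g, ] ~ factor(doses), var.equal = TRUE)
        expect_equal(fs$F[fs$gene == g], unname(ref$statistic), tolerance = 1e-10)
      }
    }
  })
})

test_that("the Welch statistic matches the hand-worked example and t.test", {
  # A = {3,5,7}, B = {1,2,3,2}: t = 3 / sqrt(1.5)
  a <- c(3, 5, 7)
  b <- c(1, 2, 3, 2)
  ref <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
  w <- biclustsig:::welch_t(a, b, "greater")
  expect_equal(w$t, 3 / sqrt(1.5), tolerance = 1e-12)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
})

test_that("Welch implementation agrees with t.test on random group pairs", {
  withr::with_seed(99, {
    for (i in 1:300) {
      a <- rnorm(sample(3:30, 1), sd = runif(1, 0.3, 3))
      b <- rnorm(sample(3:30, 1), mean = rnorm(1), sd = runif(1, 0.3, 3))
      for (alt in c("greater", "two.sided")) {
        w <- biclustsig:::welch_t(a, b, alt)
        ref <- stats::t.test(a, b, alternative = alt, var.equal = FALSE)
        expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(w$p, ref$p.value, tolerance = 1e-8)
      }
    }
  })
})

test_that("a set equal to all genes gives t = 0 and one-sided p = 0.5", {
  withr::with_seed(2, {
    sim <- simulate_dose_experiment(100, dose_design(seed = 2))
    fs <- dose_f_statistics(sim$experiment)
    res <- gene_set_enrichment(fs, fs$gene, "everything")
    expect_equal(res$t_statistic, 0)
    expect_equal(res$p_value, 0.5)
    expect_equal(res$n_in_set, res$n_background)
  })
})

test_that("set genes absent from the experiment are dropped with a warning", {
  sim <- simulate_dose_experiment(100, dose_design(seed = 4))
  fs <- dose_f_statistics(sim$experiment)
  expect_warning(
    res <- gene_set_enrichment(fs, c(sim$truth$genes[[1]], "NOT_A_GENE"), "resp"),
    "not measured"
  )
  expect_equal(res$n_in_set, length(sim$truth$genes[[1]]))
  expect_error(
    gene_set_enrichment(fs, c("NOPE1", "NOPE2"), "bad") |> suppressWarnings(),
    "< 2 usable"
  )
})

test_that("the planted responsive set is strongly enriched at the power fixture", {
  sim <- simulate_dose_experiment(2000, dose_design(seed = 10))
  fs <- dose_f_statistics(sim$experiment)
  res <- gene_set_enrichment(fs, sim$truth$genes[[1]], "responsive")
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$mean_in_set, res$mean_background)
  # excluding the set from the background sharpens the contrast
  res2 <- gene_set_enrichment(fs, sim$truth$genes[[1]], "responsive",
                              background = "rest")
  expect_lt(res2$mean_background, res$mean_background)
})

test_that("enrichment_report composes, sorts by p and supports BH adjustment", {
  withr::with_seed(8, {
    sim <- simulate_dose_experiment(500, dose_design(seed = 8))
    resp <- sim$truth$genes[[1]]
    decoys <- lapply(1:5, function(i) sample(rownames(sim$experiment$values), 50))
    sets <- c(list(responsive = resp), stats::setNames(decoys, paste0("decoy", 1:5)))
    rep <- enrichment_report(sim$experiment, sets, adjust = TRUE)
    expect_s3_class(rep, "enrichment_tbl")
    expect_equal(nrow(rep), 6L)
    expect_equal(rep$set_name[[1]], "responsive")
    expect_false(is.unsorted(rep$p_value))
    expect_true(all(rep$p_adjusted >= rep$p_value - 1e-15))
    # single-set report is consistent with gene_set_enrichment
    one <- enrichment_report(sim$experiment, list(responsive = resp))
    fs <- dose_f_statistics(sim$experiment)
    direct <- gene_set_enrichment(fs, resp, "responsive")
    expect_equal(one$p_value, direct$p_value, tolerance = 1e-12)
    # empty set list -> empty table
    expect_equal(nrow(enrichment_report(sim$experiment, list())), 0L)
  })
})

test_that("null p-values are roughly uniform and power grows with effect size", {
  withr::with_seed(31, {
    pvals <- unlist(lapply(1:20, function(i) {
      sim <- simulate_dose_experiment(
        800, dose_design(per_dose_shift = c(0, 0, 0, 0), seed = 3000 + i)
      )
      fs <- dose_f_statistics(sim$experiment)
      vapply(1:15, function(j) {
        set <- sample(fs$gene, 50)
        gene_set_enrichment(fs, set, "null")$p_value
      }, 0)
    }))
    rate <- mean(pvals < 0.05)
    expect_gt(rate, 0.02)
    expect_lt(rate, 0.09)
    # monotone power over three effect sizes (median -log10 p over seeds)
    med_logp <- vapply(c(0.25, 0.5, 1), function(scale) {
      ps <- vapply(1:25, function(i) {
        sim <- simulate_dose_experiment(
          400,
          dose_design(per_dose_shift = scale * c(0, 1, 2, 3), seed = 5000 + i)
        )
        fs <- dose_f_statistics(sim$experiment)
        gene_set_enrichment(fs, sim$truth$genes[[1]], "resp")$p_value
      }, 0)
      stats::median(-log10(ps))
    }, 0)
    expect_true(all(diff(med_logp) > 0))
  })
})
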