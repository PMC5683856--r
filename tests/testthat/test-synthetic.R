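test_that("compendium generation is deterministic and honours the null case", {
  cfg0 <- sim_config(30, 5, noise_sd = 0, planted = list(), seed = 11)
  comp0 <- simulate_compendium(cfg0)
  expect_true(all(comp0$fc$values == 0))
  expect_identical(dim(comp0$fc$values), c(30L, 5L))

  cfg <- recoverable_config(seed = 99)
  a <- simulate_compendium(cfg)
  b <- simulate_compendium(cfg)
  expect_identical(a$fc$values, b$fc$values)
  expect_identical(a$truth, b$truth)

  # a different seed changes the noise realisation
  c2 <- simulate_compendium(recoverable_config(seed = 100))
  expect_false(identical(a$fc$values, c2$fc$values))
})

test_that("planted cells carry the effect and background stays near zero", {
  pb <- planted_bicluster(sprintf("g%04d", 1:20), sprintf("study1|cond%02d", 1:6),
                          "up", effect_mean = 2, effect_sd = 0.1)
  cfg <- sim_config(100, 10, noise_sd = 0.2, planted = list(pb), seed = 5)
  comp <- simulate_compendium(cfg)
  block <- comp$fc$values[pb$genes, pb$conditions]
  expect_gt(mean(block), 1.8)
  bg <- comp$fc$values[setdiff(rownames(comp$fc$values), pb$genes), ]
  expect_lt(max(abs(mean(bg))), 0.1)
  # downstream recovery of exactly the planted block
  found <- bimax(binarize(comp$fc, "up"), min_rows = 15, min_cols = 5, max_cols = 15)
  expect_equal(nrow(found), 1L)
  expect_identical(found$genes[[1]], sort(pb$genes))
  expect_identical(found$conditions[[1]], sort(pb$conditions))
})

test_that("overlapping planted blocks resolve last-writer-wins", {
  genes <- sprintf("g%04d", 1:40)
  conds <- sprintf("study1|cond%02d", 1:10)
  p1 <- planted_bicluster(genes[1:20], conds[1:6], "up", effect_mean = 2, effect_sd = 0)
  p2 <- planted_bicluster(genes[10:30], conds[4:8], "down", effect_mean = -3, effect_sd = 0)
  cfg <- sim_config(40, 10, noise_sd = 0, planted = list(p1, p2), seed = 1)
  comp <- simulate_compendium(cfg)
  expect_equal(comp$fc$values["g0015", "study1|cond05"], -3) # overwritten
  expect_equal(comp$fc$values["g0005", "study1|cond05"], 2)  # untouched by p2
})

test_that("planted bicluster validation rejects bad inputs", {
  expect_error(planted_bicluster(character(), "c1"), "non-empty")
  expect_error(planted_bicluster("g1", "c1", "up", effect_mean = -1), "> 0")
  expect_error(planted_bicluster("g1", "c1", "down", effect_mean = 1), "< 0")
  expect_error(
    planted_bicluster(c("g1", "g1"), "c1"), "duplicate"
  )
  pb <- planted_bicluster(sprintf("g%d", 1:30), "c1")
  expect_error(sim_config(10, 5, planted = list(pb)), "larger than")
})

test_that("dose experiments embed the per-dose shifts and reject bad designs", {
  expect_error(dose_design(dose_levels = "0"), ">= 2 dose levels")
  expect_error(dose_design(replicates_per_dose = 1), ">= 2")
  expect_error(dose_design(per_dose_shift = c(1, 1, 1, 1)), "first")
  expect_error(dose_design(per_dose_shift = c(0, 1)), "one entry per dose")

  dd <- dose_design(seed = 3)
  sim <- simulate_dose_experiment(200, dd)
  sim2 <- simulate_dose_experiment(200, dd)
  expect_identical(sim$experiment$values, sim2$experiment$values)
  resp <- sim$truth$genes[[1]]
  expect_length(resp, 20) # 10% of 200
  v <- sim$experiment$values
  top_idx <- sim$experiment$doses == "162"
  ctl_idx <- sim$experiment$doses == "0"
  shift_hat <- mean(v[resp, top_idx]) - mean(v[resp, ctl_idx])
  expect_lt(abs(shift_hat - 3), 0.5)
  null_genes <- setdiff(rownames(v), resp)
  expect_lt(abs(mean(v[null_genes, top_idx])), 0.2)
})

test_that("raw-study preprocessing round-trips the compendium", {
  # noise_sd = 0: exact equality with the embedded fold changes
  cfg <- recoverable_config(seed = 7, noise_sd = 0, effect_sd = 0)
  raw <- simulate_raw_study(cfg, replicates = 1, controls = 1)
  fc <- suppressMessages(fold_change_vs_control(raw))
  comp <- simulate_compendium(cfg)
  expect_identical(colnames(fc$values), colnames(comp$fc$values))
  expect_equal(fc$values, comp$fc$values, tolerance = 1e-12)

  # with replicates and noise the difference is bounded by the noise scale
  cfg2 <- recoverable_config(seed = 8, noise_sd = 0.1)
  raw2 <- simulate_raw_study(cfg2, replicates = 3, controls = 2,
                             tech_replicates = 2)
  fc2 <- suppressMessages(fold_change_vs_control(raw2))
  comp2 <- simulate_compendium(cfg2)
  err <- abs(fc2$values - comp2$fc$values[rownames(fc2$values), colnames(fc2$values)])
  expect_lt(max(err), 6 * 0.1)
})
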