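# Small literal study used across the preprocessing tests: two genes, one
# gene measured by three probes, two conditions with replicates + control.
make_tiny_study <- function() {
  samples <- tibble::tibble(
    sample = c("ctl1", "a1", "a2", "b1"),
    study = "s1",
    condition = c("control", "trtA", "trtA", "trtB"),
    is_control = c(TRUE, FALSE, FALSE, FALSE),
    replicate = c(1L, 1L, 2L, 1L)
  )
  values <- rbind(
    p1 = c(3, 5, 5, 4),
    p2 = c(3, 7, 9, 4),
    p3 = c(3, 6, 7, 4),
    q1 = c(2, 2, 2, 6)
  )
  colnames(values) <- samples$sample
  map <- tibble::tibble(probe = c("p1", "p2", "p3", "q1"),
                        gene = c("GA", "GA", "GA", "GB"))
  expression_study(values, samples, map)
}

test_that("probe collapse takes the per-gene median with the even-n convention", {
  st <- make_tiny_study()
  out <- collapse_technical_replicates(st, quiet = TRUE)
  expect_identical(rownames(out$values), c("GA", "GB"))
  # GA in ctl1: median(3,3,3) = 3; in a2: median(5,9,7) = 7
  expect_equal(out$values["GA", "ctl1"], 3)
  expect_equal(out$values["GA", "a2"], 7)
  # even number of probes: mean of the middle pair
  st2 <- expression_study(
    rbind(p1 = c(1), p2 = c(3)) |> `colnames<-`("s1"),
    tibble::tibble(sample = "s1", condition = "c1"),
    tibble::tibble(probe = c("p1", "p2"), gene = "G")
  )
  expect_equal(collapse_technical_replicates(st2, quiet = TRUE)$values["G", "s1"], 2)
  # single probe passes through unchanged
  expect_equal(out$values["GB", "b1"], 6)
  # idempotent: a collapsed study has no probe map and is returned unchanged
  expect_identical(collapse_technical_replicates(out, quiet = TRUE), out)
})

test_that("probes without a gene symbol are dropped, multi-mapping ones fan out", {
  samples <- tibble::tibble(sample = "s1", condition = "c1")
  values <- matrix(c(1, 5, 9), 3, 1, dimnames = list(c("p1", "p2", "p3"), "s1"))
  map <- tibble::tibble(
    probe = c("p1", "p1", "p2"),
    gene = c("GA", "GB", "GA")
  ) # p3 unmapped
  st <- expression_study(values, samples, map)
  expect_message(out <- collapse_technical_replicates(st), "1 probe")
  expect_setequal(rownames(out$values), c("GA", "GB"))
  expect_equal(out$values["GA", "s1"], median(c(1, 5)))
  expect_equal(out$values["GB", "s1"], 1)
})

test_that("biological replicate collapse is a per-condition median, order-invariant", {
  st <- make_tiny_study()
  out <- collapse_biological_replicates(st)
  # trtA replicates for p2: median(7, 9) = 8
  expect_equal(out$values["p2", "s1|trtA"], 8)
  expect_equal(out$values["q1", "s1|trtB"], 6)
  # permuting samples leaves the collapse unchanged
  perm <- c(3, 1, 4, 2)
  st_perm <- expression_study(st$values[, perm], st$samples[perm, ], st$probe_to_gene)
  expect_equal(collapse_biological_replicates(st_perm)$values, out$values)
  # idempotent
  expect_equal(collapse_biological_replicates(out)$values, out$values)
})

test_that("fold change vs control subtracts the matched control and drops it", {
  st <- make_tiny_study()
  fc <- suppressMessages(fold_change_vs_control(st))
  # GA: trtA median over probes/replicates; probe medians per sample
  # a1: median(5,7,6)=6, a2: median(5,9,7)=7 -> bio median 6.5; control 3
  expect_equal(fc$values["GA", "s1|trtA"], 3.5)
  expect_equal(fc$values["GB", "s1|trtB"], 4)
  expect_false(any(grepl("control", colnames(fc$values))))
  # treated equals control -> 0
  expect_equal(fc$values["GB", "s1|trtA"], 0)
})

test_that("a condition without a resolvable control is a hard error naming it", {
  st <- make_tiny_study()
  st$samples$is_control <- FALSE # no control left in the study
  expect_error(
    suppressMessages(fold_change_vs_control(st)),
    "no unambiguous control"
  )
  # explicit map to a non-existent control also errors with the name
  st2 <- make_tiny_study()
  expect_error(
    suppressMessages(fold_change_vs_control(st2, control_map = c(trtA = "nope"))),
    "nope"
  )
})

test_that("merging studies intersects gene symbols and normalizes column order", {
  fc1 <- fold_change_matrix(
    matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1|x", "s1|y"))),
    tibble::tibble(condition_id = c("s1|x", "s1|y"), study = "s1",
                   condition = c("x", "y"))
  )
  fc2 <- fold_change_matrix(
    matrix(1:4, 2, 2, dimnames = list(c("B", "D"), c("s2|z", "s2|w"))),
    tibble::tibble(condition_id = c("s2|z", "s2|w"), study = "s2",
                   condition = c("z", "w"))
  )
  m <- suppressMessages(merge_studies(list(fc1, fc2)))
  expect_identical(rownames(m$values), "B")
  expect_identical(m$conditions$study, c("s1", "s1", "s2", "s2"))
  # columns sorted by (study, condition): w before z within s2
  expect_identical(m$conditions$condition, c("x", "y", "w", "z"))
  # order of the study list does not change the merged gene set
  m2 <- suppressMessages(merge_studies(list(fc2, fc1)))
  expect_identical(rownames(m2$values), rownames(m$values))
  expect_setequal(colnames(m2$values), colnames(m$values))
  # union keeps all genes, with NA where unmeasured
  mu <- suppressMessages(merge_studies(list(fc1, fc2), genes = "union"))
  expect_setequal(rownames(mu$values), c("A", "B", "C", "D"))
  expect_true(is.na(mu$values["D", "s1|x"]))
  # self-merge duplicates provenance-tagged columns
  ms <- suppressMessages(merge_studies(list(fc1, fc1)))
  expect_identical(ncol(ms$values), 4L)
  expect_identical(rownames(ms$values), c("A", "B", "C"))
  # disjoint gene sets cannot be intersected
  fc3 <- fold_change_matrix(
    matrix(1, 1, 1, dimnames = list("Z", "s3|q")),
    tibble::tibble(condition_id = "s3|q", study = "s3", condition = "q")
  )
  expect_error(suppressMessages(merge_studies(list(fc1, fc3))), "shared")
})
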