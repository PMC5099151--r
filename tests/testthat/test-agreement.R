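test_that("ibmd hits the hand-derived spot values", {
  expect_equal(ibmd(rep(7, 11)), 0)
  expect_equal(ibmd(c(0, 0)), 0)            # agreement on absence
  expect_equal(ibmd(c(1, 10)), log2(9 / 10 + 1), tolerance = 1e-12)
  expect_equal(ibmd(c(2, 2, 4)), mean(c(0, log2(1.5), log2(1.5))),
               tolerance = 1e-12)
  expect_error(ibmd(5), "at least 2")
  expect_error(ibmd(c(-1, 2)), "non-negative")
})

test_that("ibmd is zero iff all observers agree, and permutation-invariant", {
  set.seed(101)
  for (i in 1:50) {
    m <- sample(2:11, 1)
    v <- sample(0:10, m, replace = TRUE)
    expect_equal(ibmd(v), ibmd(sample(v)))
    if (length(unique(v)) == 1) expect_identical(ibmd(v), 0)
    else expect_gt(ibmd(v), 0)
  }
})

test_that("two-observer ibmd increases with the gap at fixed maximum", {
  vals <- vapply(0:9, function(d) ibmd(c(10 - d, 10)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("bootstrap CI is deterministic, ordered, and brackets sensibly", {
  v <- c(1, 10, 1, 10)
  ci1 <- ibmd_ci(v, n_boot = 2000, seed = 42)
  ci2 <- ibmd_ci(v, n_boot = 2000, seed = 42)
  expect_identical(ci1, ci2)                    # bit-identical per seed
  expect_lte(ci1["ci_low"], ci1["ci_high"])
  expect_lte(ci1[["ci_low"]], ibmd(v))
  expect_gte(ci1[["ci_high"]], ibmd(v))
  expect_equal(unname(ibmd_ci(rep(4, 6), n_boot = 50, seed = 1)), c(0, 0))
  ci_one <- ibmd_ci(v, n_boot = 1, seed = 9)
  expect_identical(ci_one[["ci_low"]], ci_one[["ci_high"]])
  expect_error(ibmd_ci(v, n_boot = 2000), "seed")
  expect_error(ibmd_ci(5, seed = 1), "at least 2")
})

test_that("bootstrap CI matches an independent percentile reimplementation", {
  v <- c(2, 3, 2, 5, 4)
  n_boot <- 500
  got <- ibmd_ci(v, n_boot = n_boot, seed = 7)
  # independent route: same seed stream, same resampling order, plain loop
  ref <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(7L)
    idx <- matrix(sample.int(length(v), n_boot * length(v), replace = TRUE),
                  nrow = n_boot)
    stats <- apply(idx, 1, function(ii) ibmd_oracle(v[ii]))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    stats::quantile(stats, c(0.025, 0.975), names = FALSE)
  })
  expect_equal(unname(got), ref, tolerance = 1e-12)
})

test_that("filter retains agreed cells and drops extreme disagreement at 0.15", {
  ros <- roster(c("A", "B"))
  evs <- do.call(rbind, lapply(1:11, function(j) {
    data.frame(rater_id = sprintf("j%02d", j), emotion = "joy",
               source = "A", target = "B", value = 7)
  }))
  # second cell: judges span the full Likert range
  evs2 <- do.call(rbind, lapply(1:11, function(j) {
    data.frame(rater_id = sprintf("j%02d", j), emotion = "joy",
               source = "B", target = "A",
               value = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 1)[j])
  }))
  set <- accumulate_events(rbind(evs, evs2), ros, emotions = "joy")
  agr <- filter_cells(set, threshold = 0.15, n_boot = 400, seed = 5)
  expect_s3_class(agr, "cell_agreement")
  row_ab <- agr[agr$source == "A" & agr$target == "B", ]
  row_ba <- agr[agr$source == "B" & agr$target == "A", ]
  expect_equal(row_ab$ibmd, 0)
  expect_equal(c(row_ab$ci_low, row_ab$ci_high), c(0, 0))
  expect_true(row_ab$retained)
  expect_gt(row_ba$ci_high, 0.15)
  expect_false(row_ba$retained)
  # all-zero cells are scored 0 and retained
  zero_rows <- agr[agr$source == agr$target, ]
  expect_true(all(zero_rows$ibmd == 0) && all(zero_rows$retained))
  # CI bounds always bracket the point estimate
  expect_true(all(agr$ci_low <= agr$ibmd + 1e-12))
  expect_true(all(agr$ci_high >= agr$ibmd - 1e-12))
  expect_identical(attr(agr, "threshold"), 0.15)
})

test_that("icc_a1 reproduces hand-derived values and structure", {
  expect_equal(icc_a1(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))), 1)
  expect_equal(icc_a1(cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))), 10 / 13,
               tolerance = 1e-12)
  expect_warning(out <- icc_a1(matrix(3, 4, 2)), "zero variance")
  expect_true(is.na(out))
})

test_that("icc_a1 matches the aov variance-components oracle", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    x <- cbind(sample(0:10, n, TRUE), sample(0:10, n, TRUE))
    if (sd(as.vector(x)) == 0) next
    expect_equal(icc_a1(x), icc_oracle(x), tolerance = 1e-8)
  }
})

test_that("pairwise judge ICC matrix is symmetric with unit diagonal", {
  s <- small_set(seed = 23, n_char = 4, emotions = c("joy", "anger"),
                 n_raters = 3, noise_sd = 1)$set
  icc <- judge_pair_icc(s)
  expect_identical(dim(unclass(icc)), c(3L, 3L))
  expect_equal(unclass(icc), t(unclass(icc)))
  expect_equal(unname(diag(icc)), rep(1, 3))
  expect_true(all(icc >= -1 & icc <= 1, na.rm = TRUE))
  # identical judges agree perfectly
  ros <- roster(c("A", "B", "C"))
  ev <- data.frame(source = c("A", "A", "B", "B"),
                   target = c("B", "C", "C", "A"), stringsAsFactors = FALSE)
  ev <- rbind(cbind(ev, rater_id = "j1", emotion = "joy", value = 1:4),
              cbind(ev, rater_id = "j2", emotion = "joy", value = 1:4))
  dup <- accumulate_events(ev, ros, emotions = "joy")
  expect_equal(unclass(judge_pair_icc(dup))["j1", "j2"], 1)
  # per-emotion mode returns one matrix per emotion
  per <- judge_pair_icc(s, per_emotion = TRUE)
  expect_named(per, c("joy", "anger"))
  expect_equal(unname(diag(per$joy)), rep(1, 3))
})
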