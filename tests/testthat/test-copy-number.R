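# The published counting table for the benchmark HapMap/1000 Genomes samples
# (totals in bases, printed ratios in percent, printed copy-number k).
# Only the rows whose printed totals and ratios are mutually consistent are
# used; see the methods vignette on the excluded family rows.
published_rows <- data.frame(
  sample = c("NA18507", "NA18508", "NA18506", "NA11831", "NA06985"),
  mt_bases = c(249.8e6, 239.7e6, 273.0e6, 7.54e6, 24.80e6),
  all_bases = c(135.2e9, 133.2e9, 132.3e9, 4.15e9, 11.97e9),
  ratio_pct = c(0.185, 0.180, 0.206, 0.182, 0.207),
  k = c(646.84, 629.69, 722.10, NA, NA))

test_that("mito_ratio reproduces the published per-sample ratios", {
  for (i in seq_len(nrow(published_rows))) {
    r <- mito_ratio(list(mt_bases = published_rows$mt_bases[i],
                         all_bases = published_rows$all_bases[i]))
    expect_equal(round(100 * r, 3), published_rows$ratio_pct[i],
                 tolerance = 1e-12)
  }
  expect_identical(mito_ratio(list(mt_bases = 0, all_bases = 1e9)), 0)
  expect_error(mito_ratio(list(mt_bases = 0, all_bases = 0)),
               class = "mitocount_degenerate_error")
})

test_that("estimate_copies implements the ratio inversion exactly", {
  # 2N = 1000, M = 10, mtBases = 100, allBases = 1100:
  # k = (100 * 1000) / (1000 * 10) = 10
  gp <- genome_params(N = 500, M = 10)
  expect_identical(estimate_copies(100, 1100, gp), 10)
  expect_identical(estimate_copies(0, 1100, gp), 0)
  expect_error(estimate_copies(1100, 1100, gp),
               class = "mitocount_degenerate_error")
  expect_error(estimate_copies(-1, 1100, gp),
               class = "mitocount_degenerate_error")
})

test_that("inverting the estimator on the published trio implies one nuclear size", {
  # the diploid nuclear base count 2N the authors used is not printed;
  # inverting k = mtBases*2N / ((allBases-mtBases)*M) per row must give the
  # same 2N for all three rows of the trio (M = 16,567 for this family)
  trio <- published_rows[1:3, ]
  implied_2N <- trio$k * (trio$all_bases - trio$mt_bases) * 16567 / trio$mt_bases
  spread <- (max(implied_2N) - min(implied_2N)) / mean(implied_2N)
  expect_lt(spread, 0.002)
  # and plugging the shared constant back in reproduces the printed k
  gp <- genome_params(N = mean(implied_2N) / 2, M = 16567)
  for (i in 1:3)
    expect_equal(estimate_copies(trio$mt_bases[i], trio$all_bases[i], gp),
                 trio$k[i], tolerance = 2e-3)
})

test_that("aggregate_runs pools counts and keeps per-run ratios", {
  gp <- genome_params(N = 1e6, M = 1000)
  mk <- function(mt, all, id = "r") structure(
    list(run_id = id, total_reads = 10L, mito_reads = 2L,
         all_bases = all, mt_bases = mt), class = "run_count")

  single <- aggregate_runs(list(mk(10, 1000)), gp)
  expect_identical(single$k, estimate_copies(10, 1000, gp))

  equal_ratio <- aggregate_runs(list(mk(10, 1000), mk(20, 2000)), gp)
  expect_equal(equal_ratio$pooled_mt_bases / equal_ratio$pooled_all_bases, 0.01)
  expect_equal(unname(equal_ratio$per_run_ratios), c(0.01, 0.01))

  two <- aggregate_runs(list(mk(10, 1000), mk(30, 1000)), gp)
  expect_equal(two$pooled_mt_bases / two$pooled_all_bases, 40 / 2000)
  expect_identical(two$pooled_mt_bases, 40)
  expect_error(aggregate_runs(list(), gp), class = "mitocount_input_error")
})

test_that("estimator invariants: monotonicity, scale invariance, identity with the sampling ratio", {
  set.seed(88)
  for (i in 1:50) {
    N <- runif(1, 1e5, 1e10)
    M <- runif(1, 1e3, 2e4)
    all <- runif(1, 1e6, 1e12)
    mt <- runif(1, 1, all * 0.99)
    gp <- genome_params(N = N, M = M)
    k <- estimate_copies(mt, all, gp)

    # strictly increasing in mt_bases, strictly decreasing in M
    expect_gt(estimate_copies(mt * 1.01, all, gp), k)
    expect_lt(estimate_copies(mt, all, genome_params(N, M * 1.01)), k)

    # scale invariance
    expect_equal(estimate_copies(mt * 7, all * 7, gp), k, tolerance = 1e-12)

    # solving ratio = kM / (2N + kM) for k gives the same number
    r <- mt / all
    k_from_ratio <- 2 * N * r / (M * (1 - r))
    expect_equal(k, k_from_ratio, tolerance = 1e-9)
  }
})

test_that("oneway_anova matches the textbook decomposition and handles edge cases", {
  # three groups of 24 observations leave df (2, 69)
  set.seed(99)
  g3 <- lapply(1:3, function(i) rnorm(24, mean = i))
  res <- oneway_anova(g3)
  expect_identical(res$df_between, 2L)
  expect_identical(res$df_within, 69L)

  # hand-computed sums of squares for {1,2,3}, {2,3,4}:
  # SSB = 1.5, SSW = 4, F = (1.5/1) / (4/4) = 1.5
  res2 <- oneway_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res2$F, 1.5, tolerance = 1e-12)
  expect_identical(res2$df_between, 1L)
  expect_identical(res2$df_within, 4L)
  expect_equal(res2$p_value, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  # identical values in every group, equal means: F = 0
  expect_identical(oneway_anova(list(c(2, 2), c(2, 2)))$F, 0)

  # zero within-group variance with unequal means: F infinite, p = 0
  degen <- oneway_anova(list(c(1, 1), c(2, 2)))
  expect_identical(degen$F, Inf)
  expect_identical(degen$p_value, 0)

  expect_error(oneway_anova(list(1, c(1, 2))), class = "mitocount_input_error")
  expect_error(oneway_anova(list(c(1, 2))), class = "mitocount_input_error")
})

test_that("oneway_anova equals stats::oneway.test on random small configurations", {
  set.seed(110)
  for (i in 1:40) {
    n_groups <- sample(2:4, 1)
    sizes <- sample(2:5, n_groups, replace = TRUE)
    while (sum(sizes) > 12) sizes <- sample(2:5, n_groups, replace = TRUE)
    groups <- lapply(sizes, function(n) rnorm(n))
    res <- oneway_anova(groups)
    x <- unlist(groups)
    g <- factor(rep(seq_along(groups), sizes))
    ref <- stats::oneway.test(x ~ g, var.equal = TRUE)
    expect_equal(res$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
    expect_identical(res$df_between, as.integer(ref$parameter[["num df"]]))
    expect_identical(res$df_within, as.integer(ref$parameter[["denom df"]]))
  }
})
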