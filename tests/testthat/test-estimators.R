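test_that("Jarzynski estimate matches direct evaluation and its bound", {
  # constant works: exponential average collapses to the common value
  expect_equal(dg_jarzynski(work_set(rep(1.3, 3), 250))$dG, 1.3)
  # two-point ensemble, oracle = direct formula -RT ln((1 + e^-b w)/2)
  oracle <- -RT300 * log((1 + exp(-BETA300 * 1.372)) / 2)
  expect_equal(dg_jarzynski(work_set(c(0, 1.372), 300))$dG, oracle)
  expect_equal(oracle, 0.356, tolerance = 2e-3)
  # shift invariance and the Jensen bound, over random ensembles
  set.seed(101)
  for (i in 1:25) {
    w <- random_work_set()
    est <- dg_jarzynski(w)$dG
    expect_lte(est, mean(as.numeric(w)) + 1e-12)
    shifted <- work_set(as.numeric(w) + 3.7, 300)
    expect_equal(dg_jarzynski(shifted)$dG, est + 3.7, tolerance = 1e-10)
  }
})

test_that("Jarzynski is numerically stable for very large work values", {
  w <- work_set(c(-1200, -1190, -1185), 300)
  expect_true(is.finite(dg_jarzynski(w)$dG))
  expect_lte(dg_jarzynski(w)$dG, -1190)
})

test_that("Crooks-Gaussian estimate uses the unbiased sample variance", {
  expect_equal(dg_gaussian(work_set(rep(2.5, 4), 300))$dG, 2.5)
  # var([-1,0,1]) = 1, so dG = -beta/2 by hand
  expect_equal(dg_gaussian(work_set(c(-1, 0, 1), 300))$dG, -BETA300 / 2)
  expect_equal(-BETA300 / 2, -0.839, tolerance = 1e-3)
  expect_error(dg_gaussian(work_set(1, 300)), "N >= 2")
})

test_that("Gaussian estimate is consistent on large normal samples", {
  mu <- 2; sigma <- 1.5
  set.seed(20)
  w <- work_set(rnorm(1e5, mu, sigma), 300)
  truth <- mu - BETA300 * sigma^2 / 2
  # standard error of the estimate is dominated by the mean's sigma/sqrt(n)
  se <- sigma / sqrt(1e5) + BETA300 * sigma^2 / sqrt(2e5)
  expect_lt(abs(dg_gaussian(w)$dG - truth), 3 * se)
})

test_that("Anderson-Darling statistic agrees with an independent implementation", {
  skip_if_not_installed("nortest")
  for (s in c(7, 13, 99)) {
    set.seed(s)
    x <- rnorm(200)
    n <- length(x)
    ref <- unname(nortest::ad.test(x)$statistic) * (1 + 0.75 / n + 2.25 / n^2)
    expect_equal(ad_normality(work_set(x, 300)), ref, tolerance = 1e-12)
  }
  # heavily skewed sample
  set.seed(3)
  y <- rexp(200)
  ref <- unname(nortest::ad.test(y)$statistic) * (1 + 0.75 / 200 + 2.25 / 200^2)
  expect_equal(ad_normality(work_set(y, 300)), ref, tolerance = 1e-12)
})

test_that("Anderson-Darling statistic behaves as a normality measure", {
  # exact normal quantiles: as normal as a sample can be
  q <- qnorm((1:50 - 0.5) / 50)
  expect_lt(ad_normality(work_set(q, 300)), 0.34)
  # seeded exponential sample: far beyond the upper threshold
  set.seed(3)
  expect_gt(ad_normality(work_set(rexp(200), 300)), 0.754)
  # affine invariance
  set.seed(5)
  x <- rnorm(100)
  a <- ad_normality(work_set(x, 300))
  expect_equal(ad_normality(work_set(2.5 * x - 7, 300)), a, tolerance = 1e-10)
  expect_error(ad_normality(work_set(rep(1, 10), 300)), "degenerate")
  expect_error(ad_normality(work_set(rnorm(5), 300)), "N >= 8")
})

test_that("convolution estimate equals per-stage Jarzynski sum exactly", {
  # single pair
  s1 <- stage_work_set(work_set(2, 300), work_set(3, 300))
  expect_equal(dg_convolution(s1)$dG, 5)
  # two-point stages, oracle = brute force over the 4 pairwise sums
  lj <- c(0, 1.372); qq <- c(0, 1.372)
  pairs <- as.vector(outer(lj, qq, `+`))
  brute <- -RT300 * log(mean(exp(-BETA300 * pairs)))
  s2 <- stage_work_set(work_set(lj, 300), work_set(qq, 300))
  expect_equal(dg_convolution(s2)$dG, brute, tolerance = 1e-12)
  expect_equal(brute, 0.713, tolerance = 1e-3)
  # algebraic factorization on random unequal-length stages
  set.seed(11)
  for (i in 1:50) {
    st <- stage_work_set(random_work_set(sample(3:30, 1)),
                         random_work_set(sample(3:30, 1)))
    expect_equal(dg_convolution(st)$dG,
                 dg_jarzynski(st$lj)$dG + dg_jarzynski(st$qq)$dG,
                 tolerance = 1e-12)
  }
})

test_that("decision tree routes by the total-work A*2 and consistency gap", {
  # normal totals at a seed with A*2 < 0.34 -> gaussian
  st <- gen_stage_works(spec_normal(), spec_normal(), 0, 200, seed = 9)
  e <- select_estimator(st)
  expect_lt(e$ad_statistic, 0.34)
  expect_identical(e$method, "gaussian")
  # strongly separated mixture totals -> convolution
  st2 <- gen_stage_works(spec_separated(), spec_narrow_qq(), 0, 200, seed = 42)
  e2 <- select_estimator(st2)
  expect_gt(e2$ad_statistic, 0.754)
  expect_identical(e2$method, "convolution")
  expect_equal(e2$dG, dg_convolution(st2)$dG)
  # same inputs, same branch (pure function)
  e2b <- select_estimator(st2)
  expect_identical(e2b$method, e2$method)
  expect_equal(e2b$dG, e2$dG)
})

test_that("gray-zone consistency rule keeps or rejects the Gaussian estimate", {
  # documented seeds put the total-work A*2 in [0.34, 0.754]
  st_keep <- gen_stage_works(spec_grayzone(), spec_gray_qq(), 0, 200, seed = 17)
  e_keep <- select_estimator(st_keep)
  expect_gte(e_keep$ad_statistic, 0.34)
  expect_lte(e_keep$ad_statistic, 0.754)
  expect_lt(e_keep$gaussian_jarzynski_gap, 0.2)
  expect_identical(e_keep$method, "gaussian")

  st_rej <- gen_stage_works(spec_grayzone(), spec_gray_qq(), 0, 200, seed = 29)
  e_rej <- select_estimator(st_rej)
  expect_gte(e_rej$ad_statistic, 0.34)
  expect_lte(e_rej$ad_statistic, 0.754)
  expect_gte(e_rej$gaussian_jarzynski_gap, 0.2)
  expect_identical(e_rej$method, "convolution")
})

test_that("decision tree degenerate and error branches", {
  # constant works short-circuit to gaussian with dG = w, A*2 not applicable
  e <- select_estimator(work_set(rep(1.5, 10), 300))
  expect_identical(e$method, "gaussian")
  expect_equal(e$dG, 1.5)
  expect_true(is.na(e$ad_statistic))
  # non-normal totals without stage input must instruct stage input
  set.seed(3)
  tot <- work_set(rexp(200), 300)
  expect_error(select_estimator(tot), "stage")
})

test_that("stage independence diagnostics", {
  x <- rnorm(50)
  s_same <- stage_work_set(work_set(x, 300), work_set(x, 300))
  expect_equal(stage_independence(s_same),
               tibble::tibble(pearson = 1, kendall = 1))
  s_neg <- stage_work_set(work_set(x, 300), work_set(-x, 300))
  expect_equal(stage_independence(s_neg),
               tibble::tibble(pearson = -1, kendall = -1))
  st <- gen_stage_works(spec_normal(), spec_normal(), 0, 200, seed = 5)
  ind <- stage_independence(st)
  expect_lt(abs(ind$pearson), 0.2)
  expect_lt(abs(ind$kendall), 0.2)
  expect_error(stage_independence(
    stage_work_set(work_set(1:3, 300), work_set(1:4, 300))), "equal length")
})

test_that("tidy and glance return one-row tibbles with the diagnostics", {
  st <- gen_stage_works(spec_normal(), spec_normal(), 0, 200, seed = 2)
  est <- estimate_free_energy(st, cfg = ci_config(seed = 1))
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_named(td, c("dG", "method", "ci95", "ad_statistic",
                     "gaussian_jarzynski_gap", "n", "temperature"))
  expect_true(is.finite(td$ci95))
  expect_equal(glance(est), td)
})
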