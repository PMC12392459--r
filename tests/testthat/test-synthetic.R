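test_that("normal work generator hits its closed-form target", {
  # sigma = 0: all works equal the target
  w0 <- gen_normal_works(-2, 0, n = 5, seed = 1)
  expect_equal(as.numeric(w0), rep(-2, 5))
  # population mean is dG + beta sigma^2 / 2
  w <- gen_normal_works(-5, 2, n = 1e5, temperature = 300, seed = 2)
  expect_lt(abs(mean(as.numeric(w)) - (-5 + BETA300 * 4 / 2)),
            3 * 2 / sqrt(1e5))
  # Gaussian estimate on the large ensemble recovers the target
  expect_lt(abs(dg_gaussian(w)$dG - (-5)), 0.05)
})

test_that("exact mixture free energy matches hand evaluation", {
  # single component reduces to the Crooks-Gaussian closed form
  s1 <- mixture_spec(1, -3, 1.5, 300)
  expect_equal(exact_free_energy(s1), -3 - BETA300 * 1.5^2 / 2,
               tolerance = 1e-12)
  # two components, hand evaluation of the lognormal-moment formula
  s2 <- mixture_spec(c(0.5, 0.5), c(0, 2), c(0.5, 0.5), 300)
  hand <- -RT300 * log(0.5 * exp(BETA300^2 * 0.25 / 2) +
                       0.5 * exp(-BETA300 * 2 + BETA300^2 * 0.25 / 2))
  expect_equal(exact_free_energy(s2), hand, tolerance = 1e-12)
  expect_equal(hand, 0.183, tolerance = 1e-3)
  # zero-weight components are inert
  s3 <- mixture_spec(c(0.5, 0.5, 0), c(0, 2, 99), c(0.5, 0.5, 1), 300)
  expect_equal(exact_free_energy(s3), exact_free_energy(s2))
})

test_that("mixture sampler converges to the exact free energy", {
  s2 <- mixture_spec(c(0.5, 0.5), c(0, 2), c(0.5, 0.5), 300)
  w <- gen_mixture_works(s2, n = 1e5, seed = 11)
  expect_lt(abs(dg_jarzynski(w)$dG - exact_free_energy(s2)), 0.05)
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(as.numeric(gen_normal_works(-5, 2, 50, seed = 3)),
                   as.numeric(gen_normal_works(-5, 2, 50, seed = 3)))
  s <- spec_separated()
  expect_identical(as.numeric(gen_mixture_works(s, 50, seed = 3)),
                   as.numeric(gen_mixture_works(s, 50, seed = 3)))
  a <- gen_stage_works(s, spec_normal(), 0.3, 50, seed = 3)
  b <- gen_stage_works(s, spec_normal(), 0.3, 50, seed = 3)
  expect_identical(as.numeric(a$lj), as.numeric(b$lj))
  expect_identical(as.numeric(a$qq), as.numeric(b$qq))
  expect_identical(gen_benchmark_table(10, 0.5, 0.5, seed = 3),
                   gen_benchmark_table(10, 0.5, 0.5, seed = 3))
})

test_that("copula coupling controls the stage correlation", {
  st0 <- gen_stage_works(spec_normal(), spec_normal(), 0, 200, seed = 5)
  expect_lt(abs(stage_independence(st0)$pearson), 0.2)
  st9 <- gen_stage_works(spec_normal(), spec_normal(), 0.99, 200, seed = 5)
  expect_gt(stage_independence(st9)$pearson, 0.9)
  # marginals respect their spec within 3 standard errors
  s <- mixture_spec(c(0.6, 0.4), c(-1, 2), c(0.5, 0.5), 300)
  st <- gen_stage_works(s, spec_normal(), 0, 400, seed = 6)
  mu_s <- sum(c(0.6, 0.4) * c(-1, 2))
  var_s <- sum(c(0.6, 0.4) * (c(0.5, 0.5)^2 + c(-1, 2)^2)) - mu_s^2
  expect_lt(abs(mean(as.numeric(st$lj)) - mu_s), 3 * sqrt(var_s / 400))
  expect_lt(abs(mean(as.numeric(st$qq)) - 0), 3 * 1 / sqrt(400))
})

test_that("benchmark-table generator: perfect, biased, and noisy cases", {
  perf <- gen_benchmark_table(20, 0, 0, seed = 1)
  row <- metric_row(perf, "exp_w", "synthetic_w")
  expect_equal(row$pearson, 1); expect_equal(row$kendall, 1)
  expect_equal(row$ccc, 1); expect_equal(row$mue, 0); expect_equal(row$mse, 0)

  shifted <- gen_benchmark_table(20, 0, 0, bias_w = 1, seed = 1)
  rs <- metric_row(shifted, "exp_w", "synthetic_w")
  expect_equal(rs$mue, 1); expect_equal(rs$mse, -1)
  expect_equal(rs$pearson, 1); expect_lt(rs$ccc, 1)

  # folded-normal oracle for the noisy MUE: E|N(0, 0.5^2)| = 0.5 sqrt(2/pi)
  noisy <- gen_benchmark_table(50, noise_w = 0.5, seed = 21)
  rn <- metric_row(noisy, "exp_w", "synthetic_w")
  expect_lt(abs(rn$mue - 0.5 * sqrt(2 / pi)) / (0.5 * sqrt(2 / pi)), 0.2)
})

test_that("zero-noise pipeline recovers the generator LogP exactly", {
  tab <- gen_benchmark_table(12, 0, 0, seed = 9)
  lp <- build_logp_table(tab, "synthetic", 300)
  truth <- logp(tab$exp_w, tab$exp_o, 300)
  expect_equal(lp$logp, truth, tolerance = 1e-12)
  row <- metric_row(dplyr::mutate(tab, lp_exp = truth, lp_calc = lp$logp),
                    "lp_exp", "lp_calc")
  expect_equal(row$mue, 0); expect_equal(row$ccc, 1)
})

test_that("estimator routing on generated data follows the distribution shape", {
  st_norm <- gen_stage_works(spec_normal(), spec_normal(), 0, 200, seed = 16)
  expect_identical(select_estimator(st_norm)$method, "gaussian")
  st_mix <- gen_stage_works(spec_separated(), spec_narrow_qq(), 0, 200, seed = 42)
  expect_identical(select_estimator(st_mix)$method, "convolution")
})
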