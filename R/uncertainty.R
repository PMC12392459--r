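#' Confidence-interval configuration
#'
#' @param alpha Nominal error rate (default 0.05 for 95% intervals).
#' @param z z-score multiplying the standard error (default 1.96, the
#'   two-sided normal quantile at alpha = 0.05).
#' @param bootstrap_B Number of bootstrap resamples (default 1000, >= 100).
#' @param seed Integer seed for the bootstrap resampling; `NULL` leaves the
#'   RNG state alone.
#' @param summary `"z_sd"` (z times the standard deviation of the bootstrap
#'   replicates, mirroring the z-based analytic interval) or `"percentile"`
#'   (half the central 1-alpha percentile range).
#' @return A list of class `ci_config`.
#' @export
ci_config <- function(alpha = 0.05, z = 1.96, bootstrap_B = 1000L,
                      seed = NULL, summary = c("z_sd", "percentile")) {
  stopifnot(alpha > 0, alpha < 1, z > 0, bootstrap_B >= 100L)
  structure(list(alpha = alpha, z = z, bootstrap_B = as.integer(bootstrap_B),
                 seed = seed, summary = match.arg(summary)),
            class = "ci_config")
}

#' Analytic 95% half-width for the Crooks-Gaussian estimate
#'
#' The Gaussian estimate is \eqn{\langle W\rangle - \beta\sigma^2/2}; its
#' standard error combines the error of the sample mean, \eqn{\sigma/\sqrt
#' n}, with the error of the variance term, \eqn{\beta\sigma^2/\sqrt{2n}}
#' (from \eqn{\mathrm{Var}(s^2) \approx 2\sigma^4/n} for normal data). The
#' half-width is z times their sum:
#' \deqn{\delta\Delta G = z\left(\frac{\sigma}{\sqrt n} +
#'   \frac{\beta\sigma^2}{\sqrt{2n}}\right)}
#' with sigma the unbiased sample standard deviation, consistent with the
#' variance convention of the estimator itself.
#'
#' @param works A `work_set` with N >= 2.
#' @param cfg A [ci_config()].
#' @return Half-width in kcal/mol.
#' @examples
#' w <- work_set(rnorm(200), 300)
#' gaussian_ci(w) # ~0.3 for sd ~ 1
#' @export
gaussian_ci <- function(works, cfg = ci_config()) {
  stopifnot(inherits(works, "work_set"), inherits(cfg, "ci_config"))
  n <- length(works)
  if (n < 2L) stop("analytic CI needs N >= 2", call. = FALSE)
  s <- stats::sd(unclass(works))
  b <- beta_kcal(ws_temperature(works))
  cfg$z * (s / sqrt(n) + b * s^2 / sqrt(2 * n))
}

# z*sd (or percentile half-range) of bootstrap Jarzynski replicates of one leg
boot_jarzynski_err <- function(values, beta, cfg) {
  n <- length(values)
  reps <- vapply(seq_len(cfg$bootstrap_B), function(i) {
    w <- values[sample.int(n, n, replace = TRUE)]
    -log_mean_exp(-beta * w) / beta
  }, numeric(1))
  if (cfg$summary == "z_sd") {
    cfg$z * stats::sd(reps)
  } else {
    diff(stats::quantile(reps, c(cfg$alpha / 2, 1 - cfg$alpha / 2),
                         names = FALSE)) / 2
  }
}

#' Bootstrap 95% half-width for Jarzynski-type estimates
#'
#' Each stage is resampled with replacement B times and the Jarzynski
#' estimate recomputed on every resample; the stage error is z times the
#' standard deviation of the replicates (or the percentile half-range, see
#' [ci_config()]). For two-stage input the per-stage errors are combined in
#' quadrature, reflecting the independence of the two legs. Deterministic
#' under a fixed `cfg$seed`.
#'
#' @param works A `stage_work_set` (quadrature over the two legs) or a
#'   single `work_set` (single-leg error).
#' @param cfg A [ci_config()].
#' @return Half-width in kcal/mol.
#' @export
bootstrap_ci <- function(works, cfg = ci_config()) {
  stopifnot(inherits(cfg, "ci_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (inherits(works, "stage_work_set")) {
    b <- beta_kcal(ws_temperature(works))
    # reseed per leg so the half-width is exactly invariant under
    # exchanging the stage labels
    e_lj <- boot_jarzynski_err(unclass(works$lj), b, cfg)
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    e_qq <- boot_jarzynski_err(unclass(works$qq), b, cfg)
    sqrt(e_lj^2 + e_qq^2)
  } else {
    stopifnot(inherits(works, "work_set"))
    boot_jarzynski_err(unclass(works), beta_kcal(ws_temperature(works)), cfg)
  }
}
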