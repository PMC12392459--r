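#' Free-energy estimate container
#'
#' Result of any of the work-distribution estimators. Carries the estimate,
#' the method used, the decision diagnostics when the normality-gated
#' selection produced it, and (optionally) a 95% confidence half-width.
#'
#' @param dG Free-energy estimate, kcal/mol.
#' @param method One of `"gaussian"`, `"jarzynski"`, `"convolution"`.
#' @param temperature Kelvin.
#' @param n Number of work values the estimate used (per stage for the
#'   convolution estimate, reported as `n_lj * n_qq` pair count).
#' @param ad_statistic Anderson-Darling A*^2 on the total-work distribution,
#'   or `NA` when not applicable (degenerate ensembles).
#' @param gaussian_jarzynski_gap |Gaussian - Jarzynski| gap, kcal/mol.
#' @param ci95 95% confidence half-width, kcal/mol.
#' @return Object of class `fgm_estimate`.
#' @keywords internal
new_fgm_estimate <- function(dG, method, temperature, n,
                             ad_statistic = NA_real_,
                             gaussian_jarzynski_gap = NA_real_,
                             ci95 = NA_real_) {
  stopifnot(is.finite(dG), method %in% c("gaussian", "jarzynski", "convolution"))
  structure(
    list(dG = dG, method = method, temperature = temperature, n = n,
         ad_statistic = ad_statistic,
         gaussian_jarzynski_gap = gaussian_jarzynski_gap,
         ci95 = ci95),
    class = "fgm_estimate")
}

#' @export
print.fgm_estimate <- function(x, ...) {
  ci <- if (is.finite(x$ci95)) sprintf(" ± %.3f", x$ci95) else ""
  cat(sprintf("<fgm_estimate> dG = %.4f%s kcal/mol (%s, n = %d, T = %g K)\n",
              x$dG, ci, x$method, x$n, x$temperature))
  if (is.finite(x$ad_statistic)) {
    cat(sprintf("  A*² = %.3f", x$ad_statistic))
    if (is.finite(x$gaussian_jarzynski_gap)) {
      cat(sprintf(", |gaussian - jarzynski| = %.3f kcal/mol", x$gaussian_jarzynski_gap))
    }
    cat("\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a free-energy estimate into a one-row tibble
#'
#' @param x An `fgm_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with columns `dG`, `method`, `ci95`,
#'   `ad_statistic`, `gaussian_jarzynski_gap`, `n`, `temperature`.
#' @method tidy fgm_estimate
#' @export
tidy.fgm_estimate <- function(x, ...) {
  tibble::tibble(
    dG = x$dG, method = x$method, ci95 = x$ci95,
    ad_statistic = x$ad_statistic,
    gaussian_jarzynski_gap = x$gaussian_jarzynski_gap,
    n = x$n, temperature = x$temperature)
}

#' @rdname tidy.fgm_estimate
#' @method glance fgm_estimate
#' @export
glance.fgm_estimate <- function(x, ...) tidy(x, ...)

#' Jarzynski free-energy estimate
#'
#' The nonequilibrium work identity \eqn{\Delta G = -RT \ln \langle
#' e^{-\beta W} \rangle} applied to a work ensemble. The exponential
#' average is computed with a max-shifted log-sum-exp, so very negative
#' works cannot overflow. By Jensen's inequality the estimate never
#' exceeds the mean work.
#'
#' @param works A `work_set`.
#' @return An `fgm_estimate` with `method = "jarzynski"`.
#' @examples
#' w <- work_set(c(0, 1.372), 300)
#' dg_jarzynski(w)$dG # ~0.356 kcal/mol
#' @export
dg_jarzynski <- function(works) {
  stopifnot(inherits(works, "work_set"))
  temperature <- ws_temperature(works)
  b <- beta_kcal(temperature)
  dG <- -log_mean_exp(-b * unclass(works)) / b
  new_fgm_estimate(dG, "jarzynski", temperature, length(works))
}

#' Crooks-Gaussian free-energy estimate
#'
#' For a normal work distribution, the Crooks fluctuation theorem gives the
#' closed form \eqn{\Delta G = \langle W\rangle - \beta\sigma^2/2}. The
#' unbiased (N-1) sample variance is used.
#'
#' @param works A `work_set` with at least 2 values.
#' @return An `fgm_estimate` with `method = "gaussian"`.
#' @examples
#' w <- work_set(c(-1, 0, 1), 300)
#' dg_gaussian(w)$dG # ~-0.839 kcal/mol
#' @export
dg_gaussian <- function(works) {
  stopifnot(inherits(works, "work_set"))
  if (length(works) < 2L) stop("Gaussian estimate needs N >= 2", call. = FALSE)
  temperature <- ws_temperature(works)
  b <- beta_kcal(temperature)
  v <- stats::var(unclass(works))
  dG <- mean(unclass(works)) - b * v / 2
  new_fgm_estimate(dG, "gaussian", temperature, length(works))
}

#' Anderson-Darling normality statistic A*^2
#'
#' The A^2 statistic for composite normality (both mean and variance
#' estimated from the sample) with the small-sample modification
#' \eqn{A^{*2} = A^2 (1 + 0.75/N + 2.25/N^2)}. The statistic is invariant
#' under affine rescaling of the data. Values below ~0.34 correspond to a
#' p-value above ~0.5 for the normal null.
#'
#' @param works A `work_set` (or plain numeric vector) with N >= 8.
#' @return The modified statistic A*^2 (scalar).
#' @examples
#' ad_normality(work_set(qnorm((1:50 - 0.5) / 50), 300)) # small, ~0.02
#' @export
ad_normality <- function(works) {
  x <- sort(as.numeric(unclass(works)))
  n <- length(x)
  if (n < 8L) stop("Anderson-Darling statistic needs N >= 8", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate sample", call. = FALSE)
  z <- (x - mean(x)) / s
  # tail-stable log CDF avoids log(0) for extreme standardized values
  logp <- stats::pnorm(z, log.p = TRUE)
  log1mp <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (logp + rev(log1mp)))
  a2 * (1 + 0.75 / n + 2.25 / n^2)
}

#' Estimator selection policy
#'
#' Thresholds for the normality-gated decision tree. The work distribution
#' is treated as normal when A*^2 < `ad_normal_threshold` (default 0.34,
#' p ~ 0.5); between the two thresholds the Gaussian estimate is still used
#' if it agrees with the Jarzynski estimate within `consistency_gap`
#' kcal/mol; otherwise the stage-convolution estimate is required.
#'
#' @param ad_normal_threshold Lower A*^2 threshold (default 0.34).
#' @param ad_upper_threshold Upper A*^2 threshold (default 0.754).
#' @param consistency_gap Gaussian/Jarzynski agreement bound, kcal/mol
#'   (default 0.2).
#' @return A list of class `decision_policy`.
#' @export
decision_policy <- function(ad_normal_threshold = 0.34,
                            ad_upper_threshold = 0.754,
                            consistency_gap = 0.2) {
  stopifnot(ad_normal_threshold > 0,
            ad_normal_threshold <= ad_upper_threshold,
            consistency_gap > 0)
  structure(list(ad_normal_threshold = ad_normal_threshold,
                 ad_upper_threshold = ad_upper_threshold,
                 consistency_gap = consistency_gap),
            class = "decision_policy")
}

#' Convolution-Jarzynski free-energy estimate
#'
#' For non-normal total work distributions arising from two independent
#' stages, the Jarzynski identity is applied to the convolution of the two
#' stage work distributions, i.e. to all `N_lj * N_qq` pairwise sums
#' `W_lj,i + W_qq,j`. Because the double sum factorizes, the estimate is
#' computed as the sum of the per-stage log-sum-exp averages without ever
#' materializing the pair array.
#'
#' @param stage A `stage_work_set`.
#' @return An `fgm_estimate` with `method = "convolution"` and `n` the
#'   number of pairwise sums.
#' @examples
#' s <- stage_work_set(work_set(c(2), 300), work_set(c(3), 300))
#' dg_convolution(s)$dG # 5
#' @export
dg_convolution <- function(stage) {
  stopifnot(inherits(stage, "stage_work_set"))
  temperature <- ws_temperature(stage)
  b <- beta_kcal(temperature)
  dG <- -(log_mean_exp(-b * unclass(stage$lj)) +
          log_mean_exp(-b * unclass(stage$qq))) / b
  new_fgm_estimate(dG, "convolution", temperature,
                   length(stage$lj) * length(stage$qq))
}

#' Normality-gated estimator selection
#'
#' Decision tree on the total work distribution: (i) if A*^2 falls below
#' the normal threshold the Crooks-Gaussian estimate is used; (ii) in the
#' gray zone between the two thresholds the Gaussian estimate is kept if it
#' differs from the Jarzynski estimate by less than the consistency gap;
#' (iii) otherwise the stage-convolution estimate is used, which requires
#' stage-resolved input. Constant (zero-variance) ensembles short-circuit
#' to the Gaussian branch, where the estimate equals the common work value
#' exactly and A*^2 is reported as `NA`.
#'
#' @param works A `stage_work_set` (total = lj + qq, paired) or a single
#'   `work_set` of total works (branch (iii) then errors, since the
#'   convolution is defined on stage works).
#' @param policy A [decision_policy()].
#' @return An `fgm_estimate` with the chosen method, A*^2 and the
#'   Gaussian-Jarzynski gap recorded.
#' @export
select_estimator <- function(works, policy = decision_policy()) {
  stopifnot(inherits(policy, "decision_policy"))
  staged <- inherits(works, "stage_work_set")
  total <- if (staged) total_work(works) else works
  stopifnot(inherits(total, "work_set"))

  if (stats::sd(unclass(total)) == 0) {
    est <- new_fgm_estimate(mean(unclass(total)), "gaussian",
                            ws_temperature(total), length(total))
    return(est)
  }

  a2 <- ad_normality(total)
  gau <- dg_gaussian(total)
  jar <- dg_jarzynski(total)
  gap <- abs(gau$dG - jar$dG)

  if (a2 < policy$ad_normal_threshold ||
      (a2 <= policy$ad_upper_threshold && gap < policy$consistency_gap)) {
    est <- gau
  } else {
    if (!staged) {
      stop("total work distribution is non-normal (A*² = ",
           signif(a2, 3), "); the convolution estimate needs stage-resolved ",
           "works (supply a stage_work_set)", call. = FALSE)
    }
    est <- dg_convolution(works)
  }
  est$ad_statistic <- a2
  est$gaussian_jarzynski_gap <- gap
  est
}

#' Stage-independence diagnostics
#'
#' Pearson and Kendall rank correlation between the per-trajectory
#' Lennard-Jones and recharging works. The convolution estimator assumes
#' the two stages are (nearly) independent; near-zero values support that
#' assumption. Kendall's tau uses the tie-corrected tau-b convention.
#'
#' @param stage A `stage_work_set` with equal stage lengths >= 3.
#' @return A one-row tibble with columns `pearson` and `kendall`.
#' @export
stage_independence <- function(stage) {
  stopifnot(inherits(stage, "stage_work_set"))
  x <- unclass(stage$lj); y <- unclass(stage$qq)
  if (length(x) != length(y)) {
    stop("independence diagnostics need trajectory-paired stages of equal length",
         call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 trajectory pairs", call. = FALSE)
  tibble::tibble(pearson = stats::cor(x, y),
                 kendall = stats::cor(x, y, method = "kendall"))
}

#' One-call free-energy estimate with confidence interval
#'
#' Runs the estimator decision tree (or a forced method) and attaches a 95%
#' confidence half-width: the analytic formula for Gaussian estimates, the
#' per-stage bootstrap combined in quadrature for Jarzynski/convolution
#' estimates.
#'
#' @param works A `work_set` or `stage_work_set`.
#' @param method `"auto"` (decision tree) or one of `"gaussian"`,
#'   `"jarzynski"`, `"convolution"`.
#' @param policy A [decision_policy()] (used by `"auto"`).
#' @param cfg A [ci_config()]; set to `NULL` to skip the CI.
#' @return An `fgm_estimate` with `ci95` filled in.
#' @export
estimate_free_energy <- function(works,
                                 method = c("auto", "gaussian", "jarzynski",
                                            "convolution"),
                                 policy = decision_policy(),
                                 cfg = ci_config()) {
  method <- match.arg(method)
  staged <- inherits(works, "stage_work_set")
  est <- switch(method,
    auto = select_estimator(works, policy),
    gaussian = dg_gaussian(if (staged) total_work(works) else works),
    jarzynski = dg_jarzynski(if (staged) total_work(works) else works),
    convolution = {
      if (!staged) stop("convolution estimate needs a stage_work_set", call. = FALSE)
      dg_convolution(works)
    })
  if (!is.null(cfg)) {
    est$ci95 <- if (est$method == "gaussian") {
      gaussian_ci(if (staged) total_work(works) else works, cfg)
    } else if (staged) {
      bootstrap_ci(works, cfg)
    } else {
      bootstrap_ci(works, cfg) # single-leg bootstrap
    }
  }
  est
}
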