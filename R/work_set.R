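#' Molar gas constant in kcal mol^-1 K^-1
#'
#' Used throughout to convert temperature to the inverse thermal energy
#' \eqn{\beta = 1/(RT)}. Work values are in kcal/mol, so the per-mole
#' convention applies.
#'
#' @export
GAS_CONSTANT_KCAL <- 1.987204e-3

#' Inverse thermal energy beta = 1/(RT)
#'
#' @param temperature Temperature in kelvin (> 0).
#' @return beta in mol/kcal.
#' @examples
#' beta_kcal(300) # ~1.6774
#' @export
beta_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), all(is.finite(temperature)), all(temperature > 0))
  1 / (GAS_CONSTANT_KCAL * temperature)
}

#' Work ensemble for one alchemical leg
#'
#' A `work_set` holds the per-trajectory recoupling work values (kcal/mol)
#' of one solute/solvent leg of a fast-growth calculation, together with the
#' temperature at which the trajectories were run and a free-text label.
#'
#' @param values Numeric vector of work values in kcal/mol; non-empty, finite.
#' @param temperature Temperature in kelvin.
#' @param label Optional free-text label (compound/solvent/protocol).
#' @return A numeric vector of class `work_set` with `temperature` and
#'   `label` attributes.
#' @examples
#' w <- work_set(c(2.0, 3.0), temperature = 300, label = "toy")
#' mean(w)
#' @export
work_set <- function(values, temperature, label = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no work values", call. = FALSE)
  if (!all(is.finite(values))) stop("work values must be finite", call. = FALSE)
  stopifnot(is.numeric(temperature), length(temperature) == 1L, is.finite(temperature))
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  structure(values,
            temperature = as.numeric(temperature),
            label = label,
            class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<work_set> n = %d, T = %g K%s\n", length(x),
              attr(x, "temperature"),
              if (is.null(lab)) "" else paste0(", label = ", lab)))
  cat(sprintf("  mean(W) = %.4f, sd(W) = %.4f kcal/mol\n",
              mean(unclass(x)), stats::sd(unclass(x))))
  invisible(x)
}

#' Temperature of a work ensemble
#' @param x A `work_set` or `stage_work_set`.
#' @return Temperature in kelvin.
#' @export
ws_temperature <- function(x) {
  if (inherits(x, "stage_work_set")) return(attr(x$lj, "temperature"))
  t <- attr(x, "temperature")
  if (is.null(t)) stop("object carries no temperature", call. = FALSE)
  t
}

#' Paired Lennard-Jones and recharging work ensembles
#'
#' The alchemical recoupling is performed in two stages: the Lennard-Jones
#' (cavitation/dispersion) switch-on, then the recharging of the solute.
#' `stage_work_set` pairs the two per-trajectory work ensembles. Equal
#' lengths are only required for independence diagnostics that pair values
#' by trajectory index; the convolution estimator does not need pairing.
#'
#' @param lj `work_set` of Lennard-Jones stage works.
#' @param qq `work_set` of recharging stage works.
#' @return A list of class `stage_work_set` with elements `lj` and `qq`.
#' @examples
#' s <- stage_work_set(work_set(rnorm(5), 300), work_set(rnorm(5), 300))
#' @export
stage_work_set <- function(lj, qq) {
  stopifnot(inherits(lj, "work_set"), inherits(qq, "work_set"))
  if (!isTRUE(all.equal(attr(lj, "temperature"), attr(qq, "temperature")))) {
    stop("lj and qq stages must share a temperature", call. = FALSE)
  }
  structure(list(lj = lj, qq = qq), class = "stage_work_set")
}

#' @export
print.stage_work_set <- function(x, ...) {
  cat(sprintf("<stage_work_set> n_lj = %d, n_qq = %d, T = %g K\n",
              length(x$lj), length(x$qq), ws_temperature(x)))
  invisible(x)
}

#' Per-trajectory total work of a two-stage ensemble
#'
#' Sums the Lennard-Jones and recharging work trajectory-by-trajectory.
#' Requires equal stage lengths (pairing by trajectory index).
#'
#' @param stage A `stage_work_set`.
#' @return A `work_set` of total works.
#' @export
total_work <- function(stage) {
  stopifnot(inherits(stage, "stage_work_set"))
  if (length(stage$lj) != length(stage$qq)) {
    stop("total work requires equal-length, trajectory-paired stages", call. = FALSE)
  }
  work_set(unclass(stage$lj) + unclass(stage$qq),
           temperature = ws_temperature(stage),
           label = attr(stage$lj, "label"))
}

# log of mean(exp(x)) with max-shift, stable for large |x|
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}
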