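#' RT ln(10) at a given temperature
#'
#' The divisor converting a solvation free-energy difference (kcal/mol)
#' into LogP units; ~1.372 kcal/mol at 300 K (often quoted rounded as
#' 1.37).
#'
#' @param temperature Kelvin.
#' @return kcal/mol per LogP unit.
#' @export
rt_ln10 <- function(temperature) {
  GAS_CONSTANT_KCAL * temperature * log(10)
}

#' 1-octanol/water partition coefficient from solvation free energies
#'
#' \deqn{\mathrm{Log}P = \frac{\Delta G_w - \Delta G_o}{RT\ln 10}}
#' Positive values mean the solute prefers the octanol phase. Vectorized
#' over the free energies.
#'
#' @param dg_w Hydration free energy, kcal/mol.
#' @param dg_o 1-octanol solvation free energy, kcal/mol.
#' @param temperature Kelvin (default 300).
#' @return LogP (dimensionless).
#' @examples
#' logp(-5.85, -5.43) # ~-0.31
#' logp(-6.60, -8.26) # ~1.21
#' @export
logp <- function(dg_w, dg_o, temperature = 300) {
  stopifnot(all(is.finite(dg_w)), all(is.finite(dg_o)))
  (dg_w - dg_o) / rt_ln10(temperature)
}

#' Propagated LogP half-width
#'
#' The two solvation legs are computed independently, so their confidence
#' half-widths combine in quadrature before conversion to LogP units.
#'
#' @param ci_w,ci_o Non-negative half-widths of the two legs, kcal/mol.
#' @param temperature Kelvin (default 300).
#' @return LogP half-width.
#' @export
logp_ci <- function(ci_w, ci_o, temperature = 300) {
  stopifnot(all(ci_w >= 0, na.rm = TRUE), all(ci_o >= 0, na.rm = TRUE))
  sqrt(ci_w^2 + ci_o^2) / rt_ln10(temperature)
}

#' Octanol-to-water transfer free energy from LogP
#'
#' Multiplies LogP by RT ln(10) (~1.37 kcal/mol per LogP unit at 300 K).
#'
#' @param logp_value LogP (dimensionless).
#' @param temperature Kelvin (default 300).
#' @return Transfer free energy, kcal/mol.
#' @export
transfer_free_energy <- function(logp_value, temperature = 300) {
  stopifnot(all(is.finite(logp_value)))
  logp_value * rt_ln10(temperature)
}

#' Assemble a LogP table from a per-compound free-energy table
#'
#' Takes a compound table (see [read_compound_table()]) and a protocol
#' name, and derives LogP, its propagated half-width (when the per-leg
#' half-width columns are present) and the transfer free energy for every
#' compound with both solvation legs. Compounds missing a leg are dropped
#' with a warning.
#'
#' @param table Tibble with `name`, `<protocol>_w`, `<protocol>_o` and
#'   optional `<protocol>_w_ci`, `<protocol>_o_ci` columns; optional
#'   `exp_w`/`exp_o` experimental legs yield an `logp_exp` column.
#' @param protocol Protocol column prefix, e.g. `"abcg2"`.
#' @param temperature Kelvin (default 300).
#' @return A tibble with columns `name`, `logp`, `ci`, `transfer_dG` (and
#'   `logp_exp` when experimental legs are present).
#' @export
build_logp_table <- function(table, protocol, temperature = 300) {
  w_col <- paste0(protocol, "_w"); o_col <- paste0(protocol, "_o")
  if (!all(c("name", w_col, o_col) %in% names(table))) {
    stop("table lacks columns ", w_col, " and/or ", o_col,
         " for protocol '", protocol, "'", call. = FALSE)
  }
  wc <- paste0(w_col, "_ci"); oc <- paste0(o_col, "_ci")
  has_ci <- all(c(wc, oc) %in% names(table))

  miss <- is.na(table[[w_col]]) | is.na(table[[o_col]])
  if (any(miss)) {
    warning("skipping compounds missing a solvation leg: ",
            paste(table$name[miss], collapse = ", "), call. = FALSE)
  }
  kept <- dplyr::filter(table, !miss)
  if (nrow(kept) == 0L) stop("no compound has both solvation legs", call. = FALSE)

  out <- tibble::tibble(
    name = kept$name,
    logp = logp(kept[[w_col]], kept[[o_col]], temperature),
    ci = if (has_ci) logp_ci(kept[[wc]], kept[[oc]], temperature) else NA_real_)
  out$transfer_dG <- transfer_free_energy(out$logp, temperature)
  if (all(c("exp_w", "exp_o") %in% names(kept))) {
    out$logp_exp <- logp(kept$exp_w, kept$exp_o, temperature)
  }
  out
}
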