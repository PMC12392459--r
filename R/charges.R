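#' Average atomic charges over conformers
#'
#' Unweighted per-atom mean of the conformer charge sets, with the per-atom
#' relative spread delta q / |q| (standard deviation over mean magnitude)
#' reported alongside. For charges fitted to conformations sampled from a
#' condensed-phase simulation a relative spread around 0.03-0.06 is
#' typical; atoms in that band are flagged `"normal"`.
#'
#' @param charges Long tibble with columns `atom`, `type`, `conformer`,
#'   `charge` (see [read_charge_sets()]); every conformer must cover the
#'   same atoms.
#' @return A tibble with columns `atom`, `type`, `charge` (mean),
#'   `rel_spread`, `spread_flag`, in the atom order of the input.
#' @export
average_charges <- function(charges) {
  check_charge_long(charges)
  n_conf <- dplyr::n_distinct(charges$conformer)
  out <- charges |>
    dplyr::group_by(.data$atom, .data$type) |>
    dplyr::summarise(
      n = dplyr::n(),
      sd = if (dplyr::n() > 1) stats::sd(.data$charge) else 0,
      charge = mean(.data$charge),
      .groups = "drop")
  if (any(out$n != n_conf)) {
    stop("mismatched atom labels across conformers", call. = FALSE)
  }
  # preserve input atom order
  out <- out[match(unique(charges$atom), out$atom), ]
  out |>
    dplyr::mutate(
      rel_spread = ifelse(.data$charge == 0, NA_real_,
                          .data$sd / abs(.data$charge)),
      spread_flag = dplyr::case_when(
        is.na(.data$rel_spread) ~ "undefined",
        .data$rel_spread >= 0.03 & .data$rel_spread <= 0.06 ~ "normal",
        .data$rel_spread < 0.03 ~ "low",
        TRUE ~ "high")) |>
    dplyr::select("atom", "type", "charge", "rel_spread", "spread_flag")
}

#' Convex combination of charge sets
#'
#' Population-weighted per-atom combination, e.g. mixing the averaged
#' charge sets of two conformational basins with their occupancies
#' (`weights = c(0.67, 0.33)`). The net charge of the result is exactly the
#' same convex combination of the input net charges.
#'
#' @param charges Long tibble as in [average_charges()]; the `conformer`
#'   column indexes the sets being combined.
#' @param weights Non-negative weights summing to 1 (within 1e-6), one per
#'   distinct set, in the order the sets first appear.
#' @return A tibble with columns `atom`, `type`, `charge`.
#' @export
combine_charge_sets <- function(charges, weights) {
  check_charge_long(charges)
  sets <- unique(charges$conformer)
  if (length(weights) != length(sets)) {
    stop("need one weight per charge set (", length(sets), ")", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  wtab <- tibble::tibble(conformer = sets, .w = as.numeric(weights))
  out <- charges |>
    dplyr::inner_join(wtab, by = "conformer") |>
    dplyr::group_by(.data$atom, .data$type) |>
    dplyr::summarise(charge = sum(.data$.w * .data$charge), .groups = "drop")
  out[match(unique(charges$atom), out$atom), c("atom", "type", "charge")]
}

#' Mean charge per atom type
#'
#' Groups a single charge set by its force-field atom-type string and
#' reports the group mean and atom count per type.
#'
#' @param charge_set Tibble with columns `atom`, `type`, `charge` (the
#'   output of [average_charges()] or one conformer of a long table).
#' @return A tibble with columns `type`, `charge` (mean), `n_atoms`.
#' @export
average_charge_by_type <- function(charge_set) {
  stopifnot(all(c("type", "charge") %in% names(charge_set)),
            nrow(charge_set) > 0)
  charge_set |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(charge = mean(.data$charge), n_atoms = dplyr::n(),
                     .groups = "drop")
}

#' Total (net) charge of a charge set
#'
#' @inheritParams average_charge_by_type
#' @param net_charge Optional declared net charge; when given, deviation
#'   beyond `tol` errors.
#' @param tol Tolerance in elementary charges (default 0.01).
#' @return The summed charge, invisibly checked against `net_charge`.
#' @export
net_charge <- function(charge_set, net_charge = NULL, tol = 0.01) {
  total <- sum(charge_set$charge)
  if (!is.null(net_charge) && abs(total - net_charge) > tol) {
    stop(sprintf("net charge %.4f deviates from declared %g by more than %g",
                 total, net_charge, tol), call. = FALSE)
  }
  total
}

check_charge_long <- function(charges) {
  need <- c("atom", "type", "conformer", "charge")
  if (!all(need %in% names(charges))) {
    stop("charge table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(charges) == 0L) stop("empty charge table", call. = FALSE)
  invisible(TRUE)
}
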