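#' Pearson correlation between experimental and calculated values
#'
#' @param x,y Equal-length numeric vectors (n >= 3, nonzero variance).
#' @return Product-moment correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  check_xy(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected tau-b; identical to tau-a when there are no ties.
#'
#' @inheritParams pearson
#' @return tau in [-1, 1].
#' @export
kendall_tau <- function(x, y) {
  check_xy(x, y)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("all-tied vector: Kendall tau undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "kendall")
}

#' Mean unsigned error
#' @param exp,calc Equal-length numeric vectors (same units).
#' @return mean |exp - calc|.
#' @export
mue <- function(exp, calc) {
  stopifnot(length(exp) == length(calc), length(exp) >= 1L)
  mean(abs(exp - calc))
}

#' Mean signed error
#'
#' Sign convention: experimental minus calculated, so overestimated
#' magnitudes of negative quantities give a positive MSE.
#'
#' @inheritParams mue
#' @return mean (exp - calc).
#' @export
mse <- function(exp, calc) {
  stopifnot(length(exp) == length(calc), length(exp) >= 1L)
  mean(exp - calc)
}

#' Best-fit line of calculated on experimental values
#'
#' Ordinary least squares with the calculated values as response and the
#' experimental values as regressor.
#'
#' @param x Experimental values (regressor).
#' @param y Calculated values (response).
#' @return Named numeric vector `c(slope =, intercept =)`.
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0) stop("degenerate regressor", call. = FALSE)
  cf <- stats::coef(stats::lm(y ~ x))
  c(slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\mathrm{CCC} = \frac{2\,\mathrm{cov}(x,y)}
#'   {\mathrm{var}(x)+\mathrm{var}(y)+(\bar x-\bar y)^2}}
#' with population (1/n) moments. CCC combines precision (Pearson
#' correlation) with accuracy (closeness of the best-fit line to the
#' identity); unlike Pearson's rho it is penalized by location and scale
#' shifts, and |CCC| <= |rho| always.
#'
#' @inheritParams pearson
#' @return CCC in [-1, 1].
#' @export
ccc <- function(x, y) {
  check_xy(x, y)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("zero variance and equal means: CCC undefined", call. = FALSE)
  2 * sxy / denom
}

check_xy <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  invisible(TRUE)
}

#' Full benchmark metric row
#'
#' Computes the seven standard benchmark metrics (CCC, Pearson rho, slope,
#' intercept, MUE, Kendall tau, MSE) for one experimental/calculated column
#' pair of a compound table, optionally excluding named outliers.
#'
#' @param data Data frame with a name column and the two value columns.
#' @param exp_col,calc_col Column names (strings) of the experimental and
#'   calculated values.
#' @param exclude Character vector of compound names to drop (must all be
#'   present in `data`).
#' @param name_col Name column (default `"name"`).
#' @return A one-row tibble with columns `ccc`, `pearson`, `slope`,
#'   `intercept`, `mue`, `kendall`, `mse`, `n_used`, `excluded`.
#' @export
metric_row <- function(data, exp_col, calc_col, exclude = NULL,
                       name_col = "name") {
  stopifnot(all(c(name_col, exp_col, calc_col) %in% names(data)))
  if (!is.null(exclude)) {
    missing_nm <- setdiff(exclude, data[[name_col]])
    if (length(missing_nm)) {
      stop("excluded names not in data: ", paste(missing_nm, collapse = ", "),
           call. = FALSE)
    }
    data <- data[!data[[name_col]] %in% exclude, , drop = FALSE]
  }
  data <- data[stats::complete.cases(data[, c(exp_col, calc_col)]), , drop = FALSE]
  if (nrow(data) < 3L) stop("fewer than 3 compounds retained", call. = FALSE)
  x <- data[[exp_col]]; y <- data[[calc_col]]
  line <- fit_line(x, y)
  tibble::tibble(
    ccc = ccc(x, y), pearson = pearson(x, y),
    slope = line[["slope"]], intercept = line[["intercept"]],
    mue = mue(x, y), kendall = kendall_tau(x, y), mse = mse(x, y),
    n_used = nrow(data),
    excluded = list(exclude %||% character(0)))
}

#' Metric rows for several calculated columns at once
#'
#' @inheritParams metric_row
#' @param calc_cols Character vector of calculated-value columns.
#' @return A tibble with one metric row per calculated column, first
#'   column `model`.
#' @export
metrics_table <- function(data, exp_col, calc_cols, exclude = NULL,
                          name_col = "name") {
  purrr::map_dfr(calc_cols, function(cl) {
    dplyr::bind_cols(tibble::tibble(model = cl),
                     metric_row(data, exp_col, cl, exclude, name_col))
  })
}

#' Pairwise concordance matrix across protocols
#'
#' Lin's CCC between every pair of the given columns; symmetric with a
#' unit diagonal.
#'
#' @param data Data frame holding the columns.
#' @param cols Character vector (>= 2) of column names.
#' @return A symmetric numeric matrix with `cols` as dimnames, class
#'   `ccc_matrix`.
#' @export
ccc_matrix <- function(data, cols) {
  stopifnot(length(cols) >= 2L, all(cols %in% names(data)))
  k <- length(cols)
  m <- diag(1, k)
  dimnames(m) <- list(cols, cols)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- ccc(data[[cols[i]]], data[[cols[j]]])
    }
  }
  class(m) <- c("ccc_matrix", class(m))
  m
}
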