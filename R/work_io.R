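#' Read a plain-text work-value file
#'
#' One work value (kcal/mol) per line; lines starting with `#` and blank
#' lines are ignored. Order is preserved.
#'
#' @param path File path.
#' @param temperature Kelvin.
#' @param label Optional label; defaults to the file name.
#' @return A [work_set()].
#' @export
read_work_file <- function(path, temperature, label = NULL) {
  if (!file.exists(path)) stop("work file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no work values in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(normalize_minus(trimws(lines[idx]))))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1]]
    stop("unparseable work value at line ", bad, " of ", path, call. = FALSE)
  }
  message(length(vals), " work values read from ", basename(path))
  work_set(vals, temperature, label = label %||% basename(path))
}

#' Write a work ensemble to a plain-text file
#'
#' @param works A `work_set`.
#' @param path Output path.
#' @param digits Decimal digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_work_file <- function(works, path, digits = 10) {
  stopifnot(inherits(works, "work_set"))
  header <- sprintf("# work values (kcal/mol), T = %g K%s",
                    ws_temperature(works),
                    if (is.null(attr(works, "label"))) "" else
                      paste0(", ", attr(works, "label")))
  writeLines(c(header, formatC(unclass(works), digits = digits,
                               format = "f")), path)
  invisible(path)
}

#' Read paired two-stage works
#'
#' Either two one-column files (`lj`, `qq`) or a single two-column
#' tab-separated file with header `W_lj`/`W_qq`.
#'
#' @param lj,qq Paths of the per-stage work files (one value per line).
#' @param tsv Path of a two-column TSV; mutually exclusive with `lj`/`qq`.
#' @param temperature Kelvin.
#' @return A [stage_work_set()].
#' @export
read_stage_work <- function(lj = NULL, qq = NULL, tsv = NULL, temperature) {
  if (!is.null(tsv)) {
    df <- utils::read.delim(tsv, comment.char = "#", check.names = FALSE)
    need <- c("W_lj", "W_qq")
    if (!all(need %in% names(df))) {
      stop("two-stage TSV needs columns W_lj and W_qq", call. = FALSE)
    }
    return(stage_work_set(
      work_set(df$W_lj, temperature, label = "lj"),
      work_set(df$W_qq, temperature, label = "qq")))
  }
  if (is.null(lj) || is.null(qq)) {
    stop("supply either tsv= or both lj= and qq=", call. = FALSE)
  }
  stage_work_set(read_work_file(lj, temperature, label = "lj"),
                 read_work_file(qq, temperature, label = "qq"))
}

# typographic dashes in pasted tables -> ASCII minus
normalize_minus <- function(x) {
  gsub("−|–|—", "-", x)
}

#' Read a per-compound free-energy table
#'
#' CSV with a header row, a required `name` column, optional experimental
#' columns `exp_w` / `exp_o`, and per-protocol columns `<protocol>_w`,
#' `<protocol>_o` with optional half-width columns `<protocol>_w_ci`,
#' `<protocol>_o_ci` (all kcal/mol). Typographic minus signs (en/em dash,
#' true minus) are normalized to ASCII. Missing cells are allowed.
#'
#' @param path CSV path.
#' @return A tibble, one row per compound.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("compound table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8", comment.char = "#")
  if (!"name" %in% names(raw)) stop("missing 'name' column", call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty compound table: ", path, call. = FALSE)
    return(tibble::as_tibble(raw))
  }
  if (anyDuplicated(raw$name)) {
    stop("duplicate compound names: ",
         paste(unique(raw$name[duplicated(raw$name)]), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(names(raw), "name")
  out <- tibble::as_tibble(raw)
  for (cl in num_cols) {
    v <- normalize_minus(trimws(out[[cl]]))
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(parsed)
    if (any(bad)) {
      stop("non-numeric value '", v[which(bad)[1]], "' in column ", cl,
           ", row ", which(bad)[1], call. = FALSE)
    }
    if (anyNA(parsed)) {
      message("column ", cl, ": ", sum(is.na(parsed)), " missing cell(s)")
    }
    out[[cl]] <- parsed
  }
  out
}

#' Write a per-compound free-energy table
#'
#' @param table Tibble/data frame with a `name` column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(table, path) {
  stopifnot("name" %in% names(table))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read per-conformer atomic charge sets
#'
#' CSV with columns `atom`, `type`, then one numeric charge column per
#' conformer (elementary charge units). Returns a long tibble with one row
#' per atom x conformer, the representation consumed by the charge
#' arithmetic functions.
#'
#' @param path CSV path.
#' @return A tibble with columns `atom`, `type`, `conformer`, `charge`.
#' @export
read_charge_sets <- function(path) {
  if (!file.exists(path)) stop("charge table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8", comment.char = "#")
  need <- c("atom", "type")
  if (!all(need %in% names(raw))) {
    stop("charge table needs columns 'atom' and 'type'", call. = FALSE)
  }
  conf_cols <- setdiff(names(raw), need)
  if (length(conf_cols) == 0L) stop("no conformer charge columns", call. = FALSE)
  for (cl in conf_cols) {
    v <- normalize_minus(trimws(raw[[cl]]))
    parsed <- suppressWarnings(as.numeric(v))
    if (anyNA(parsed)) {
      r <- which(is.na(parsed))[1]
      stop("non-numeric charge at column '", cl, "', row ", r, call. = FALSE)
    }
    raw[[cl]] <- parsed
  }
  tibble::as_tibble(raw) |>
    tidyr::pivot_longer(cols = dplyr::all_of(conf_cols),
                        names_to = "conformer", values_to = "charge")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
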