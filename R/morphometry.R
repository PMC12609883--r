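#' Add proportional orbital indices
#'
#' Computes the three dimensionless shape indices for every record:
#' Depth Index `di = depth_mm / width_mm`, Width Index
#' `wi = width_mm / height_mm` and Height Index `hi = height_mm / width_mm`.
#' Values are kept at full precision; round only for display (see
#' [round_half_up()]). By construction `hi * wi == 1` for every record.
#'
#' @param data A data frame with positive `depth_mm`, `height_mm`,
#'   `width_mm` columns.
#' @return `data` with `di`, `wi`, `hi` columns appended, as a tibble.
#' @examples
#' m <- tibble::tibble(depth_mm = 40.1, height_mm = 35.97, width_mm = 37.11)
#' add_indices(m)            # Type A mean dimensions: DI rounds to 1.08
#' @export
add_indices <- function(data) {
  check_dimension_cols(data)
  if (any(data$height_mm <= 0) || any(data$width_mm <= 0)) {
    abort("height_mm and width_mm must be strictly positive to form indices")
  }
  data |>
    tibble::as_tibble() |>
    dplyr::mutate(
      di = .data$depth_mm / .data$width_mm,
      wi = .data$width_mm / .data$height_mm,
      hi = .data$height_mm / .data$width_mm
    )
}

#' Round half away from zero
#'
#' Display rounding used for the indices and cut-offs: ties go away from
#' zero (1.085 -> 1.09), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(1.085)   # 1.09
#' round(1.085, 2)        # 1.08 under round-half-even
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Read orbit measurements from CSV
#'
#' Reads a delimited file of per-orbit measurements. The three dimension
#' columns (`depth_mm`, `height_mm`, `width_mm`) are required; rows whose
#' dimensions are missing or unparseable are rejected with row-numbered
#' errors. Missing covariate columns are filled with `"unknown"` (`side`,
#' `sex`, `modality`) or `NA` (`age_years`, `true_type`). Dimensions outside
#' a plausibility window trigger a warning, never rejection, so unusual but
#' real anatomy is kept.
#'
#' @param path Path to a CSV file.
#' @param plausible Length-2 numeric window (mm) outside which a warning is
#'   raised. Default `c(15, 70)`.
#' @return A tibble with the standard cohort columns.
#' @export
read_measurements <- function(path, plausible = c(15, 70)) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0L) abort("empty measurement file")
  missing <- setdiff(DIM_COLS, names(raw))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }

  dims <- lapply(DIM_COLS, function(col) suppressWarnings(as.numeric(raw[[col]])))
  names(dims) <- DIM_COLS
  bad <- Reduce(`|`, lapply(dims, function(x) !is.finite(x) | x <= 0))
  if (any(bad)) {
    abort(paste0("unparseable or non-positive dimension value(s) in row(s): ",
                 paste(which(bad), collapse = ", ")))
  }

  out <- tibble::tibble(
    orbit_id = raw[["orbit_id"]] %||% sprintf("row%05d", seq_len(nrow(raw))),
    side = raw[["side"]] %||% "unknown",
    sex = raw[["sex"]] %||% "unknown",
    age_years = suppressWarnings(as.numeric(raw[["age_years"]] %||% NA_character_)),
    depth_mm = dims$depth_mm,
    height_mm = dims$height_mm,
    width_mm = dims$width_mm,
    modality = raw[["modality"]] %||% "unknown",
    true_type = raw[["true_type"]] %||% NA_character_
  )
  out$side[is.na(out$side)] <- "unknown"
  out$sex[is.na(out$sex)] <- "unknown"
  out$modality[is.na(out$modality)] <- "unknown"

  vals <- unlist(dims, use.names = FALSE)
  n_implausible <- sum(vals < plausible[1] | vals > plausible[2])
  if (n_implausible > 0) {
    warn(paste0(n_implausible, " dimension value(s) outside the plausibility ",
                "window [", plausible[1], ", ", plausible[2], "] mm"))
  }
  out
}

#' Write orbit measurements to CSV
#'
#' Writes a cohort using the standard column set (UTF-8, decimal point).
#' With `indices = TRUE` the `di`, `wi`, `hi` columns are appended first.
#'
#' @param data Cohort data frame.
#' @param path Output path.
#' @param indices Append proportional indices? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path, indices = FALSE) {
  check_dimension_cols(data)
  if (indices) data <- add_indices(data)
  readr::write_csv(data, path)
  invisible(path)
}

check_dimension_cols <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  missing <- setdiff(DIM_COLS, names(data))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(data)
}
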