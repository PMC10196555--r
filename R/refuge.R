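#' Effective refuge percentage from crop areas
#'
#' Computes the share of the pest's selection habitat made up of non-Bt
#' host plants, weighting each crop's non-Bt area by its production of the
#' pest relative to non-Bt cotton:
#' \deqn{100 \cdot \frac{\sum_i a_i (1 - b_i) w_i}
#'                      {\sum_i a_i (1 - b_i) w_i + \sum_i a_i b_i}}
#' where for crop i, \eqn{a_i} is area, \eqn{b_i} the fraction of that
#' area planted to the Bt variety and \eqn{w_i} the per-hectare moth
#' production relative to non-Bt cotton (which has weight 1). Bt cotton
#' enters the denominator hectare-for-hectare as selection habitat with no
#' refuge contribution; the weighting for Bt area is configurable via
#' `bt_weight`.
#'
#' @param records Data frame of crop records for a single year with
#'   columns `year`, `crop`, `area_ha` (>= 0), `bt_fraction` (in \[0, 1\])
#'   and `production_weight` (>= 0, non-Bt cotton = 1).
#' @param bt_weight Weight per hectare of Bt-planted area in the
#'   denominator (default 1).
#' @return The effective refuge percentage, a single number in \[0, 100\].
#' @examples
#' crops <- tibble::tibble(
#'   year = 2019, crop = c("Bt cotton", "corn"),
#'   area_ha = c(2e6, 8e6), bt_fraction = c(1, 0),
#'   production_weight = c(1, 0.5)
#' )
#' effective_refuge_percentage(crops)
#' @export
effective_refuge_percentage <- function(records, bt_weight = 1) {
  validate_crop_records(records)
  if (length(unique(records$year)) > 1L) {
    abort("`records` mixes several years; pass one year at a time (or use effective_refuge_series()).")
  }
  non_bt <- sum(records$area_ha * (1 - records$bt_fraction) * records$production_weight)
  bt <- sum(records$area_ha * records$bt_fraction) * bt_weight
  if (non_bt + bt <= 0) {
    abort("No host-plant area at all: the effective refuge percentage is undefined.")
  }
  100 * non_bt / (non_bt + bt)
}

#' @describeIn effective_refuge_percentage Per-year series for a
#'   multi-year crop table: a tibble with columns `year`, `refuge_pct` and
#'   `refuge` (the fraction, usable directly in [scenario()]).
#' @export
effective_refuge_series <- function(records, bt_weight = 1) {
  validate_crop_records(records)
  records |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(~ tibble::tibble(
      refuge_pct = effective_refuge_percentage(
        dplyr::mutate(.x, year = .y$year), bt_weight = bt_weight))) |>
    dplyr::ungroup() |>
    dplyr::mutate(refuge = .data$refuge_pct / 100)
}

validate_crop_records <- function(records) {
  required <- c("year", "crop", "area_ha", "bt_fraction", "production_weight")
  if (!is.data.frame(records) || !all(required %in% names(records))) {
    abort(sprintf("Crop records need columns: %s.", paste(required, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("Crop records are empty.")
  if (any(records$area_ha < 0)) abort("`area_ha` must be >= 0.")
  check_fraction(records$bt_fraction, "bt_fraction", allow_vector = TRUE)
  if (any(records$production_weight < 0)) abort("`production_weight` must be >= 0.")
  invisible(records)
}

#' Yearly refuge series from a printed linear regression
#'
#' Reconstructs the effective-refuge series from the regression of
#' effective refuge percentage on calendar year reported for northern
#' China (y = 2.85x - 5667, with y in percent and x the year), evaluating
#' the line at each requested year and optionally clamping to \[0, 100\]%.
#' Useful when the underlying yearly crop-area table is not available.
#'
#' @param years Integer vector of years.
#' @param slope Regression slope in percent per year (default 2.85).
#' @param intercept Regression intercept in percent (default -5667).
#' @param clamp Clamp the refuge fraction to \[0, 1\] (default `TRUE`),
#'   guarding extrapolated years.
#' @return A tibble with columns `year`, `refuge_pct` and `refuge`
#'   (fraction in \[0, 1\] when clamped).
#' @examples
#' refuge_series_from_regression(2006:2020)
#' @export
refuge_series_from_regression <- function(years, slope = 2.85,
                                          intercept = -5667, clamp = TRUE) {
  if (length(years) == 0) abort("`years` must be non-empty.")
  pct <- slope * years + intercept
  if (clamp) pct <- pmin(100, pmax(0, pct))
  tibble::tibble(year = as.integer(years), refuge_pct = pct,
                 refuge = pct / 100)
}

#' Read a crop-area table from CSV
#'
#' Expects the header `year,crop,area_ha,bt_fraction,production_weight`.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of crop records.
#' @export
read_crop_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Crop table not found: %s", path))
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      year = readr::col_integer(),
      crop = readr::col_character(),
      area_ha = readr::col_double(),
      bt_fraction = readr::col_double(),
      production_weight = readr::col_double()
    )
  )
  validate_crop_records(records)
  records
}

#' Write a crop-area table to CSV
#'
#' @param records Crop records as produced by [make_crop_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_crop_table <- function(records, path) {
  validate_crop_records(records)
  readr::write_csv(records[c("year", "crop", "area_ha", "bt_fraction",
                             "production_weight")], path)
  invisible(path)
}
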