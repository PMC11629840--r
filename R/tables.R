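#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange bind_rows left_join n
#' @importFrom tibble tibble as_tibble
NULL

# Age-banded PreMO point tables. SER bands are contiguous with the middle
# band closed at both ends; AL bands are half-open, anchored at the lower
# printed bound of each higher band (printed bounds are at 0.01 mm
# precision, so e.g. 23.11 and 23.12 delimit adjacent bands).
.premo_bands <- c("age_6_8", "age_9_10")

.premo_tables <- list(
  age_6_8 = list(
    parental = c(`0` = 0L, `1` = 2L, `2` = 3L),
    # points for SER strictly below each break, last = above all breaks
    ser_breaks = c(1.00, 0.75),   # > 1.00 -> 0 ; [0.75, 1.00] -> 2 ; < 0.75 -> 3
    ser_points = c(0L, 2L, 3L),
    al_breaks  = c(22.94, 23.12, 23.19),  # lower bounds of the 1/2/3-point bands
    al_points  = c(0L, 1L, 2L, 3L),
    max_total  = 9L
  ),
  age_9_10 = list(
    parental = c(`0` = 0L, `1` = 1L, `2` = 2L),
    ser_breaks = c(0.875, 0.375),
    ser_points = c(0L, 1L, 2L),
    al_breaks  = c(23.33, 23.62),
    al_points  = c(0L, 1L, 2L),
    max_total  = 6L
  )
)

#' Risk categories for PreMO totals
#'
#' Fixed bins mapping a total PreMO score to a risk category and the
#' predicted refractive outcome. The bins are the same for both age bands;
#' in the 9--10 band the maximum total is 6, so the high-risk bin (7--9)
#' is unreachable there (see the methods vignette).
#'
#' @return A tibble with columns `total_min`, `total_max`, `label`,
#'   `predicted_outcome`.
#' @export
#' @examples
#' premo_risk_categories()
premo_risk_categories <- function() {
  tibble::tibble(
    total_min = c(0L, 1L, 4L, 7L),
    total_max = c(0L, 3L, 6L, 9L),
    label = factor(
      c("little_no_risk", "low", "moderate", "high"),
      levels = c("little_no_risk", "low", "moderate", "high")
    ),
    predicted_outcome = c(
      "likely to remain emmetropic",
      "likely to be myopic by 16 years of age",
      "likely to be myopic by 13 years of age",
      "likely to be myopic by 10 years of age"
    )
  )
}

#' Route a baseline age to a PreMO age band
#'
#' Ages in \[6, 9) use the 6--8-year table, ages in \[9, 11) the
#' 9--10-year table. Other ages have no published table and map to `NA`.
#'
#' @param age_years Numeric vector of decimal ages at baseline.
#' @return Character vector: `"age_6_8"`, `"age_9_10"` or `NA`.
#' @export
#' @examples
#' premo_band(c(6, 8.9, 9.7, 11.2))
premo_band <- function(age_years) {
  stopifnot(is.numeric(age_years))
  dplyr::case_when(
    age_years >= 6 & age_years < 9  ~ "age_6_8",
    age_years >= 9 & age_years < 11 ~ "age_9_10",
    .default = NA_character_
  )
}

.check_band <- function(band) {
  if (!all(band %in% .premo_bands)) {
    rlang::abort(paste0(
      "`band` must be one of ",
      paste0('"', .premo_bands, '"', collapse = ", "), "."
    ))
  }
  invisible(band)
}
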