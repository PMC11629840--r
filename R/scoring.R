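#' Points for parental myopia
#'
#' Number of myopic parents (0, 1 or 2) mapped to PreMO points for the
#' given age band: 0/2/3 points at ages 6--8, 0/1/2 at ages 9--10.
#'
#' @param n_myopic_parents Integer vector with values in `{0, 1, 2}`.
#' @param band `"age_6_8"` or `"age_9_10"`; recycled against
#'   `n_myopic_parents`.
#' @return Integer vector of points.
#' @export
#' @examples
#' score_parental(0:2, "age_6_8")
#' score_parental(0:2, "age_9_10")
score_parental <- function(n_myopic_parents, band) {
  .check_band(band)
  if (!all(is.na(n_myopic_parents) | n_myopic_parents %in% 0:2)) {
    rlang::abort("`n_myopic_parents` must be 0, 1 or 2.")
  }
  v <- suppressWarnings(
    mapply(function(n, b) {
      if (is.na(n)) NA_integer_ else .premo_tables[[b]]$parental[[as.character(n)]]
    }, n_myopic_parents, band)
  )
  as.integer(v)
}

#' Points for baseline cycloplegic SER
#'
#' Spherical equivalent refraction (dioptres) of the selected eye mapped
#' to PreMO points. Bands at 6--8 years: above +1.00 D scores 0,
#' +0.75 to +1.00 D scores 2, below +0.75 D scores 3. At 9--10 years:
#' above +0.875 D scores 0, +0.375 to +0.875 D scores 1, below +0.375 D
#' scores 2. The middle band is closed at both ends so the point
#' assignment covers every dioptre value.
#'
#' @param ser Numeric vector, dioptres.
#' @param band Age band, recycled against `ser`.
#' @return Integer vector of points.
#' @export
#' @examples
#' score_ser(c(1.25, 1.00, 0.50), "age_6_8")
score_ser <- function(ser, band) {
  .check_band(band)
  stopifnot(is.numeric(ser))
  v <- mapply(function(s, b) {
    if (is.na(s)) return(NA_integer_)
    tab <- .premo_tables[[b]]
    # middle band closed at both ends: 0 pts strictly above breaks[1],
    # full pts strictly below breaks[2]
    idx <- 1L + (s <= tab$ser_breaks[1]) + (s < tab$ser_breaks[2])
    tab$ser_points[[idx]]
  }, ser, band)
  as.integer(v)
}

#' Points for baseline axial length
#'
#' Axial length (mm) of the selected eye mapped to PreMO points using
#' half-open intervals anchored at the lower printed bound of each band:
#' at 6--8 years 0 points below 22.94 mm, then 1 / 2 / 3 points from
#' 22.94, 23.12 and 23.19 mm; at 9--10 years 0 points below 23.33 mm,
#' then 1 / 2 points from 23.33 and 23.62 mm.
#'
#' @param al Numeric vector, millimetres (positive).
#' @param band Age band, recycled against `al`.
#' @return Integer vector of points.
#' @export
#' @examples
#' score_al(c(22.5, 23.00, 23.19), "age_6_8")
score_al <- function(al, band) {
  .check_band(band)
  stopifnot(is.numeric(al))
  if (any(!is.na(al) & al <= 0)) rlang::abort("`al` must be positive (mm).")
  v <- mapply(function(a, b) {
    if (is.na(a)) return(NA_integer_)
    tab <- .premo_tables[[b]]
    tab$al_points[[sum(a >= tab$al_breaks) + 1L]]
  }, al, band)
  as.integer(v)
}

#' Select per-child SER and axial length from per-eye measurements
#'
#' Applies the PreMO eye-selection rule to a cohort data frame. Under the
#' `"least_hyperopic"` policy the eye with the algebraically smaller SER
#' (the least hyperopic / most emmetropic eye) supplies both SER and AL;
#' an exact SER tie uses the right eye. Under the `"mean"` policy the
#' supplied `ser_mean` / `al_mean` columns are used, for cohorts where
#' only between-eye means are recorded.
#'
#' @param data Data frame with columns `ser_right`, `ser_left`,
#'   `al_right`, `al_left` (least_hyperopic policy) or `ser_mean`,
#'   `al_mean` (mean policy). Missing columns are treated as all-`NA`.
#' @param eye_policy `"least_hyperopic"` (default) or `"mean"`.
#' @return `data` as a tibble with columns `ser_used`, `al_used`,
#'   `eye_used` (`"right"`, `"left"` or `"mean"`) appended. Rows missing
#'   the fields the policy needs raise an error naming the field.
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   ser_right = 1.25, ser_left = 0.75,
#'   al_right = 22.8, al_left = 23.1
#' )
#' select_eye_measurements(obs)
select_eye_measurements <- function(data,
                                    eye_policy = c("least_hyperopic", "mean")) {
  eye_policy <- match.arg(eye_policy)
  data <- tibble::as_tibble(data)
  needed <- if (eye_policy == "least_hyperopic") {
    c("ser_right", "ser_left", "al_right", "al_left")
  } else {
    c("ser_mean", "al_mean")
  }
  for (col in needed) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
    bad <- which(is.na(data[[col]]))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "eye policy \"%s\" requires `%s`; missing in row(s) %s.",
        eye_policy, col, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
  }
  if (eye_policy == "mean") {
    return(dplyr::mutate(data,
      ser_used = .data$ser_mean,
      al_used  = .data$al_mean,
      eye_used = "mean"
    ))
  }
  dplyr::mutate(data,
    eye_used = dplyr::if_else(.data$ser_left < .data$ser_right, "left", "right"),
    ser_used = dplyr::if_else(.data$eye_used == "left", .data$ser_left, .data$ser_right),
    al_used  = dplyr::if_else(.data$eye_used == "left", .data$al_left, .data$al_right)
  )
}

#' Compute PreMO risk scores for a cohort
#'
#' Scores each baseline observation: routes the child's age to an age
#' band, selects the working eye, looks up the three point components
#' (parental myopia, cycloplegic SER, axial length) and sums them, then
#' assigns the risk category. Children must be non-myopic at baseline
#' (selected SER > -0.50 D): already-myopic children have no pre-myopia
#' risk to stratify and are an error.
#'
#' @param data Cohort data frame; needs `age_years`, `n_myopic_parents`
#'   and the measurement columns required by `eye_policy` (see
#'   [select_eye_measurements()]).
#' @param eye_policy Passed to [select_eye_measurements()].
#' @param assume_no_parental_myopia If `TRUE`, missing
#'   `n_myopic_parents` is scored as 0 myopic parents (with a message);
#'   by default missing parental data is an error.
#' @return A tibble: the input plus `band`, `eye_used`, `ser_used`,
#'   `al_used`, `parental_points`, `ser_points`, `al_points`, `total`,
#'   `category`, `predicted_outcome`.
#' @export
#' @examples
#' premo_score(tibble::tibble(
#'   child_id = "a", age_years = 7, n_myopic_parents = 2,
#'   ser_mean = 0.50, al_mean = 23.20
#' ), eye_policy = "mean")
premo_score <- function(data,
                        eye_policy = c("least_hyperopic", "mean"),
                        assume_no_parental_myopia = FALSE) {
  eye_policy <- match.arg(eye_policy)
  data <- tibble::as_tibble(data)
  for (col in c("age_years", "n_myopic_parents")) {
    if (!col %in% names(data)) rlang::abort(sprintf("`data` lacks column `%s`.", col))
  }
  if (anyNA(data$n_myopic_parents)) {
    if (assume_no_parental_myopia) {
      n_fix <- sum(is.na(data$n_myopic_parents))
      rlang::inform(sprintf(
        "Assuming 0 myopic parents for %d record(s) with missing parental data.",
        n_fix
      ))
      data$n_myopic_parents[is.na(data$n_myopic_parents)] <- 0L
    } else {
      rlang::abort(paste(
        "missing `n_myopic_parents`; supply it or set",
        "`assume_no_parental_myopia = TRUE`."
      ))
    }
  }

  scored <- select_eye_measurements(data, eye_policy)
  scored$band <- premo_band(scored$age_years)
  if (anyNA(scored$band)) {
    bad <- which(is.na(scored$band))
    rlang::abort(sprintf(
      "age outside the supported bands [6, 9) and [9, 11) in row(s) %s.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  myopic_now <- which(scored$ser_used <= -0.50)
  if (length(myopic_now) > 0) {
    rlang::abort(sprintf(
      "row(s) %s are already myopic at baseline (selected SER <= -0.50 D).",
      paste(utils::head(myopic_now, 5), collapse = ", ")
    ))
  }

  scored <- dplyr::mutate(scored,
    parental_points = score_parental(.data$n_myopic_parents, .data$band),
    ser_points = score_ser(.data$ser_used, .data$band),
    al_points = score_al(.data$al_used, .data$band),
    total = .data$parental_points + .data$ser_points + .data$al_points
  )
  cat_info <- assign_risk_category(scored$total)
  scored$category <- cat_info$label
  scored$predicted_outcome <- cat_info$predicted_outcome
  scored
}

#' Assign PreMO risk categories to total scores
#'
#' Pure lookup of total score into the fixed bins 0 / 1--3 / 4--6 / 7--9.
#'
#' @param total Integer vector of total PreMO scores in \[0, 9\].
#' @return Tibble with columns `total`, `label` (ordered factor) and
#'   `predicted_outcome`.
#' @export
#' @examples
#' assign_risk_category(c(0, 5, 9))
assign_risk_category <- function(total) {
  if (!all(is.na(total) | (total >= 0 & total <= 9 & total == round(total)))) {
    rlang::abort("`total` must be integer scores in [0, 9].")
  }
  bins <- premo_risk_categories()
  idx <- findInterval(total, bins$total_min)
  tibble::tibble(
    total = as.integer(total),
    label = bins$label[idx],
    predicted_outcome = bins$predicted_outcome[idx]
  )
}
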