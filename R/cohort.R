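# Cohort CSV schema shared by the reader, writer and generators.
.cohort_columns <- c(
  "child_id", "age_years", "ser_right", "ser_left", "ser_mean",
  "al_right", "al_left", "al_mean", "n_myopic_parents",
  "outcome_age_years", "outcome_ser", "outcome_myopic"
)
.cohort_mandatory <- c("child_id", "age_years", "n_myopic_parents")

# Vectorised outcome labelling; returns myopic / basis / problem without
# raising, so callers can either abort or reject rows.
.label_outcome_impl <- function(outcome_ser, outcome_age_years,
                                onset_before_15, explicit_myopic) {
  n <- max(length(outcome_ser), length(outcome_age_years),
           length(onset_before_15), length(explicit_myopic), 1L)
  ser <- rep_len(outcome_ser %||% NA_real_, n)
  age <- rep_len(outcome_age_years %||% NA_real_, n)
  onset <- rep_len(onset_before_15 %||% NA, n)
  expl <- rep_len(explicit_myopic %||% NA, n)

  myopic <- rep(NA, n)
  basis <- rep(NA_character_, n)
  problem <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    if (!is.na(ser[i]) && !is.na(age[i]) && age[i] >= 15) {
      # definitive measurement at follow-up
      myopic[i] <- ser[i] <= -0.50
      basis[i] <- "measured_at_15plus"
      if (!is.na(expl[i]) && isTRUE(expl[i] != myopic[i])) {
        problem[i] <- "explicit outcome label contradicts outcome SER at age >= 15"
        myopic[i] <- NA
        basis[i] <- NA_character_
      }
    } else if (!is.na(ser[i]) && ser[i] <= -0.50) {
      # myopic SER documented before 15 (or at unknown age): onset is
      # established and is assumed to persist
      if (!is.na(expl[i]) && !expl[i]) {
        problem[i] <- "explicit non-myopic label contradicts myopic outcome SER"
      } else {
        myopic[i] <- TRUE
        basis[i] <- "carried_forward_onset"
      }
    } else if (isTRUE(onset[i])) {
      myopic[i] <- TRUE
      basis[i] <- "carried_forward_onset"
    } else if (!is.na(expl[i]) && expl[i]) {
      myopic[i] <- TRUE
      basis[i] <- "explicit_label"
    } else if (!is.na(expl[i]) && !expl[i]) {
      # a non-myopic label is only credible once the child has reached 15
      if (!is.na(age[i]) && age[i] >= 15) {
        myopic[i] <- FALSE
        basis[i] <- "explicit_label"
      } else {
        problem[i] <- "non-myopic label before age 15 cannot rule out later onset"
      }
    } else if (!is.na(ser[i])) {
      problem[i] <- "non-myopic outcome SER before age 15 with no onset flag is unresolvable"
    } else {
      problem[i] <- "no outcome information"
    }
  }
  tibble::tibble(myopic = as.logical(myopic), basis = basis, problem = problem)
}

#' Derive a myopia outcome label
#'
#' Applies the outcome definitions used throughout the package: myopia is
#' SER <= -0.50 D, and the refractive outcome is assessed at age 15 years
#' or older. A child with a documented myopic refraction (or an explicit
#' onset record) before 15 but no later measurement is assumed to have
#' remained myopic (`basis = "carried_forward_onset"`); a non-myopic
#' refraction before age 15 resolves nothing and is an error.
#'
#' @param outcome_ser Follow-up spherical equivalent refraction, dioptres
#'   (optional).
#' @param outcome_age_years Age at that measurement, decimal years
#'   (optional; compared with 15 exactly, no rounding).
#' @param onset_before_15 Logical: myopia onset documented before age 15
#'   with no later record.
#' @param explicit_myopic Logical outcome label recorded directly; it may
#'   only confirm, never override, a label derived from `outcome_ser` —
#'   a contradiction is an error.
#' @return Tibble with columns `myopic` (logical) and `basis` (one of
#'   `"measured_at_15plus"`, `"carried_forward_onset"`,
#'   `"explicit_label"`). Vectorised; inputs are recycled.
#' @export
#' @examples
#' label_outcome(outcome_ser = c(-0.75, -0.50, -0.25), outcome_age_years = 16)
#' label_outcome(onset_before_15 = TRUE)
label_outcome <- function(outcome_ser = NULL, outcome_age_years = NULL,
                          onset_before_15 = NULL, explicit_myopic = NULL) {
  res <- .label_outcome_impl(outcome_ser, outcome_age_years,
                             onset_before_15, explicit_myopic)
  if (any(!is.na(res$problem))) {
    first <- which(!is.na(res$problem))[1]
    rlang::abort(sprintf("outcome unresolvable: %s (element %d).",
                         res$problem[first], first))
  }
  res[c("myopic", "basis")]
}

#' Read and validate a cohort CSV
#'
#' Reads the child-level cohort schema (`child_id`, `age_years`, per-eye
#' and/or mean SER and AL, `n_myopic_parents`, `outcome_age_years`,
#' `outcome_ser`, `outcome_myopic`; empty cell = missing), validates each
#' row, and derives outcome labels via [label_outcome()]. Invalid rows
#' are rejected individually — with their line numbers and reasons kept
#' in the `"rejected"` attribute — rather than failing the whole file;
#' a missing mandatory column is a schema error.
#'
#' Rejection reasons include: `n_myopic_parents` outside 0--2, age
#' outside the supported bands, measurement columns incomplete for the
#' chosen eye policy, baseline already myopic (selected SER <= -0.50 D),
#' and unresolvable or self-contradictory outcome information.
#'
#' @param path CSV file path.
#' @param eye_policy `"least_hyperopic"` (per-eye data; default) or
#'   `"mean"` (cohorts recording only between-eye means).
#' @param require_outcome If `TRUE` (default) rows without a resolvable
#'   outcome are rejected; set `FALSE` to read baseline-only cohorts for
#'   scoring.
#' @param quiet Suppress the accepted/rejected row-count message.
#' @return Tibble of accepted records: the schema columns plus
#'   `ser_used`, `al_used`, `eye_used`, `band`, `myopic`,
#'   `outcome_basis` and `spearman_eligible` (outcome SER measured at
#'   age >= 15, the subset usable for rank correlation with outcome
#'   refraction). Attribute `"rejected"` is a tibble with `line`,
#'   `child_id`, `reason`.
#' @export
read_cohort <- function(path,
                        eye_policy = c("least_hyperopic", "mean"),
                        require_outcome = TRUE,
                        quiet = FALSE) {
  eye_policy <- match.arg(eye_policy)
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      outcome_myopic = readr::col_logical(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(.cohort_mandatory, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("cohort file lacks mandatory column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(.cohort_columns, names(raw))) {
    raw[[col]] <- if (col == "outcome_myopic") NA else NA_real_
  }
  raw <- raw[.cohort_columns]

  parse_problems <- readr::problems(raw)
  reason <- rep(NA_character_, nrow(raw))
  note <- function(rows, msg) {
    new <- intersect(rows, which(is.na(reason)))
    reason[new] <<- msg
  }
  if (nrow(parse_problems) > 0) {
    note(unique(parse_problems$row), "unparseable value")
  }
  note(which(is.na(raw$age_years)), "missing age_years")
  note(which(!is.na(raw$n_myopic_parents) &
               !raw$n_myopic_parents %in% 0:2),
       "n_myopic_parents outside 0-2")
  note(which(is.na(premo_band(raw$age_years))),
       "age outside supported bands [6, 9) and [9, 11)")

  if (eye_policy == "least_hyperopic") {
    complete <- !is.na(raw$ser_right) & !is.na(raw$ser_left) &
      !is.na(raw$al_right) & !is.na(raw$al_left)
    note(which(!complete), "incomplete per-eye SER/AL for least_hyperopic policy")
    left <- !is.na(raw$ser_left) & !is.na(raw$ser_right) &
      raw$ser_left < raw$ser_right
    raw$eye_used <- dplyr::if_else(left, "left", "right")
    raw$ser_used <- dplyr::if_else(left, raw$ser_left, raw$ser_right)
    raw$al_used <- dplyr::if_else(left, raw$al_left, raw$al_right)
  } else {
    complete <- !is.na(raw$ser_mean) & !is.na(raw$al_mean)
    note(which(!complete), "incomplete mean SER/AL for mean policy")
    raw$eye_used <- "mean"
    raw$ser_used <- raw$ser_mean
    raw$al_used <- raw$al_mean
  }
  note(which(!is.na(raw$ser_used) & raw$ser_used <= -0.50),
       "already myopic at baseline (selected SER <= -0.50 D)")

  lab <- .label_outcome_impl(raw$outcome_ser, raw$outcome_age_years,
                             onset_before_15 = NULL,
                             explicit_myopic = raw$outcome_myopic)
  raw$myopic <- lab$myopic
  raw$outcome_basis <- lab$basis
  raw$spearman_eligible <- !is.na(lab$basis) & lab$basis == "measured_at_15plus"
  if (require_outcome) {
    for (i in which(!is.na(lab$problem))) {
      if (is.na(reason[i])) reason[i] <- paste0("outcome: ", lab$problem[i])
    }
  }

  ok <- is.na(reason)
  rejected <- tibble::tibble(
    line = which(!ok) + 1L,  # +1 for the header row
    child_id = raw$child_id[!ok],
    reason = reason[!ok]
  )
  accepted <- raw[ok, , drop = FALSE]
  if (!quiet) {
    rlang::inform(sprintf("read_cohort: %d record(s) accepted, %d rejected (%s).",
                          nrow(accepted), nrow(rejected), basename(path)))
  }
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Write a cohort to CSV
#'
#' Emits the cohort schema read by [read_cohort()] (derived columns such
#' as `ser_used` or `myopic` are not written; `outcome_myopic` is filled
#' from a derived `myopic` column when absent, so labels survive the
#' round trip).
#'
#' @param data Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  data <- tibble::as_tibble(data)
  if (!"outcome_myopic" %in% names(data) || all(is.na(data$outcome_myopic))) {
    if ("myopic" %in% names(data)) data$outcome_myopic <- data$myopic
  }
  for (col in setdiff(.cohort_columns, names(data))) {
    data[[col]] <- if (col == "outcome_myopic") NA else NA_real_
  }
  readr::write_csv(data[.cohort_columns], path, na = "", progress = FALSE)
  invisible(path)
}
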