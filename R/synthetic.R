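# Deterministic decompositions of a target total into (parental, ser, al)
# point components, one per reachable total, plus mid-band measurement
# values realising each point count. Mid-band values sit well inside each
# printed interval, so fixtures are insensitive to the boundary
# conventions adopted for the score tables.
.fixture_decomp <- list(
  age_6_8 = list(
    # total: parental, ser, al points
    `0` = c(0L, 0L, 0L), `1` = c(0L, 0L, 1L), `2` = c(2L, 0L, 0L),
    `3` = c(3L, 0L, 0L), `4` = c(3L, 0L, 1L), `5` = c(2L, 2L, 1L),
    `6` = c(3L, 3L, 0L), `7` = c(3L, 3L, 1L), `8` = c(3L, 3L, 2L),
    `9` = c(3L, 3L, 3L)
  ),
  age_9_10 = list(
    `0` = c(0L, 0L, 0L), `1` = c(0L, 1L, 0L), `2` = c(1L, 1L, 0L),
    `3` = c(1L, 1L, 1L), `4` = c(2L, 1L, 1L), `5` = c(2L, 2L, 1L),
    `6` = c(2L, 2L, 2L)
  )
)

.fixture_values <- list(
  age_6_8 = list(
    parents = c(`0` = 0L, `2` = 1L, `3` = 2L),          # points -> n parents
    ser = c(`0` = 2.00, `2` = 0.875, `3` = 0.25),       # points -> dioptres
    al = c(`0` = 22.50, `1` = 23.02, `2` = 23.15, `3` = 23.40),  # points -> mm
    age = 7.0
  ),
  age_9_10 = list(
    parents = c(`0` = 0L, `1` = 1L, `2` = 2L),
    ser = c(`0` = 1.50, `1` = 0.625, `2` = 0.00),
    al = c(`0` = 23.00, `1` = 23.47, `2` = 23.80),
    age = 9.5
  )
)

#' Fixture measurement values by point component
#'
#' The constant mid-band SER/AL/parental values used by the fixture
#' builders to realise a given point count through the scoring tables.
#'
#' @return Nested list by band and factor.
#' @export
premo_fixture_values <- function() .fixture_values

.obs_for_totals <- function(totals, band, id_prefix) {
  decomp <- .fixture_decomp[[band]]
  vals <- .fixture_values[[band]]
  pts <- do.call(rbind, decomp[as.character(totals)])
  ser <- unname(vals$ser[as.character(pts[, 2])])
  al <- unname(vals$al[as.character(pts[, 3])])
  tibble::tibble(
    child_id = sprintf("%s_%04d", id_prefix, seq_along(totals)),
    age_years = vals$age,
    ser_right = ser, ser_left = ser, ser_mean = ser,
    al_right = al, al_left = al, al_mean = al,
    n_myopic_parents = unname(vals$parents[as.character(pts[, 1])])
  )
}

# Spread target totals over the available range on each side of the
# cut-off, cycling deterministically, so the ROC sweep sees a realistic
# spread of scores while the confusion counts at `cutoff` are exact.
.spread_totals <- function(k, from, to) {
  if (k == 0) return(integer(0))
  from + (seq_len(k) - 1L) %% (to - from + 1L)
}

#' Build an exact cohort from confusion counts
#'
#' Reconstructs a child-level cohort from a published confusion table of
#' the PreMO score at a cut-off: exactly `tp + fn` myopes and `tn + fp`
#' non-myopes, whose observations (SER, AL, parental myopia — never
#' injected totals) score at or above the cut-off for the `tp`/`fp`
#' records and below it otherwise. Re-scoring the fixture through
#' [premo_score()] and [confusion_at_cutoff()] reproduces the requested
#' counts exactly. Outcome SER is emitted at age 16, linked negatively to
#' the total, so rank correlations are also exercised.
#'
#' @param tp,fp,tn,fn Confusion counts (non-negative integers).
#' @param cutoff Score cut-off the counts refer to (default 4).
#' @param band `"age_6_8"` or `"age_9_10"`.
#' @return Cohort tibble in the schema of [read_cohort()].
#' @export
#' @examples
#' fx <- fixture_from_confusion(tp = 32, fp = 1, tn = 23, fn = 1)
#' nrow(fx)
fixture_from_confusion <- function(tp, fp, tn, fn, cutoff = 4,
                                   band = c("age_6_8", "age_9_10")) {
  band <- match.arg(band)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) rlang::abort("all confusion counts are zero: nothing to build.")
  max_total <- .premo_tables[[band]]$max_total
  if (cutoff < 1 || cutoff > max_total) {
    rlang::abort(sprintf("`cutoff` must be in [1, %d] for band %s.", max_total, band))
  }
  pieces <- list(
    tp = list(k = tp, myopic = TRUE, from = cutoff, to = max_total),
    fn = list(k = fn, myopic = TRUE, from = 0L, to = cutoff - 1L),
    fp = list(k = fp, myopic = FALSE, from = cutoff, to = max_total),
    tn = list(k = tn, myopic = FALSE, from = 0L, to = cutoff - 1L)
  )
  rows <- purrr::imap(pieces, function(p, nm) {
    if (p$k == 0) return(NULL)
    totals <- .spread_totals(p$k, p$from, p$to)
    obs <- .obs_for_totals(totals, band, nm)
    obs$outcome_age_years <- 16
    obs$outcome_ser <- if (p$myopic) -0.75 - 0.30 * totals else 1.00 - 0.10 * totals
    obs$outcome_myopic <- p$myopic
    obs
  })
  dplyr::bind_rows(rows)
}

#' Build a cohort realising singular-predictor counts
#'
#' Like [fixture_from_confusion()], but the counts refer to a raw
#' baseline measurement (SER below a cut-off, or AL at/above one) rather
#' than the PreMO total: the fixture places each record's raw SER or AL
#' on the required side of the cut-off. The untargeted measurement and
#' parental history take neutral defaults.
#'
#' @param feature `"ser"` (positive call below `cutoff`) or `"al"`
#'   (positive call at/above `cutoff`).
#' @param cutoff Measurement cut-off (dioptres for SER, mm for AL).
#' @inheritParams fixture_from_confusion
#' @return Cohort tibble in the schema of [read_cohort()].
#' @export
fixture_singular <- function(feature = c("ser", "al"), cutoff,
                             tp, fp, tn, fn,
                             band = c("age_6_8", "age_9_10")) {
  feature <- match.arg(feature)
  band <- match.arg(band)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0) {
    rlang::abort("all confusion counts are zero: nothing to build.")
  }
  vals <- .fixture_values[[band]]
  if (feature == "ser") {
    pos_val <- cutoff - 0.50   # safely below the cut-off, still > -0.50 D
    neg_val <- cutoff + 0.50
    if (pos_val <= -0.50) rlang::abort("SER cut-off too low to keep baselines non-myopic.")
  } else {
    pos_val <- cutoff + 0.33
    neg_val <- cutoff - 0.57
  }
  pieces <- list(
    tp = list(k = tp, myopic = TRUE, positive = TRUE),
    fn = list(k = fn, myopic = TRUE, positive = FALSE),
    fp = list(k = fp, myopic = FALSE, positive = TRUE),
    tn = list(k = tn, myopic = FALSE, positive = FALSE)
  )
  rows <- purrr::imap(pieces, function(p, nm) {
    if (p$k == 0) return(NULL)
    v <- if (p$positive) pos_val else neg_val
    ser <- if (feature == "ser") rep(v, p$k) else rep(1.00, p$k)
    al <- if (feature == "al") rep(v, p$k) else rep(23.00, p$k)
    tibble::tibble(
      child_id = sprintf("%s_%04d", nm, seq_len(p$k)),
      age_years = vals$age,
      ser_right = ser, ser_left = ser, ser_mean = ser,
      al_right = al, al_left = al, al_mean = al,
      n_myopic_parents = 1L,
      outcome_age_years = 16,
      outcome_ser = if (p$myopic) -1.00 else 0.50,
      outcome_myopic = p$myopic
    )
  })
  dplyr::bind_rows(rows)
}

# Published contingency counts for the external-validation cohorts:
# the inputs the fixture builders reconstruct cohorts from.
.premo_published_counts <- list(
  table4 = list(
    uk_6_8   = list(tp = 32L, fp = 1L, tn = 23L, fn = 1L,
                    cutoff = 4, band = "age_6_8"),
    hk_6_8   = list(tp = 206L, fp = 5L, tn = 9L, fn = 14L,
                    cutoff = 4, band = "age_6_8"),
    hk_9_10  = list(tp = 51L, fp = 5L, tn = 13L, fn = 6L,
                    cutoff = 4, band = "age_9_10")
  ),
  table5 = list(
    uk_6_8_ser = list(feature = "ser", cutoff = 0.75,
                      tp = 32L, fp = 4L, tn = 20L, fn = 1L, band = "age_6_8"),
    uk_6_8_al  = list(feature = "al", cutoff = 23.07,
                      tp = 17L, fp = 0L, tn = 24L, fn = 16L, band = "age_6_8"),
    hk_6_8_ser = list(feature = "ser", cutoff = 0.75,
                      tp = 182L, fp = 2L, tn = 12L, fn = 38L, band = "age_6_8"),
    hk_6_8_al  = list(feature = "al", cutoff = 23.07,
                      tp = 73L, fp = 2L, tn = 12L, fn = 147L, band = "age_6_8")
  )
)

#' Named fixture cohorts from published contingency counts
#'
#' Convenience wrapper building the validation-cohort fixtures from the
#' published PreMO performance counts: `table = 4` rows (`"uk_6_8"`,
#' `"hk_6_8"`, `"hk_9_10"`) reconstruct the PreMO-score confusion tables
#' at cut-off >= 4; `table = 5` rows (`"uk_6_8_ser"`, `"uk_6_8_al"`,
#' `"hk_6_8_ser"`, `"hk_6_8_al"`) reconstruct the singular-predictor
#' tables for SER < +0.75 D and AL >= 23.07 mm.
#'
#' @param table 4 or 5.
#' @param row Row name; see above, or call with `row = NULL` to list the
#'   available names.
#' @return Cohort tibble, or a character vector of row names.
#' @export
#' @examples
#' premo_fixture(4, NULL)
#' fx <- premo_fixture(4, "uk_6_8")
#' table(fx$outcome_myopic)
premo_fixture <- function(table, row) {
  key <- paste0("table", table)
  if (!key %in% names(.premo_published_counts)) {
    rlang::abort("`table` must be 4 or 5.")
  }
  rows <- .premo_published_counts[[key]]
  if (is.null(row)) return(names(rows))
  if (!row %in% names(rows)) {
    rlang::abort(sprintf("unknown row \"%s\"; available: %s.",
                         row, paste(names(rows), collapse = ", ")))
  }
  p <- rows[[row]]
  if (table == 4) {
    fixture_from_confusion(p$tp, p$fp, p$tn, p$fn, cutoff = p$cutoff,
                           band = p$band)
  } else {
    fixture_singular(p$feature, p$cutoff, p$tp, p$fp, p$tn, p$fn,
                     band = p$band)
  }
}

#' Specify a synthetic cohort
#'
#' Parameters of the generative model used by [generate_cohort()]:
#' baseline (SER, AL) bivariate normal with a negative correlation
#' (longer eyes are less hyperopic), truncated to non-myopic baselines
#' (SER > -0.50 D); parental myopia multinomial; myopia by age 15+
#' Bernoulli with probability `plogis(onset_intercept + onset_slope *
#' total)`, linking onset risk to the PreMO total.
#'
#' @param n Cohort size.
#' @param band Age band.
#' @param parental_probs Probabilities of 0/1/2 myopic parents (sums
#'   to 1).
#' @param ser_mean,ser_sd Baseline SER distribution, dioptres.
#' @param al_mean,al_sd Baseline AL distribution, mm.
#' @param ser_al_corr Correlation between SER and AL, in \[-1, 0\].
#' @param onset_intercept,onset_slope Logistic-link coefficients from the
#'   PreMO total to the probability of myopia by 15.
#' @param outcome_ser_noise_sd Noise SD of the follow-up SER, dioptres.
#' @param seed Integer seed (required; each [generate_cohort()] call uses
#'   a single stream seeded from it and leaves global RNG state alone).
#' @return A `premo_cohort_spec` list.
#' @export
cohort_spec <- function(n, band = c("age_6_8", "age_9_10"),
                        parental_probs = c(0.4, 0.4, 0.2),
                        ser_mean = 1.0, ser_sd = 0.6,
                        al_mean = 22.8, al_sd = 0.65,
                        ser_al_corr = -0.45,
                        onset_intercept = 0, onset_slope = 0.9,
                        outcome_ser_noise_sd = 0.35,
                        seed) {
  band <- match.arg(band)
  if (missing(seed)) rlang::abort("`seed` is required.")
  stopifnot(
    n > 0, length(parental_probs) == 3, all(parental_probs >= 0),
    abs(sum(parental_probs) - 1) < 1e-8,
    ser_sd > 0, al_sd > 0, outcome_ser_noise_sd > 0,
    ser_al_corr >= -1, ser_al_corr <= 0
  )
  structure(list(
    n = as.integer(n), band = band, parental_probs = parental_probs,
    ser_mean = ser_mean, ser_sd = ser_sd,
    al_mean = al_mean, al_sd = al_sd, ser_al_corr = ser_al_corr,
    onset_intercept = onset_intercept, onset_slope = onset_slope,
    outcome_ser_noise_sd = outcome_ser_noise_sd,
    seed = as.integer(seed)
  ), class = "premo_cohort_spec")
}

#' Load a calibrated cohort preset
#'
#' Presets are YAML files shipped with the package
#' (`inst/extdata/presets/`) describing a UK-like population cohort
#' (`"uk_6_8"`, myopia incidence calibrated to ~58%) and Hong-Kong-like
#' clinic cohorts (`"hk_6_8"` ~94%, `"hk_9_10"` ~76%). The YAML states
#' every generative parameter; `n` and `seed` are supplied per call.
#'
#' @param name Preset name, or `NULL` to list available presets.
#' @param n,seed Passed to [cohort_spec()].
#' @return A `premo_cohort_spec`, or a character vector of names.
#' @export
premo_preset <- function(name = NULL, n = 1000, seed) {
  dir <- system.file("extdata", "presets", package = "premor")
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (is.null(name)) return(avail)
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path)) {
    rlang::abort(sprintf("unknown preset \"%s\"; available: %s.",
                         name, paste(avail, collapse = ", ")))
  }
  y <- yaml::read_yaml(path)
  cohort_spec(
    n = n, band = y$band, parental_probs = unlist(y$parental_probs),
    ser_mean = y$ser_mean, ser_sd = y$ser_sd,
    al_mean = y$al_mean, al_sd = y$al_sd, ser_al_corr = y$ser_al_corr,
    onset_intercept = y$onset_intercept, onset_slope = y$onset_slope,
    outcome_ser_noise_sd = y$outcome_ser_noise_sd,
    seed = seed
  )
}

#' Generate a synthetic cohort
#'
#' Draws a child-level cohort under the model described in
#' [cohort_spec()]: truncated bivariate-normal baseline biometry,
#' multinomial parental myopia, two per-eye records (the least hyperopic
#' eye carries the drawn values; the fellow eye is slightly more
#' hyperopic and shorter), PreMO totals computed through the scoring
#' tables, and a logistic score-linked myopia outcome with follow-up SER
#' at ages 15--18 (myopes below -0.50 D with score-linked magnitude).
#' Fully reproducible: a fixed spec (including seed) yields an identical
#' cohort.
#'
#' @param spec A `premo_cohort_spec` from [cohort_spec()] or
#'   [premo_preset()].
#' @return Scored cohort tibble: the CSV schema columns plus `ser_used`,
#'   `al_used`, `eye_used`, `band`, point components, `total`,
#'   `category`, `myopic`, `outcome_basis`, `spearman_eligible`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 50, seed = 7))
#' incidence(cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "premo_cohort_spec"))
  n <- spec$n
  withr::with_seed(spec$seed, {
    sigma <- matrix(c(
      spec$ser_sd^2, spec$ser_al_corr * spec$ser_sd * spec$al_sd,
      spec$ser_al_corr * spec$ser_sd * spec$al_sd, spec$al_sd^2
    ), 2, 2)
    # rejection-sample baselines until all are non-myopic (SER > -0.50)
    ser <- numeric(0); al <- numeric(0)
    for (round in seq_len(50)) {
      draw <- MASS::mvrnorm(max(2L * n, 100L),
                            mu = c(spec$ser_mean, spec$al_mean), Sigma = sigma)
      keep <- draw[, 1] > -0.50 & draw[, 2] > 0
      ser <- c(ser, draw[keep, 1])
      al <- c(al, draw[keep, 2])
      if (length(ser) >= n) break
    }
    if (length(ser) < n) {
      rlang::abort(paste(
        "could not draw enough non-myopic baselines;",
        "the spec's SER distribution lies almost entirely below -0.50 D."
      ))
    }
    ser <- ser[seq_len(n)]; al <- al[seq_len(n)]

    age <- if (spec$band == "age_6_8") stats::runif(n, 6, 8.99) else stats::runif(n, 9, 10.99)
    parents <- sample(0:2, n, replace = TRUE, prob = spec$parental_probs)
    # fellow eye: more hyperopic and a little shorter than the selected eye
    d_ser <- abs(stats::rnorm(n, 0, 0.25))
    d_al <- abs(stats::rnorm(n, 0, 0.10))
    left_is_worse <- stats::runif(n) < 0.5
    obs <- tibble::tibble(
      child_id = sprintf("sim_%05d", seq_len(n)),
      age_years = age,
      ser_right = ifelse(left_is_worse, ser, ser + d_ser),
      ser_left = ifelse(left_is_worse, ser + d_ser, ser),
      ser_mean = NA_real_,
      al_right = ifelse(left_is_worse, al, pmax(al - d_al, 15)),
      al_left = ifelse(left_is_worse, pmax(al - d_al, 15), al),
      al_mean = NA_real_,
      n_myopic_parents = parents
    )
    scored <- premo_score(obs, eye_policy = "least_hyperopic")
    p_myopia <- stats::plogis(spec$onset_intercept + spec$onset_slope * scored$total)
    myopic <- stats::rbinom(n, 1, p_myopia) == 1
    noise <- stats::rnorm(n, 0, spec$outcome_ser_noise_sd)
    scored$outcome_age_years <- stats::runif(n, 15, 18)
    scored$outcome_ser <- ifelse(
      myopic,
      pmin(-0.50, -0.75 - 0.30 * scored$total + noise),
      pmax(-0.45, 0.75 - 0.10 * scored$total + noise)
    )
    scored$outcome_myopic <- myopic
    scored$myopic <- myopic
    scored$outcome_basis <- "measured_at_15plus"
    scored$spearman_eligible <- TRUE
    scored
  })
}
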