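#' Define a predictor of future myopia
#'
#' A predictor is a feature of the scored cohort plus a cut-off and the
#' direction of a positive (at-risk) call. Directions are fixed by
#' convention: the PreMO total and axial length call positive at or above
#' the cut-off, SER calls positive below it (a smaller hyperopic reserve
#' means higher risk).
#'
#' @param feature `"premo_score"`, `"ser"` or `"al"`.
#' @param cutoff Numeric cut-off (e.g., 4 for the PreMO total, +0.75 D
#'   for SER, 23.07 mm for AL).
#' @param direction `"ge"` or `"lt"`; defaults to the convention above.
#' @return A `premo_predictor` list with `feature`, `cutoff`, `direction`.
#' @export
#' @examples
#' predictor_spec("premo_score", 4)
#' predictor_spec("ser", 0.75)
predictor_spec <- function(feature = c("premo_score", "ser", "al"),
                           cutoff, direction = NULL) {
  feature <- match.arg(feature)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1)
  default_dir <- if (feature == "ser") "lt" else "ge"
  direction <- direction %||% default_dir
  if (!direction %in% c("ge", "lt")) rlang::abort('`direction` must be "ge" or "lt".')
  structure(list(feature = feature, cutoff = cutoff, direction = direction),
            class = "premo_predictor")
}

.feature_column <- c(premo_score = "total", ser = "ser_used", al = "al_used")

.feature_values <- function(data, feature) {
  col <- .feature_column[[feature]]
  if (is.null(col) || !col %in% names(data)) {
    rlang::abort(sprintf(
      "feature \"%s\" needs column `%s`; score the cohort with premo_score() first.",
      feature, col %||% feature
    ))
  }
  data[[col]]
}

.check_outcomes <- function(data) {
  if (!"myopic" %in% names(data) || anyNA(data$myopic)) {
    rlang::abort("every record needs a resolved `myopic` outcome label.")
  }
  invisible(data$myopic)
}

#' Confusion counts at a fixed cut-off
#'
#' Cross-tabulates positive/negative calls of a predictor against the
#' myopia outcome. The counts partition the cohort: `tp + fn` myopes,
#' `tn + fp` non-myopes.
#'
#' @param data Scored cohort (from [premo_score()] with a `myopic`
#'   column, or any tibble carrying the predictor's column and `myopic`).
#' @param spec A [predictor_spec()].
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(data, spec) {
  stopifnot(inherits(spec, "premo_predictor"))
  if (nrow(data) == 0) rlang::abort("empty cohort.")
  y <- .check_outcomes(data)
  x <- .feature_values(data, spec$feature)
  call_pos <- if (spec$direction == "ge") x >= spec$cutoff else x < spec$cutoff
  tibble::tibble(
    tp = sum(call_pos & y), fp = sum(call_pos & !y),
    tn = sum(!call_pos & !y), fn = sum(!call_pos & y)
  )
}

#' Diagnostic metrics from confusion counts
#'
#' @param counts One-row tibble or named list with `tp`, `fp`, `tn`, `fn`.
#' @return One-row tibble: `sensitivity` = tp/(tp+fn), `specificity` =
#'   tn/(tn+fp), `fpr` = fp/(tn+fp) = 1 - specificity, `youden_j` =
#'   sensitivity + specificity - 1. Values are unrounded; rounding to two
#'   decimals happens only when reports are rendered.
#' @export
#' @examples
#' confusion_metrics(list(tp = 32, fp = 1, tn = 23, fn = 1))
confusion_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  if (tp + fn == 0 || tn + fp == 0) {
    rlang::abort("undefined metric: cohort has no myopes or no non-myopes.")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    fpr = fp / (tn + fp), youden_j = sens + spec - 1
  )
}

# ROC sweep over all distinct feature values plus sentinels, as parallel
# vectors (fast path shared by roc_curve and the bootstrap).
# direction "ge": positive call x >= t; "lt": positive call x < t.
.roc_points <- function(x, y, direction) {
  P <- sum(y); N <- sum(!y)
  if (direction == "ge") {
    o <- order(x, decreasing = TRUE)
    xs <- x[o]; ys <- y[o]
    r <- rle(xs)
    ends <- cumsum(r$lengths)
    thr <- c(Inf, r$values)
    tp <- c(0, cumsum(ys)[ends])
    fp <- c(0, cumsum(!ys)[ends])
  } else {
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    r <- rle(xs)
    ends <- cumsum(r$lengths)
    thr <- c(r$values, Inf)   # x < min(x) calls nobody; x < Inf calls everybody
    tp <- c(0, cumsum(ys)[ends])
    fp <- c(0, cumsum(!ys)[ends])
  }
  sens <- tp / P
  fpr <- fp / N
  list(threshold = thr, tp = tp, fp = fp, sens = sens, fpr = fpr,
       spec = 1 - fpr, P = P, N = N)
}

.auc_trapezoid <- function(pts) {
  sum(diff(pts$fpr) * (utils::head(pts$sens, -1) + utils::tail(pts$sens, -1)) / 2)
}

.auc <- function(x, y, direction = "ge") {
  .auc_trapezoid(.roc_points(x, y, direction))
}

#' ROC curve analysis of a myopia predictor
#'
#' Sweeps every distinct feature value (plus sentinel thresholds yielding
#' the all-negative and all-positive calls, so the curve always runs from
#' (0,0) to (1,1)), computes sensitivity, specificity, false positive
#' rate and Youden's J = sensitivity + specificity - 1 at each threshold,
#' the trapezoidal area under the (FPR, sensitivity) curve, and the
#' Youden-optimal cut-off. J ties are broken toward the more sensitive
#' threshold — the preferred trade-off when screening for a treatable
#' risk — which for `"ge"` predictors is the lowest cut-off.
#'
#' @inheritParams confusion_at_cutoff
#' @param feature `"premo_score"`, `"ser"` or `"al"` (or a
#'   [predictor_spec()] in place of `feature`, whose cut-off is ignored).
#' @param direction Positive-call direction; defaults per feature as in
#'   [predictor_spec()].
#' @return A `premo_roc` object: list with `curve` (tibble of thresholds
#'   and metrics), `auc`, `optimal_cutoff`, `youden_j`, `feature`,
#'   `direction`, `n_myopic`, `n_nonmyopic`. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @export
roc_curve <- function(data, feature = "premo_score", direction = NULL) {
  if (inherits(feature, "premo_predictor")) {
    direction <- direction %||% feature$direction
    feature <- feature$feature
  }
  feature <- match.arg(feature, c("premo_score", "ser", "al"))
  direction <- direction %||% (if (feature == "ser") "lt" else "ge")
  y <- .check_outcomes(data)
  x <- .feature_values(data, feature)
  if (sum(y) == 0 || sum(!y) == 0) {
    rlang::abort("single-class cohort: ROC analysis needs at least one myope and one non-myope.")
  }
  pts <- .roc_points(x, y, direction)
  j <- pts$sens + pts$spec - 1
  best_j <- max(j)
  # J values are ratios of small integer counts; compare with a tolerance
  # so float noise cannot pick between mathematically tied thresholds
  tol <- 1e-9
  cand <- which(j >= best_j - tol)
  # most sensitive among the tied maximisers; residual ties -> lowest threshold
  cand <- cand[pts$sens[cand] >= max(pts$sens[cand]) - tol]
  best <- cand[which.min(pts$threshold[cand])]
  curve <- tibble::tibble(
    threshold = pts$threshold,
    tp = pts$tp, fp = pts$fp,
    fn = pts$P - pts$tp, tn = pts$N - pts$fp,
    sensitivity = pts$sens, specificity = pts$spec,
    fpr = pts$fpr, youden_j = j
  )
  structure(list(
    curve = curve,
    auc = .auc_trapezoid(pts),
    optimal_cutoff = pts$threshold[best],
    youden_j = best_j,
    feature = feature, direction = direction,
    n_myopic = pts$P, n_nonmyopic = pts$N
  ), class = "premo_roc")
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap of the trapezoidal AUC with resampling stratified
#' by outcome (myopes and non-myopes are resampled separately, so every
#' resample retains both classes). Deterministic given `seed`. This is
#' the package's own interval and is not guaranteed to match intervals
#' produced by other software's analytic methods.
#'
#' @inheritParams roc_curve
#' @param n_boot Number of bootstrap resamples (default 2000; at least
#'   100).
#' @param seed Integer seed, required.
#' @param conf Confidence level (default 0.95).
#' @param max_retries Redraw cap for degenerate (single-class) resamples;
#'   stratified resampling cannot produce them, the guard is defensive.
#' @return One-row tibble: `auc`, `conf_low`, `conf_high`, `n_boot`.
#' @export
auc_ci <- function(data, feature = "premo_score", direction = NULL,
                   n_boot = 2000, seed, conf = 0.95, max_retries = 10) {
  if (missing(seed)) rlang::abort("`seed` is required for the bootstrap.")
  if (n_boot < 100) rlang::abort("`n_boot` must be at least 100.")
  if (inherits(feature, "premo_predictor")) {
    direction <- direction %||% feature$direction
    feature <- feature$feature
  }
  direction <- direction %||% (if (feature == "ser") "lt" else "ge")
  y <- .check_outcomes(data)
  x <- .feature_values(data, feature)
  pos <- x[y]; neg <- x[!y]
  if (length(pos) == 0 || length(neg) == 0) {
    rlang::abort("single-class cohort: cannot bootstrap the AUC.")
  }
  point <- .auc(x, y, direction)
  yy <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      for (try in seq_len(max_retries)) {
        xp <- sample(pos, replace = TRUE)
        xn <- sample(neg, replace = TRUE)
        if (length(xp) > 0 && length(xn) > 0) {
          return(.auc(c(xp, xn), yy, direction))
        }
      }
      rlang::abort("degenerate bootstrap resamples persisted past the retry cap.")
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(auc = point, conf_low = qs[1], conf_high = qs[2],
                 n_boot = as.integer(n_boot))
}

#' Spearman correlation between PreMO total and outcome SER
#'
#' Rank correlation (average ranks for ties) between the baseline PreMO
#' total and the spherical equivalent refraction measured at age 15 or
#' older. Only records whose outcome SER was actually measured at >= 15
#' years qualify; carried-forward or label-only outcomes are excluded,
#' mirroring their exclusion from rank correlation in validation studies.
#'
#' @param data Scored cohort with `total`, `outcome_ser` and (if present)
#'   `spearman_eligible` / `outcome_basis` columns.
#' @return One-row tibble: `rho`, `n`.
#' @export
spearman_score_ser <- function(data) {
  if (!"total" %in% names(data)) {
    rlang::abort("`data` lacks `total`; score the cohort first.")
  }
  keep <- if ("spearman_eligible" %in% names(data)) {
    data$spearman_eligible
  } else if ("outcome_basis" %in% names(data)) {
    !is.na(data$outcome_basis) & data$outcome_basis == "measured_at_15plus"
  } else {
    !is.na(data$outcome_ser) & !is.na(data$outcome_age_years) &
      data$outcome_age_years >= 15
  }
  d <- data[keep & !is.na(data$outcome_ser), ]
  if (nrow(d) < 3) rlang::abort("need at least 3 records with measured outcome SER at age >= 15.")
  if (length(unique(d$total)) < 2 || length(unique(d$outcome_ser)) < 2) {
    rlang::abort("Spearman correlation undefined for constant input.")
  }
  tibble::tibble(
    rho = stats::cor(d$total, d$outcome_ser, method = "spearman"),
    n = nrow(d)
  )
}

#' Myopia incidence of a cohort
#'
#' @param data Cohort with a resolved `myopic` column.
#' @return One-row tibble: `n`, `n_myopic`, `incidence` (proportion) and
#'   `percent` (rounded to the nearest integer, the form quoted in
#'   reports).
#' @export
incidence <- function(data) {
  if (nrow(data) == 0) rlang::abort("empty cohort.")
  y <- .check_outcomes(data)
  tibble::tibble(
    n = length(y), n_myopic = sum(y),
    incidence = mean(y), percent = round(100 * mean(y))
  )
}

#' Consolidated validation report for a scored cohort
#'
#' Evaluates each predictor on the cohort: AUC with stratified bootstrap
#' CI, sensitivity / specificity / FPR at the predictor's cut-off (with
#' the underlying count fractions), the Youden-optimal cut-off, the
#' Spearman correlation between the predictor and outcome SER (where
#' measured outcome SER is available), and cohort incidence. All values
#' are unrounded; use [format_validation_report()] for two-decimal
#' rendering.
#'
#' @param data Scored cohort with outcome labels.
#' @param predictors List of [predictor_spec()]s; default: PreMO total
#'   >= 4, SER < +0.75 D, AL >= 23.07 mm. An empty list yields a
#'   header-only (zero-row) report.
#' @param n_boot,seed,conf Passed to [auc_ci()]; `seed` required unless
#'   `n_boot = 0`, which skips the CI.
#' @return Tibble, one row per predictor.
#' @export
validation_report <- function(data,
                              predictors = list(
                                predictor_spec("premo_score", 4),
                                predictor_spec("ser", 0.75),
                                predictor_spec("al", 23.07)
                              ),
                              n_boot = 2000, seed = NULL, conf = 0.95) {
  empty <- tibble::tibble(
    feature = character(), cutoff = double(), direction = character(),
    auc = double(), auc_conf_low = double(), auc_conf_high = double(),
    sensitivity = double(), sensitivity_frac = character(),
    specificity = double(), specificity_frac = character(),
    fpr = double(), fpr_frac = character(),
    optimal_cutoff = double(), youden_j = double(),
    spearman_rho = double(), spearman_n = integer(),
    incidence = double(), n = integer()
  )
  if (length(predictors) == 0) return(empty)
  inc <- incidence(data)
  rows <- purrr::map(predictors, function(spec) {
    stopifnot(inherits(spec, "premo_predictor"))
    counts <- confusion_at_cutoff(data, spec)
    met <- confusion_metrics(counts)
    roc <- roc_curve(data, spec$feature, spec$direction)
    ci <- if (n_boot > 0) {
      if (is.null(seed)) rlang::abort("`seed` is required when n_boot > 0.")
      auc_ci(data, spec$feature, spec$direction, n_boot = n_boot,
             seed = seed, conf = conf)
    } else {
      tibble::tibble(conf_low = NA_real_, conf_high = NA_real_)
    }
    rho <- tryCatch({
      x <- .feature_values(data, spec$feature)
      d2 <- dplyr::mutate(data, total = x)  # reuse the score-vs-SER machinery
      spearman_score_ser(d2)
    }, error = function(e) tibble::tibble(rho = NA_real_, n = NA_integer_))
    tibble::tibble(
      feature = spec$feature, cutoff = spec$cutoff, direction = spec$direction,
      auc = roc$auc, auc_conf_low = ci$conf_low, auc_conf_high = ci$conf_high,
      sensitivity = met$sensitivity,
      sensitivity_frac = sprintf("%d/%d", counts$tp, counts$tp + counts$fn),
      specificity = met$specificity,
      specificity_frac = sprintf("%d/%d", counts$tn, counts$tn + counts$fp),
      fpr = met$fpr,
      fpr_frac = sprintf("%d/%d", counts$fp, counts$tn + counts$fp),
      optimal_cutoff = roc$optimal_cutoff, youden_j = roc$youden_j,
      spearman_rho = rho$rho, spearman_n = rho$n,
      incidence = inc$incidence, n = inc$n
    )
  })
  dplyr::bind_rows(rows)
}

#' Render a validation report at two-decimal precision
#'
#' @param report Output of [validation_report()].
#' @return Tibble with proportions rounded to two decimals and the AUC CI
#'   collapsed into a single string, matching the layout of published
#'   performance tables; the unrounded report remains the source of
#'   truth.
#' @export
format_validation_report <- function(report) {
  fmt2 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.2f", x))
  tibble::tibble(
    predictor = sprintf(
      "%s %s %s", report$feature,
      ifelse(report$direction == "ge", ">=", "<"), report$cutoff
    ),
    auc_ci = ifelse(
      is.na(report$auc_conf_low), sprintf("%.3f", report$auc),
      sprintf("%.3f (%.3f-%.3f)", report$auc, report$auc_conf_low,
              report$auc_conf_high)
    ),
    sensitivity = sprintf("%s (n = %s)", fmt2(report$sensitivity),
                          report$sensitivity_frac),
    specificity = sprintf("%s (n = %s)", fmt2(report$specificity),
                          report$specificity_frac),
    fpr = sprintf("%s (n = %s)", fmt2(report$fpr), report$fpr_frac),
    optimal_cutoff = report$optimal_cutoff,
    spearman_rho = fmt2(report$spearman_rho),
    incidence_percent = round(100 * report$incidence)
  )
}
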