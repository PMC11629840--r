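test_that("confusion counts partition the cohort and respect call direction", {
  # perfect separation
  d <- tibble::tibble(total = c(9, 9, 0, 0), myopic = c(TRUE, TRUE, FALSE, FALSE))
  counts <- confusion_at_cutoff(d, predictor_spec("premo_score", 4))
  expect_equal(unlist(counts), c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))

  # direct enumeration: myope scores {4, 3}, non-myope {5}, cut-off >= 4
  d2 <- tibble::tibble(total = c(4, 3, 5), myopic = c(TRUE, TRUE, FALSE))
  counts2 <- confusion_at_cutoff(d2, predictor_spec("premo_score", 4))
  expect_equal(unlist(counts2), c(tp = 1L, fp = 1L, tn = 0L, fn = 1L))

  # SER calls positive below the cut-off
  d3 <- tibble::tibble(ser_used = c(0.25, 1.25), myopic = c(TRUE, FALSE))
  counts3 <- confusion_at_cutoff(d3, predictor_spec("ser", 0.75))
  expect_equal(unlist(counts3), c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))

  expect_error(confusion_at_cutoff(d2[0, ], predictor_spec("premo_score", 4)),
               "empty")
})

test_that("metrics reproduce the published fraction cells", {
  uk <- confusion_metrics(list(tp = 32, fp = 1, tn = 23, fn = 1))
  expect_equal(round(uk$sensitivity, 2), 0.97)
  expect_equal(round(uk$specificity, 2), 0.96)
  expect_equal(round(uk$fpr, 2), 0.04)
  expect_equal(uk$youden_j, uk$sensitivity + uk$specificity - 1)

  hk <- confusion_metrics(list(tp = 206, fp = 5, tn = 9, fn = 14))
  expect_equal(round(hk$sensitivity, 2), 0.94)
  expect_equal(round(hk$specificity, 2), 0.64)
  expect_equal(round(hk$fpr, 2), 0.36)

  perfect <- confusion_metrics(list(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_equal(perfect$youden_j, 1)

  expect_error(confusion_metrics(list(tp = 0, fp = 1, tn = 1, fn = 0)),
               "undefined")
})

test_that("ROC handles separation, chance and tied scores", {
  sep <- roc_curve(tibble::tibble(total = c(7, 8, 1, 2),
                                  myopic = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(sep$auc, 1.0)

  flat <- roc_curve(tibble::tibble(total = c(5, 5, 5, 5),
                                   myopic = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(flat$auc, 0.5)

  # Mann-Whitney enumeration with a tie: myopes {3, 5}, non-myopes {2, 5}
  tied <- roc_curve(tibble::tibble(total = c(3, 5, 2, 5),
                                   myopic = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(tied$auc, 0.625)

  expect_error(roc_curve(tibble::tibble(total = 1:3, myopic = rep(TRUE, 3))),
               "single-class")
})

test_that("Youden ties break toward the more sensitive threshold", {
  d <- tibble::tibble(total = c(4, 5, 7, 1, 3, 4),
                      myopic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  r <- roc_curve(d)
  expect_equal(r$optimal_cutoff, 4)  # J ties at 4 and 5; 4 is more sensitive
  expect_equal(r$youden_j, 2 / 3, tolerance = 1e-12)
})

test_that("ROC endpoints, AUC bounds and label-flip symmetry hold", {
  withr::local_seed(421)
  for (i in 1:50) {
    d <- random_scored_cohort(sample(5:40, 1))
    r <- roc_curve(d)
    curve <- r$curve[order(r$curve$fpr, r$curve$sensitivity), ]
    expect_equal(c(curve$fpr[1], curve$sensitivity[1]), c(0, 0))
    expect_equal(c(curve$fpr[nrow(curve)], curve$sensitivity[nrow(curve)]),
                 c(1, 1))
    expect_true(r$auc >= 0 && r$auc <= 1)
    flipped <- roc_curve(dplyr::mutate(d, myopic = !myopic))
    expect_equal(flipped$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney estimate", {
  withr::local_seed(90125)
  for (i in 1:200) {
    d <- random_scored_cohort(sample(4:50, 1))
    r <- roc_curve(d)
    expect_equal(r$auc, oracle_auc_mw(d$total, d$myopic), tolerance = 1e-12)
  }
})

test_that("the optimal cut-off matches exhaustive maximisation", {
  withr::local_seed(777)
  for (i in 1:200) {
    d <- random_scored_cohort(sample(4:50, 1))
    r <- roc_curve(d)
    oracle <- oracle_best_cutoff(d$total, d$myopic)
    expect_equal(r$youden_j, oracle$j, tolerance = 1e-12)
    expect_equal(r$optimal_cutoff, oracle$t)
  }
})

test_that("ROC and AUC agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(2024)
  for (i in 1:20) {
    d <- random_scored_cohort(40)
    ours <- roc_curve(d)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = d$myopic, predictor = d$total, direction = "<", quiet = TRUE
    )))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("bootstrap AUC interval is deterministic, bracketing and degenerate-safe", {
  d <- random_scored_cohort(60)
  ci1 <- auc_ci(d, n_boot = 300, seed = 42)
  ci2 <- auc_ci(d, n_boot = 300, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(ci1$conf_low <= ci1$conf_high)

  sep <- tibble::tibble(total = c(rep(9, 10), rep(0, 10)),
                        myopic = rep(c(TRUE, FALSE), each = 10))
  ci <- auc_ci(sep, n_boot = 200, seed = 1)
  expect_equal(c(ci$conf_low, ci$conf_high), c(1, 1))

  expect_error(auc_ci(d, n_boot = 10, seed = 1), "at least 100")
  expect_error(auc_ci(d, n_boot = 200), "seed")
})

test_that("Spearman matches perfect monotone cases and the rank-Pearson oracle", {
  mk <- function(total, ser) tibble::tibble(
    total = total, outcome_ser = ser, spearman_eligible = TRUE
  )
  expect_equal(spearman_score_ser(mk(1:3, c(1, 0, -1)))$rho, -1)
  expect_equal(spearman_score_ser(mk(1:3, c(-1, 0, 1)))$rho, 1)

  tied <- mk(c(1, 2, 2, 4), c(0.5, 0.0, 0.25, -1.0))
  expect_equal(spearman_score_ser(tied)$rho,
               oracle_spearman(c(1, 2, 2, 4), c(0.5, 0.0, 0.25, -1.0)))

  # tie-free data: closed form 1 - 6 sum(d^2) / (n (n^2 - 1))
  withr::local_seed(5)
  x <- sample(1:20); y <- rnorm(20)
  dd <- rank(x) - rank(y)
  expect_equal(spearman_score_ser(mk(x, y))$rho,
               1 - 6 * sum(dd^2) / (20 * (20^2 - 1)))

  expect_error(spearman_score_ser(mk(rep(2, 5), rnorm(5))), "constant")
})

test_that("Spearman uses only outcomes with measured SER at age 15+", {
  d <- tibble::tibble(
    total = c(1, 2, 3, 9),
    outcome_ser = c(1, 0, -1, -5),
    spearman_eligible = c(TRUE, TRUE, TRUE, FALSE)  # last: carried forward
  )
  res <- spearman_score_ser(d)
  expect_equal(res$n, 3)
  expect_equal(res$rho, -1)
})

test_that("incidence reports the myopic fraction and rounded percentage", {
  d <- tibble::tibble(myopic = c(rep(TRUE, 33), rep(FALSE, 24)))
  inc <- incidence(d)
  expect_equal(inc$n_myopic, 33)
  expect_equal(inc$percent, 58)
  expect_equal(incidence(tibble::tibble(myopic = rep(FALSE, 10)))$percent, 0)
})

test_that("validation_report assembles one row per predictor", {
  fx <- premo_score(premo_fixture(4, "uk_6_8"))
  fx$myopic <- fx$outcome_myopic
  fx$spearman_eligible <- TRUE
  rep <- validation_report(fx, n_boot = 0)
  expect_equal(nrow(rep), 3)
  score_row <- rep[rep$feature == "premo_score", ]
  expect_equal(round(score_row$sensitivity, 2), 0.97)
  expect_equal(score_row$sensitivity_frac, "32/33")
  expect_equal(score_row$optimal_cutoff, 4)
  expect_equal(round(100 * score_row$incidence), 58)

  empty <- validation_report(fx, predictors = list(), n_boot = 0)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("auc", "sensitivity", "specificity") %in% names(empty)))

  fmt <- format_validation_report(rep)
  expect_match(fmt$sensitivity[fmt$predictor == "premo_score >= 4"],
               "0.97 \\(n = 32/33\\)")
})

test_that("SER as a singular predictor on the HK-like fixture loses sensitivity", {
  fx <- premo_score(premo_fixture(5, "hk_6_8_ser"))
  fx$myopic <- fx$outcome_myopic
  met <- confusion_metrics(confusion_at_cutoff(fx, predictor_spec("ser", 0.75)))
  expect_equal(round(met$sensitivity, 2), 0.83)
  expect_equal(round(met$specificity, 2), 0.86)
})
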