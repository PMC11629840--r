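# Independent oracles used against the implementation.

# Mann-Whitney probability estimate of the AUC by full pairwise
# enumeration, ties half-weighted.
oracle_auc_mw <- function(x, y, direction = "ge") {
  pos <- x[y]
  neg <- x[!y]
  wins <- if (direction == "ge") outer(pos, neg, ">") else outer(pos, neg, "<")
  ties <- outer(pos, neg, "==")
  mean(wins + 0.5 * ties)
}

# Brute-force Youden maximiser over every swept threshold, ties broken
# toward the more sensitive threshold, then the lower threshold value.
oracle_best_cutoff <- function(x, y, direction = "ge") {
  thresholds <- c(sort(unique(x)), Inf)
  best <- NULL
  for (t in thresholds) {
    called <- if (direction == "ge") x >= t else x < t
    sens <- sum(called & y) / sum(y)
    spec <- sum(!called & !y) / sum(!y)
    j <- sens + spec - 1
    better <- is.null(best) ||
      j > best$j + 1e-12 ||
      (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12) ||
      (abs(j - best$j) <= 1e-12 && abs(sens - best$sens) <= 1e-12 && t < best$t)
    if (better) best <- list(t = t, j = j, sens = sens)
  }
  best
}

# Spearman via explicit average ranks + Pearson correlation.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Random small scored cohort with both outcome classes present.
random_scored_cohort <- function(n, score_values = 0:9) {
  repeat {
    d <- tibble::tibble(
      total = sample(score_values, n, replace = TRUE),
      myopic = sample(c(TRUE, FALSE), n, replace = TRUE)
    )
    if (any(d$myopic) && any(!d$myopic)) return(d)
  }
}

# Minimal well-formed cohort rows for I/O tests.
toy_cohort <- function() {
  tibble::tibble(
    child_id = c("a", "b", "c"),
    age_years = c(7, 8.5, 9.7),
    ser_right = c(1.25, 0.50, 0.25),
    ser_left = c(0.75, 0.50, 0.50),
    ser_mean = NA_real_,
    al_right = c(22.8, 23.15, 23.50),
    al_left = c(23.1, 23.10, 23.40),
    al_mean = NA_real_,
    n_myopic_parents = c(0, 1, 2),
    outcome_age_years = c(16, 17, 15),
    outcome_ser = c(0.25, -1.50, -0.50),
    outcome_myopic = NA
  )
}
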