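test_that("eye selection follows the least-hyperopic rule with right-eye tie-break", {
  obs <- tibble::tibble(
    ser_right = c(1.25, 1.00), ser_left = c(0.75, 1.00),
    al_right = c(22.80, 23.00), al_left = c(23.10, 23.20)
  )
  sel <- select_eye_measurements(obs)
  expect_equal(sel$eye_used, c("left", "right"))
  expect_equal(sel$ser_used, c(0.75, 1.00))
  expect_equal(sel$al_used, c(23.10, 23.00))  # AL travels with the selected eye

  m <- select_eye_measurements(
    tibble::tibble(ser_mean = 0.75, al_mean = 23.00), eye_policy = "mean"
  )
  expect_equal(m$eye_used, "mean")
  expect_equal(m$ser_used, 0.75)
  expect_equal(m$al_used, 23.00)
})

test_that("eye selection errors name the missing field", {
  expect_error(
    select_eye_measurements(tibble::tibble(
      ser_right = 1, ser_left = NA_real_, al_right = 23, al_left = 23
    )),
    "ser_left"
  )
  expect_error(
    select_eye_measurements(tibble::tibble(ser_mean = 1), eye_policy = "mean"),
    "al_mean"
  )
})

test_that("point tables reproduce the published cells and boundary conventions", {
  # parental myopia
  expect_equal(score_parental(0:2, "age_6_8"), c(0L, 2L, 3L))
  expect_equal(score_parental(0:2, "age_9_10"), c(0L, 1L, 2L))
  expect_error(score_parental(3, "age_6_8"), "0, 1 or 2")

  # SER: middle band closed at both ends
  expect_equal(score_ser(c(1.25, 1.00, 0.75, 0.50), "age_6_8"), c(0L, 2L, 2L, 3L))
  expect_equal(score_ser(c(1.00, 0.875, 0.50, 0.375, 0.25), "age_9_10"),
               c(0L, 1L, 1L, 1L, 2L))

  # AL: half-open bands anchored at the lower printed bound
  expect_equal(score_al(c(22.50, 22.94, 23.00, 23.115, 23.12, 23.18, 23.19),
                        "age_6_8"),
               c(0L, 1L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(score_al(c(23.00, 23.33, 23.50, 23.615, 23.62), "age_9_10"),
               c(0L, 1L, 1L, 1L, 2L))
})

test_that("premo_score routes ages, sums components and assigns categories", {
  sc <- premo_score(tibble::tibble(
    child_id = c("hi", "zero", "bandB"),
    age_years = c(7, 7, 9.7),
    ser_mean = c(0.50, 2.00, 0.50),
    al_mean = c(23.20, 22.50, 23.50),
    n_myopic_parents = c(2, 0, 1)
  ), eye_policy = "mean")
  expect_equal(sc$band, c("age_6_8", "age_6_8", "age_9_10"))
  expect_equal(sc$parental_points, c(3L, 0L, 1L))
  expect_equal(sc$ser_points, c(3L, 0L, 1L))
  expect_equal(sc$al_points, c(3L, 0L, 1L))
  expect_equal(sc$total, c(9L, 0L, 3L))
  expect_equal(as.character(sc$category), c("high", "little_no_risk", "low"))
})

test_that("premo_score rejects already-myopic baselines and unroutable ages", {
  expect_error(
    premo_score(tibble::tibble(
      age_years = 7, ser_mean = -0.75, al_mean = 23, n_myopic_parents = 0
    ), eye_policy = "mean"),
    "already myopic"
  )
  expect_error(
    premo_score(tibble::tibble(
      age_years = 12, ser_mean = 1, al_mean = 23, n_myopic_parents = 0
    ), eye_policy = "mean"),
    "outside the supported bands"
  )
})

test_that("missing parental data errors unless the assume-zero override is set", {
  obs <- tibble::tibble(
    age_years = 7, ser_mean = 1.5, al_mean = 22.5, n_myopic_parents = NA_real_
  )
  expect_error(premo_score(obs, eye_policy = "mean"), "n_myopic_parents")
  expect_message(
    sc <- premo_score(obs, eye_policy = "mean", assume_no_parental_myopia = TRUE),
    "Assuming 0 myopic parents"
  )
  expect_equal(sc$parental_points, 0L)
})

test_that("risk categories follow the fixed bins and round-trip their bounds", {
  cats <- assign_risk_category(c(0, 2, 5, 9))
  expect_equal(as.character(cats$label),
               c("little_no_risk", "low", "moderate", "high"))
  expect_match(cats$predicted_outcome[3], "13 years")

  bins <- premo_risk_categories()
  for (i in seq_len(nrow(bins))) {
    for (t in bins$total_min[i]:bins$total_max[i]) {
      expect_equal(as.character(assign_risk_category(t)$label),
                   as.character(bins$label[i]))
    }
  }
  expect_error(assign_risk_category(10), "0, 9")
})

test_that("points are monotone in each risk factor", {
  for (band in c("age_6_8", "age_9_10")) {
    expect_true(all(diff(score_parental(0:2, band)) >= 0))
    ser_grid <- seq(-0.45, 3, by = 0.005)
    expect_true(all(diff(score_ser(ser_grid, band)) <= 0))  # lower SER, more points
    al_grid <- seq(20, 26, by = 0.005)
    expect_true(all(diff(score_al(al_grid, band)) >= 0))
  }
})

test_that("every SER and AL value maps to exactly one valid point value", {
  # independent re-statement of the printed intervals via cut()
  ser_oracle <- list(
    age_6_8 = function(s) c(3L, 2L, 0L)[cut(s, c(-Inf, 0.75, 1.00, Inf),
                                            right = TRUE, labels = FALSE)],
    age_9_10 = function(s) c(2L, 1L, 0L)[cut(s, c(-Inf, 0.375, 0.875, Inf),
                                             right = TRUE, labels = FALSE)]
  )
  # cut(right=TRUE) puts the lower middle-band endpoint in the lower bin;
  # the middle band is closed at both ends, so patch the boundary up
  ser_fix <- list(age_6_8 = c(0.75, 2L), age_9_10 = c(0.375, 1L))
  al_oracle <- list(
    age_6_8 = function(a) c(0L, 1L, 2L, 3L)[cut(a, c(-Inf, 22.94, 23.12, 23.19, Inf),
                                                right = FALSE, labels = FALSE)],
    age_9_10 = function(a) c(0L, 1L, 2L)[cut(a, c(-Inf, 23.33, 23.62, Inf),
                                             right = FALSE, labels = FALSE)]
  )
  for (band in c("age_6_8", "age_9_10")) {
    s <- seq(-0.45, 3, by = 0.0025)
    expected <- ser_oracle[[band]](s)
    expected[s == ser_fix[[band]][1]] <- as.integer(ser_fix[[band]][2])
    got <- score_ser(s, band)
    expect_false(anyNA(got))
    expect_equal(got, expected)

    a <- seq(20, 26, by = 0.0025)
    got_al <- score_al(a, band)
    expect_false(anyNA(got_al))
    expect_equal(got_al, al_oracle[[band]](a))
  }
})

test_that("brute force over all factor combinations respects the band maxima", {
  vals <- premo_fixture_values()
  for (band in c("age_6_8", "age_9_10")) {
    v <- vals[[band]]
    combos <- expand.grid(p = unname(v$parents), s = unname(v$ser),
                          a = unname(v$al))
    totals <- score_parental(combos$p, band) + score_ser(combos$s, band) +
      score_al(combos$a, band)
    max_total <- if (band == "age_6_8") 9L else 6L
    expect_equal(max(totals), max_total)
    expect_equal(min(totals), 0L)
    expect_true(all(totals >= 0 & totals <= max_total))
  }
})
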