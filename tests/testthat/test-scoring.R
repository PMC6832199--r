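test_that("select_markers filters by alpha and tags median direction", {
  # hand-built cohort: marker A up in deaths, C down, B null
  set.seed(2)
  n <- 60
  death <- rep(c(TRUE, FALSE), c(20, 40))
  co <- simulate_cohort(default_study_config(seed = 2))[1:n, ]
  co$icu_death <- death
  co$overall_event <- death | co$overall_event
  co[["miR-122"]] <- exp(rnorm(n) + 2 * death)        # up in non-survivors
  co[["miR-150"]] <- exp(rnorm(n) - 2 * death)        # down in non-survivors
  co[["miR-155"]] <- exp(rnorm(n))                    # null

  sel <- select_markers(co, "icu_death", alpha = 0.05)
  expect_true(all(c("miR-122", "miR-150") %in% sel$marker))
  expect_identical(sel$direction[sel$marker == "miR-122"], "high_scores")
  expect_identical(sel$direction[sel$marker == "miR-150"], "low_scores")
  expect_false("miR-155" %in% sel$marker)

  # alpha = 0 selects nothing
  expect_identical(nrow(select_markers(co, "icu_death", alpha = 0)), 0L)

  co$icu_death <- rep(FALSE, n)
  expect_error(select_markers(co, "icu_death"),
               class = "mirscore_degenerate_error")
})

test_that("build_score derives Youden cut-offs and the age item", {
  co <- test_cohort(seed = 4)
  sel <- data.frame(marker = "miR-133a", direction = "high_scores")
  def <- build_score(co, sel, "icu_death", include_age = FALSE)
  expect_identical(nrow(def$items), 1L)
  # one-item score has range {0, 1}
  expect_setequal(sort(unique(score_cohort(def, co))), c(0L, 1L))
  # the stored cut-off reproduces the stand-alone Youden computation
  cp <- youden_cutpoint(co[["miR-133a"]], co$icu_death, "high_is_positive")
  expect_equal(def$items$cutoff, cp$cutoff)

  def_age <- build_score(co, sel, "icu_death", include_age = TRUE)
  expect_identical(nrow(def_age$items), 2L)
  expect_identical(def_age$items$marker[2], "AGE")
  expect_identical(def_age$items$direction[2], "high_scores")

  expect_error(build_score(co, sel[0, ], "icu_death"),
               class = "mirscore_input_error")
})

test_that("age cut-off is recovered within adjacent-age spacing under a
           known separation", {
  for (s in 1:10) {
    cfg <- default_study_config(seed = 40 + s)
    cfg$age_mean_survivor <- 50
    cfg$age_mean_nonsurvivor <- 80
    cfg$age_sd <- 4
    co <- simulate_cohort(cfg)
    cp <- youden_cutpoint(co$age, co$overall_event, "high_is_positive",
                          marker = "AGE")
    lo <- max(co$age[!co$overall_event][co$age[!co$overall_event] <
                                          cp$cutoff])
    hi <- min(co$age[co$overall_event][co$age[co$overall_event] >
                                         cp$cutoff])
    # generative threshold (midpoint 65) falls in the same adjacent-age gap
    expect_lt(lo, cp$cutoff)
    expect_gt(hi, cp$cutoff)
    expect_gt(cp$youden_j, 0.9)
    expect_lt(abs(cp$cutoff - 65), 10)
  }
})

test_that("apply_score applies strict inequalities per item", {
  def <- reference_overall_definition(include_age = TRUE)
  # published rules: miR-133a > 4.3, miR-150 < 22.7, age > 68.5
  expect_identical(
    apply_score(def, list(`miR-133a` = 5.0, `miR-150` = 10.0, age = 70)),
    3L)
  # values exactly at the cut-offs never score
  expect_identical(
    apply_score(def, list(`miR-133a` = 4.3, `miR-150` = 22.7, age = 68.5)),
    0L)
  # without the age item the same record scores 2
  expect_identical(
    apply_score(reference_overall_definition(include_age = FALSE),
                list(`miR-133a` = 6.0, `miR-150` = 15.0)),
    2L)
  expect_error(apply_score(def, list(`miR-133a` = 5.0, age = 70)),
               class = "mirscore_input_error")
})

test_that("the reference ICU definition scores a fully adverse patient 4", {
  cuts <- c(`miR-133a` = 2.1, `miR-143` = 8, `miR-223` = 30)
  def <- reference_icu_definition(cuts, include_age = TRUE)
  expect_identical(nrow(def$items), 4L)
  rec <- list(`miR-133a` = 3, `miR-143` = 5, `miR-223` = 10, age = 80)
  expect_identical(apply_score(def, rec), 4L)
  # age at/below 72.5 drops exactly the age point
  rec$age <- 72.5
  expect_identical(apply_score(def, rec), 3L)
})

test_that("apply_score is monotone in high_scores markers", {
  co <- test_cohort(seed = 6)
  sel <- select_markers(co, "icu_death")
  def <- build_score(co, sel, "icu_death", include_age = TRUE)
  set.seed(60)
  for (i in 1:25) {
    rec <- as.list(co[sample(nrow(co), 1), ])
    base <- apply_score(def, rec)
    up <- def$items$marker[def$items$direction == "high_scores"]
    m <- sample(up, 1)
    rec[[if (m == "AGE") "age" else m]] <-
      rec[[if (m == "AGE") "age" else m]] + abs(rnorm(1, 2))
    expect_gte(apply_score(def, rec), base)
  }
})

test_that("score + age definition spans [0, items + 1] on extreme records", {
  co <- test_cohort(seed = 8)
  sel <- select_markers(co, "icu_death")
  def <- build_score(co, sel, "icu_death", include_age = TRUE)
  m <- nrow(def$items)
  worst <- list(age = 100)
  best <- list(age = 1)
  for (i in seq_len(m)) {
    mk <- def$items$marker[i]
    if (mk == "AGE") next
    adverse <- def$items$direction[i] == "high_scores"
    worst[[mk]] <- def$items$cutoff[i] * if (adverse) 2 else 0.5
    best[[mk]] <- def$items$cutoff[i] * if (adverse) 0.5 else 2
  }
  expect_identical(apply_score(def, worst), m)
  expect_identical(apply_score(def, best), 0L)
})

test_that("stratum_mortality counts, rounds half-up, and conserves totals", {
  tab <- stratum_mortality(c(0, 0, 1, 3, 3, 3),
                           c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
                           list(0, c(1, 2), 3))
  expect_identical(tab$n, c(2L, 1L, 3L))
  expect_identical(tab$deaths, c(0L, 0L, 2L))
  expect_equal(tab$mortality_percent[3], 66.7)

  # all alive
  tab0 <- stratum_mortality(c(0, 1, 2), rep(FALSE, 3), list(0, 1, 2))
  expect_true(all(tab0$mortality_percent == 0))

  # conservation on random inputs
  set.seed(77)
  for (i in 1:20) {
    sc <- sample(0:4, 30, replace = TRUE)
    dd <- runif(30) < 0.4
    tab <- stratum_mortality(sc, dd, list(0, 1:3, 4))
    expect_identical(sum(tab$n), 30L)
    expect_identical(sum(tab$deaths), sum(dd))
  }

  # half-up rounding convention (22.5% of 40 deaths -> 22.5; 1/204 etc.)
  expect_equal(stratum_mortality(rep(0, 204),
                                 rep(c(TRUE, FALSE), c(45, 159)),
                                 list(0))$mortality_percent, 22.1)

  expect_error(stratum_mortality(c(0, 5), c(TRUE, FALSE), list(0, 1)),
               class = "mirscore_input_error")
  expect_error(stratum_mortality(c(0, 1), c(TRUE, FALSE), list(0, 0:1)),
               class = "mirscore_input_error")
})

test_that("score definitions round-trip through JSON", {
  def <- reference_overall_definition(TRUE)
  back <- score_from_json(json = score_to_json(def))
  expect_equal(back$items, def$items)
  expect_identical(back$includes_age, def$includes_age)
  rec <- list(`miR-133a` = 9, `miR-150` = 1, age = 90)
  expect_identical(apply_score(back, rec), apply_score(def, rec))
})
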