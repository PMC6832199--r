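test_that("mann_whitney_u matches hand-computed and enumerated cases", {
  # identical groups: U at its null centre, no direction
  mw <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw$statistic_u, 4.5)
  expect_equal(mw$direction, "none")
  expect_equal(mw$p_value, 1)

  # complete separation at n = 2 vs 2: exact enumeration gives p = 2/6
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$statistic_u, 0)
  expect_equal(mw$p_value, 2 / 6)
  expect_equal(mw$method, "exact")

  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "mirscore_input_error")
})

test_that("mann_whitney_u properties hold on random instances", {
  set.seed(42)
  for (i in 1:60) {
    n1 <- sample(2:9, 1)
    n2 <- sample(2:9, 1)
    a <- sample(seq(0, 8, by = 0.5), n1, replace = i %% 2 == 0)
    b <- sample(seq(0, 8, by = 0.5), n2, replace = i %% 2 == 0)
    ua <- mann_whitney_u(a, b)
    ub <- mann_whitney_u(b, a)
    # rank-sum identity and bounds
    expect_equal(ua$statistic_u + ub$statistic_u, n1 * n2)
    expect_gte(ua$statistic_u, 0)
    expect_lte(ua$statistic_u, n1 * n2)
    expect_equal(ua$p_value, ub$p_value)
    if (ua$method == "exact") {
      expect_equal(ua$p_value, oracle_mw_exact_p(a, b))
    }
    # independent reference implementation
    ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
    expect_equal(ua$statistic_u, unname(ref$statistic))
    if (ua$method == "normal_approximation") {
      expect_equal(ua$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("spearman_rho matches midrank oracle and handles monotone cases", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_rho(1:4, c(40, 30, 20, 10))$rho, -1)

  # tied case against an independent midrank + Pearson computation
  x <- c(1, 2, 2, 4)
  y <- c(3, 1, 4, 4)
  expect_equal(spearman_rho(x, y)$rho,
               stats::cor(oracle_midrank(x), oracle_midrank(y)))

  set.seed(7)
  for (i in 1:30) {
    x <- sample(1:6, 10, replace = TRUE)
    y <- sample(1:6, 10, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    s <- spearman_rho(x, y)
    expect_equal(s$rho, stats::cor(x, y, method = "spearman"))
    expect_equal(s$rho, stats::cor(oracle_midrank(x), oracle_midrank(y)))
    expect_gte(s$p_value, 0)
    expect_lte(s$p_value, 1)
  }
  expect_error(spearman_rho(1:3, 1:4), class = "mirscore_input_error")
  expect_error(spearman_rho(1:2, 1:2), class = "mirscore_input_error")
  expect_error(spearman_rho(c(1, 1, 1), 1:3),
               class = "mirscore_degenerate_error")
})

test_that("roc_curve AUC equals the pair-counting AUC (both directions)", {
  # perfect separation / identical multisets
  expect_equal(roc_curve(c(5, 6, 7, 1, 2, 3),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_curve(c(1, 2, 3, 1, 2, 3),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 0.5)

  set.seed(11)
  for (i in 1:100) {
    inst <- random_roc_instance(sample(2:8, 1), sample(2:8, 1),
                                tied = i %% 2 == 0)
    for (dir in c("high_is_positive", "low_is_positive")) {
      rc <- roc_curve(inst$values, inst$labels, dir)
      expect_equal(rc$auc,
                   oracle_auc_paircount(inst$values, inst$labels, dir),
                   tolerance = 1e-12)
      expect_true(all(rc$sensitivity >= 0 & rc$sensitivity <= 1))
      expect_true(all(rc$specificity >= 0 & rc$specificity <= 1))
      expect_equal(length(rc$thresholds), length(rc$sensitivity))
    }
  }
  expect_error(roc_curve(1:4, rep(TRUE, 4)),
               class = "mirscore_degenerate_error")
})

test_that("youden_cutpoint reproduces enumerated optima and tie-breaks", {
  # perfect separation: midpoint cut-off, J = 1
  cp <- youden_cutpoint(c(5, 6, 7, 1, 2, 3), c(T, T, T, F, F, F))
  expect_equal(cp$cutoff, 4)
  expect_equal(cp$youden_j, 1)

  # interleaved: J maximal (1/3) at thresholds 1.5 / 3.5 / 5.5; the
  # sensitivity-first tie-break selects 1.5 with sensitivity 1
  cp <- youden_cutpoint(c(2, 4, 6, 1, 3, 5), c(T, T, T, F, F, F))
  expect_equal(cp$cutoff, 1.5)
  expect_equal(cp$youden_j, 1 / 3, tolerance = 1e-12)
  expect_equal(cp$sensitivity, 1)
})

test_that("youden_cutpoint equals brute-force scan on random instances", {
  set.seed(23)
  for (i in 1:100) {
    inst <- random_roc_instance(sample(3:10, 1), sample(3:10, 1),
                                tied = i %% 3 == 0)
    for (dir in c("high_is_positive", "low_is_positive")) {
      cp <- youden_cutpoint(inst$values, inst$labels, dir)
      br <- oracle_youden_scan(inst$values, inst$labels, dir)
      expect_equal(cp$cutoff, br$cutoff)
      expect_equal(cp$youden_j, br$j, tolerance = 1e-12)
      # J at the reported cut-off recomputed from scratch
      hit <- if (dir == "high_is_positive") inst$values > cp$cutoff
             else inst$values < cp$cutoff
      sens <- sum(hit & inst$labels) / sum(inst$labels)
      spec <- sum(!hit & !inst$labels) / sum(!inst$labels)
      expect_equal(cp$youden_j, sens + spec - 1, tolerance = 1e-12)
      expect_equal(cp$sensitivity, sens)
      expect_equal(cp$specificity, spec)
    }
  }
})

test_that("direction symmetry: low_is_positive on v == high on -v negated", {
  set.seed(31)
  for (i in 1:40) {
    inst <- random_roc_instance(sample(3:8, 1), sample(3:8, 1),
                                tied = i %% 2 == 0)
    lo <- youden_cutpoint(inst$values, inst$labels, "low_is_positive")
    hi <- youden_cutpoint(-inst$values, inst$labels, "high_is_positive")
    expect_equal(lo$cutoff, -hi$cutoff)
    expect_equal(lo$youden_j, hi$youden_j)
    expect_equal(lo$sensitivity, hi$sensitivity)
    expect_equal(lo$auc, hi$auc)
  }
})
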