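test_that("the concordance index handles ties, perfect order and censoring", {
  time <- c(3, 2, 1, 5)
  event <- c(TRUE, TRUE, TRUE, TRUE)
  expect_equal(harrell_c(rep(1, 4), time, event), 0.5)
  # protective orientation: earlier failure has the lower score
  expect_equal(harrell_c(c(3, 2, 1, 5), time, event), 1.0)
  # 3 uncensored patients, exactly 2 of 3 pairs concordant
  expect_equal(harrell_c(c(2, 3, 1), c(3, 2, 1), rep(TRUE, 3)), 2 / 3)
  expect_error(harrell_c(1, 5, FALSE), "comparable")
})

test_that("the concordance index equals pair enumeration on random instances", {
  withr::local_seed(101)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    inst <- random_surv_instance(n)
    # discretize some scores to force ties
    s <- round(inst$score, sample(0:2, 1))
    expect_identical(harrell_c(s, inst$time, inst$event),
                     oracle_harrell_c(s, inst$time, inst$event))
  }
})

test_that("the bootstrap CI is seed-stable, degenerate for constant risks, and convergent", {
  withr::local_seed(7)
  inst <- random_surv_instance(60)
  ci1 <- bootstrap_ci(inst$score, inst$time, inst$event, seed = 5)
  ci2 <- bootstrap_ci(inst$score, inst$time, inst$event, seed = 5)
  expect_identical(ci1[], ci2[])
  expect_true(ci1[["lo"]] <= ci1[["hi"]])

  const <- bootstrap_ci(rep(1, 60), inst$time, inst$event, seed = 5)
  expect_equal(as.numeric(const), c(0.5, 0.5), ignore_attr = TRUE)

  # a large-replicate CI brackets the small-replicate centre
  big <- bootstrap_ci(inst$score, inst$time, inst$event, n_reps = 2000, seed = 6)
  centre <- mean(c(ci1[["lo"]], ci1[["hi"]]))
  expect_gt(centre, big[["lo"]])
  expect_lt(centre, big[["hi"]])

  # the jackknife mode agrees with the bootstrap to first order
  jk <- bootstrap_ci(inst$score, inst$time, inst$event, method = "jackknife")
  expect_lt(abs(mean(c(jk[["lo"]], jk[["hi"]])) - centre), 0.05)
  expect_true(jk[["lo"]] <= jk[["hi"]])
})

test_that("the permutation p-value is exact at the extremes", {
  withr::local_seed(11)
  inst <- random_surv_instance(30)
  # constant risks: every permuted c equals the observed 0.5
  expect_equal(permutation_test(rep(0, 30), inst$time, inst$event,
                                n_perm = 200, seed = 1), 1)
  # perfectly ordered risks on distinct uncensored times
  time <- 1:10
  event <- rep(TRUE, 10)
  p <- permutation_test(1:10, time, event, n_perm = 999, seed = 2)
  expect_lte(p, 0.01)
  expect_gt(p, 0)
})

test_that("the Kaplan-Meier estimator matches a hand product-limit computation", {
  cv <- km_curve(10, TRUE)
  expect_equal(cv$surv, c(1, 0))
  expect_equal(cv$time, c(0, 10))

  # events at 1, 2, 3 and a censored record at 2.5:
  # S(1) = 3/4, S(2) = 3/4 * 2/3 = 1/2, S(3) = 1/2 * 0 = 0 (1 at risk)
  cv2 <- km_curve(c(1, 2, 2.5, 3), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(cv2$surv[cv2$time == 0], 1)
  expect_equal(cv2$surv[cv2$time == 1], 3 / 4)
  expect_equal(cv2$surv[cv2$time == 2], 1 / 2)
  expect_equal(cv2$surv[cv2$time == 3], 0)
  expect_true(all(diff(cv2$surv) <= 0))
})

test_that("fraction surviving interpolates linearly between step corners", {
  cv <- km_curve(c(10, 20), c(TRUE, TRUE))
  # corners: (0, 1), (10, 0.5), (20, 0)
  expect_equal(survival_at(cv, 5), 0.75)
  expect_equal(survival_at(cv, 10), 0.5)
  expect_equal(survival_at(cv, 15), 0.25)
  expect_equal(survival_at(cv, 99), 0)
  expect_error(survival_at(cv, -1), "non-negative")
})

test_that("the log-rank test matches the hypergeometric oracle", {
  # hand-checkable instance: two groups of two, distinct uncensored times
  time <- c(1, 3, 2, 4)
  event <- rep(TRUE, 4)
  group <- c("a", "a", "b", "b")
  res <- logrank_test(time, event, group)
  expect_equal(res$statistic, oracle_logrank2(time, event, group),
               tolerance = 1e-10)
  expect_equal(res$df, 1)

  # identical outcome multisets: statistic ~ 0, p ~ 1
  sym <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6), rep(c("a", "b"), 3))
  expect_lt(sym$statistic, 1e-10)
  expect_gt(sym$p, 0.999)

  withr::local_seed(55)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    inst <- random_surv_instance(n)
    grp <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || sum(inst$event) == 0) next
    expect_equal(logrank_test(inst$time, inst$event, grp)$statistic,
                 oracle_logrank2(inst$time, inst$event, grp),
                 tolerance = 1e-10)
  }

  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c("a", "b")), "events")
  expect_error(logrank_test(c(1, 2), c(TRUE, TRUE), c("a", "a")), "two nonempty")
})

test_that("three-group log-rank reduces to k - 1 degrees of freedom", {
  withr::local_seed(56)
  inst <- random_surv_instance(45)
  grp <- rep(c("a", "b", "c"), each = 15)
  res <- logrank_test(inst$time, inst$event, grp)
  expect_equal(res$df, 2)
  expect_gt(res$p, 0)
})

test_that("the threshold search recovers a median split and respects the grid", {
  hits <- 0
  for (seed in 1:10) {
    withr::local_seed(seed)
    n <- 400
    risk <- rbinom(n, 1, 0.5) # true split at the median
    score <- -risk + rnorm(n, 0, 0.05)
    t_ev <- rexp(n, exp(1.2 * risk))
    rg <- threshold_search(score, t_ev, rep(TRUE, n))
    if (abs(rg$percentile - 0.5) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 6)

  rg1 <- threshold_search(rnorm(50), rexp(50), rep(TRUE, 50), grid = 0.5)
  expect_equal(rg1$percentile, 0.5)
})

test_that("threshold ties break toward the middle of the grid", {
  # all outcomes identical: every split has p ~ 1
  withr::local_seed(4)
  score <- rnorm(60)
  rg <- threshold_search(score, rep(5, 60), rep(TRUE, 60))
  expect_equal(rg$percentile, 0.5)
})

test_that("frozen cuts classify new scores without touching test outcomes", {
  withr::local_seed(13)
  score <- rnorm(100)
  rg <- threshold_search(score, rexp(100, exp(-score)), rep(TRUE, 100))
  new_scores <- c(rg$cut - 1, rg$cut, rg$cut + 1)
  expect_equal(assign_risk_group(rg, new_scores), c("high", "high", "low"))
  # the search function cannot even receive test outcomes
  expect_false(any(grepl("test", names(formals(threshold_search)))))
})

test_that("Kendall cross-modal concordance matches pair enumeration", {
  sc <- tibble::tibble(id = letters[1:5],
                       a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_equal(kendall_cross_modal(sc, c("a", "b")), 1)
  sc$b <- rev(sc$b)
  expect_equal(kendall_cross_modal(sc, c("a", "b")), -1)

  sc$b <- c(2, 1, 4, 3, 5)
  expect_equal(kendall_cross_modal(sc, c("a", "b")),
               oracle_tau_b(sc$a, sc$b))

  sc$b[1:4] <- NA
  expect_error(kendall_cross_modal(sc, c("a", "b")), "complete pairs")

  km <- kendall_matrix(tibble::tibble(id = letters[1:6], g = rnorm(6),
                                      r = rnorm(6), h = rnorm(6)))
  expect_equal(nrow(km), 3)
})

test_that("the exact Mann-Whitney enumeration reproduces closed-form cases", {
  # most extreme arrangement of 3 vs 3: one-sided p = 1/20
  expect_equal(mann_whitney_ordinal(c(1, 2, 3), c(4, 5, 6), "less"), 0.05)
  expect_equal(mann_whitney_ordinal(c(4, 5, 6), c(1, 2, 3), "greater"), 0.05)
  # identical strata: no shift, p >= 0.5
  expect_gte(mann_whitney_ordinal(c(1, 2, 3), c(1, 2, 3), "greater"), 0.5)

  # direction swap identity: p_greater + p_less = 1 + P(U = U_obs)
  withr::local_seed(21)
  x <- sample(1:5, 6, replace = TRUE)
  y <- sample(1:5, 5, replace = TRUE)
  pg <- mann_whitney_ordinal(x, y, "greater")
  pl <- mann_whitney_ordinal(x, y, "less")
  expect_gte(pg + pl, 1)
  expect_lte(pg + pl, 1 + 1)

  # large samples agree with the tie-corrected normal approximation
  withr::local_seed(22)
  xb <- rnorm(30); yb <- rnorm(25) - 0.5
  expect_equal(mann_whitney_ordinal(xb, yb, "greater"),
               wilcox.test(xb, yb, alternative = "greater", exact = FALSE)$p.value)
})

test_that("the CRS association tests good responders against the rest", {
  withr::local_seed(23)
  score <- c(rnorm(10, 1), rnorm(20, 0))
  crs <- c(rep(3, 10), rep(1:2, 10))
  res <- crs_association(score, crs)
  expect_lt(res$p, 0.05)
  expect_equal(res$n_good, 10)
  expect_error(crs_association(rnorm(5), rep(3, 5)), "empty")
})

test_that("evaluation reports are internally consistent and seed-stable", {
  withr::local_seed(77)
  inst <- random_surv_instance(80)
  scores <- tibble::tibble(id = sprintf("p%02d", 1:80),
                           score = inst$score)
  out <- tibble::tibble(id = sprintf("p%02d", 1:80), time = inst$time,
                        event = inst$event)
  ev <- evaluate_risks(scores, out, n_boot = 50, n_perm = 100, seed = 3)
  expect_true(ev$c_index >= 0 && ev$c_index <= 1)
  expect_true(ev$perm_p > 0 && ev$perm_p <= 1)
  expect_equal(ev$n, 80)
  ev2 <- evaluate_risks(scores, out, n_boot = 50, n_perm = 100, seed = 3)
  expect_identical(ev, ev2)
})
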