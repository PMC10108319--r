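# Point estimators, sampling variances, CV pooling and the Geary screen.

test_that("cv and raw lnRR follow their definitions and domain rules", {
  expect_equal(cv(10, 2), 0.2)
  expect_equal(cv(5, 0), 0)
  expect_equal(cv(4, 6), 1.5)  # over-dispersed data allowed
  expect_error(cv(10, NA), class = "lnrrmiss_missing_sd")
  expect_error(cv(-1, 2), class = "lnrrmiss_domain")

  expect_equal(lnrr_raw(10, 5), log(2))
  expect_equal(lnrr_raw(7, 7), 0)
  expect_error(lnrr_raw(0, 5), class = "lnrrmiss_domain")
})

test_that("raw lnRR is antisymmetric under group swap", {
  set.seed(11)
  m1 <- runif(50, 0.1, 20)
  m2 <- runif(50, 0.1, 20)
  expect_equal(lnrr_raw(m1, m2), -lnrr_raw(m2, m1))
})

test_that("bias-corrected lnRR applies the crossed-index correction term", {
  # equal CVs, equal n: correction cancels
  expect_equal(lnrr_corrected(10, 2, 10, 5, 1, 10), log(2))
  # CV1 = 0.2, CV2 = 0.4, n1 = n2 = 10: ln2 + (0.04 - 0.16)/20
  expect_equal(lnrr_corrected(10, 2, 10, 5, 2, 10),
               log(2) + 0.5 * (0.04 / 10 - 0.16 / 10))
  # zero SDs reduce to the raw ratio
  expect_equal(lnrr_corrected(10, 0, 10, 5, 0, 10), lnrr_raw(10, 5))
  expect_error(lnrr_corrected(10, NA, 10, 5, 1, 10), class = "lnrrmiss_missing_sd")
})

test_that("pooled-CV lnRR uses the record's n with dataset-level CVs", {
  expect_equal(lnrr_pooled(10, 5, 10, 10, 0.3, 0.3), log(2))
  expect_equal(lnrr_pooled(10, 5, 10, 10, 0, 0), lnrr_raw(10, 5))
  expect_equal(lnrr_pooled(10, 5, 5, 20, 0.2, 0.4),
               log(2) + 0.5 * (0.04 / 20 - 0.16 / 5))
})

test_that("first- and second-order sampling variances match hand evaluation", {
  expect_equal(var_individual_first(10, 2, 10, 5, 1, 10), 0.008)
  expect_equal(var_individual_second(10, 2, 10, 5, 1, 10), 0.008016)
  expect_equal(var_pooled_second(10, 10, 0.3, 0.3), 0.018081)
  expect_equal(var_pooled_first(10, 10, 0.3, 0.3), 0.018)
})

test_that("unit CVs reduce the first-order variance to 1/n-tilde", {
  for (n1 in c(2, 3, 7, 30)) {
    for (n2 in c(2, 5, 12, 40)) {
      expect_equal(var_individual_first(10, 10, n1, 4, 4, n2),
                   (n1 + n2) / (n1 * n2))
      expect_equal(var_pooled_first(n1, n2, 1, 1), (n1 + n2) / (n1 * n2))
    }
  }
})

test_that("second-order variances dominate first-order, equality iff CVs are 0", {
  set.seed(42)
  for (i in 1:50) {
    n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
    m1 <- runif(1, 1, 20); m2 <- runif(1, 1, 20)
    sd1 <- runif(1, 0, 10); sd2 <- runif(1, 0, 10)
    v1 <- var_individual_first(m1, sd1, n1, m2, sd2, n2)
    v2 <- var_individual_second(m1, sd1, n1, m2, sd2, n2)
    expect_gte(v2, v1)
    cb1 <- runif(1, 0, 2); cb2 <- runif(1, 0, 2)
    expect_gte(var_pooled_second(n1, n2, cb1, cb2),
               var_pooled_first(n1, n2, cb1, cb2))
  }
  expect_equal(var_individual_second(10, 0, 5, 5, 0, 5),
               var_individual_first(10, 0, 5, 5, 0, 5))
})

test_that("doubling both n halves the first-order part and quarters the second", {
  first <- function(n) var_pooled_first(n, n, 0.3, 0.4)
  second_part <- function(n) var_pooled_second(n, n, 0.3, 0.4) - first(n)
  expect_equal(first(20), first(10) / 2)
  expect_equal(second_part(20), second_part(10) / 4)
})

test_that("pooled_cv is the two-stage sample-size-weighted average", {
  d <- as_effect_data(data.frame(
    study_id = c("a", "b"), effect_id = c("e1", "e2"),
    m1 = 10, sd1 = c(2, 4), n1 = c(10, 30),
    m2 = 10, sd2 = c(2, 4), n2 = c(10, 30)))
  p <- pooled_cv(d)
  expect_equal(p$cv1_bar, (10 * 0.2 + 30 * 0.4) / 40)  # 0.35
  expect_equal(p$n_studies_used, 2L)
  expect_equal(p$n_effects_used, 2L)

  # within-study averaging first: study a has CVs 0.2 and 0.4 at n = 10 each
  d2 <- as_effect_data(data.frame(
    study_id = c("a", "a", "b"), effect_id = paste0("e", 1:3),
    m1 = 10, sd1 = c(2, 4, 3), n1 = c(10, 10, 20),
    m2 = 10, sd2 = c(2, 4, 3), n2 = c(10, 10, 20)))
  expect_equal(pooled_cv(d2)$cv1_bar, 0.3)

  # brute-force two-stage oracle on a random mixed dataset
  set.seed(7)
  d3 <- as_effect_data(data.frame(
    study_id = rep(c("a", "b", "c"), c(3, 2, 1)), effect_id = paste0("e", 1:6),
    m1 = runif(6, 5, 15), sd1 = runif(6, 0.5, 5), n1 = sample(3:20, 6),
    m2 = runif(6, 5, 15), sd2 = runif(6, 0.5, 5), n2 = sample(3:20, 6)))
  by_study <- split(seq_len(6), d3$study_id)
  cv1 <- d3$sd1 / d3$m1
  within <- vapply(by_study, function(i) sum(d3$n1[i] * cv1[i]) / sum(d3$n1[i]), 0)
  wts <- vapply(by_study, function(i) sum(d3$n1[i]), 0)
  expect_equal(pooled_cv(d3)$cv1_bar, sum(wts * within) / sum(wts))
})

test_that("pooled_cv of homogeneous CVs returns those CVs", {
  d <- as_effect_data(data.frame(
    study_id = paste0("s", 1:4), effect_id = paste0("e", 1:4),
    m1 = c(5, 8, 12, 3), sd1 = 0.25 * c(5, 8, 12, 3), n1 = c(4, 9, 13, 6),
    m2 = c(6, 7, 11, 2), sd2 = 0.25 * c(6, 7, 11, 2), n2 = c(5, 8, 12, 7)))
  p <- pooled_cv(d)
  expect_equal(p$cv1_bar, 0.25)
  expect_equal(p$cv2_bar, 0.25)
})

test_that("pooled_cv uses available group CVs of partially missing records", {
  d <- as_effect_data(data.frame(
    study_id = c("a", "b"), effect_id = c("e1", "e2"),
    m1 = 10, sd1 = c(2, 4), n1 = c(10, 30),
    m2 = 10, sd2 = c(2, NA), n2 = c(10, 30)))
  p <- pooled_cv(d)
  expect_equal(p$cv1_bar, 0.35)   # both group-1 CVs contribute
  expect_equal(p$cv2_bar, 0.2)    # only the complete record's group-2 CV
  expect_equal(p$n_effects_used, 1L)
})

test_that("pooled_cv errors when every record is missing SDs", {
  d <- data.frame(study_id = "a", effect_id = "e1",
                  m1 = 10, sd1 = NA, n1 = 5, m2 = 8, sd2 = NA, n2 = 5)
  expect_error(pooled_cv(as_effect_data(d)), class = "lnrrmiss_no_complete_records")
})

test_that("Geary criterion and its minimum-n inverse agree", {
  expect_gt(geary_criterion(5, 226), 3)
  expect_lt(geary_criterion(5, 225), 3)
  expect_equal(geary_criterion(0, 10), Inf)
  expect_equal(geary_min_n(5), 226)
  expect_equal(geary_min_n(1), 10)

  # bracketing over a log grid of CVs, against a linear-scan oracle
  for (cvv in exp(seq(log(0.01), log(10), length.out = 9))) {
    n_star <- geary_min_n(cvv)
    scan <- 1L
    while (geary_criterion(cvv, scan) < 3) scan <- scan + 1L
    expect_identical(n_star, scan)
    expect_gte(geary_criterion(cvv, n_star), 3)
    if (n_star > 1) expect_lt(geary_criterion(cvv, n_star - 1), 3)
  }
  # monotone nondecreasing in cv
  ns <- vapply(c(0.05, 0.2, 0.5, 1, 2, 5), geary_min_n, 1L)
  expect_true(all(diff(ns) >= 0))
})

test_that("geary_screen requires both groups to pass and NA's missing SDs", {
  d <- as_effect_data(data.frame(
    study_id = c("a", "b", "c"), effect_id = paste0("e", 1:3),
    m1 = 10, sd1 = c(1, 50, NA), n1 = 10,
    m2 = 10, sd2 = c(1, 1, 1), n2 = 10))
  expect_identical(geary_screen(d), c(TRUE, FALSE, NA))
})
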