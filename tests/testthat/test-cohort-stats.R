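test_that("mean arterial pressure is 1/3 systolic + 2/3 diastolic, averaged", {
  expect_equal(mean_arterial_pressure(c(120, 80)), 120 / 3 + 2 * 80 / 3)
  expect_equal(mean_arterial_pressure(rbind(c(120, 80), c(126, 84),
                                            c(114, 76))),
               mean(c(120 / 3 + 160 / 3, 42 + 56, 38 + 152 / 3)))
  expect_error(mean_arterial_pressure(c(100, 100)), "below systolic")
  expect_error(mean_arterial_pressure(c(80, 120)), "below systolic")
})

test_that("folded F-test and Shapiro-Wilk behave as expected", {
  set.seed(4)
  a <- rnorm(15)
  b <- a + 2                     # identical variance, equal n
  ca <- check_assumptions(a, b)
  expect_equal(ca$folded_f$F, 1)
  expect_equal(ca$folded_f$p, 1)

  b2 <- rnorm(20)
  b2 <- (b2 - mean(b2)) / sd(b2) * 2 * sd(a)   # s2 = 2 * s1 exactly
  expect_equal(check_assumptions(a, b2)$folded_f$F, 4)
  expect_error(check_assumptions(a[1:2], b), "at least 3")

  hits <- vapply(1:100, function(s) {
    set.seed(s)
    stats::shapiro.test(rnorm(500))$p.value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("summary t-test reproduces the published group comparisons", {
  expect_equal(ttest_from_summary(5, 1, 10, 5, 1, 12)$t, 0)
  expect_equal(ttest_from_summary(5, 1, 10, 5, 1, 12)$p, 1)

  map_row <- ttest_from_summary(86, 13, 12, 102, 13, 19)
  expect_identical(map_row$df, 29)
  expect_equal(map_row$p, 0.002, tolerance = 0.25)  # prints as 0.002
  expect_equal(round(map_row$p, 3), 0.002)

  hct_row <- ttest_from_summary(29, 4, 12, 44, 3, 19)
  expect_lt(hct_row$p, 0.0001)

  swapped <- ttest_from_summary(102, 13, 19, 86, 13, 12)
  expect_equal(swapped$p, map_row$p)
  expect_equal(swapped$t, -map_row$t)
  expect_error(ttest_from_summary(1, 0, 5, 2, 1, 5), "positive")
})

test_that("Fisher exact p matches exhaustive enumeration", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_2x2(2, 10, 10, 9), 0.07, tolerance = 0.1)
  set.seed(12)
  for (i in 1:25) {
    tb <- rmultinom(1, sample(8:30, 1), rep(0.25, 4))
    if (any(rowSums(matrix(tb, 2)) == 0) ||
        any(colSums(matrix(tb, 2)) == 0)) next
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 oracle_fisher(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margins")
})

test_that("correlation power matches its Monte-Carlo oracle and is monotone", {
  p <- power_correlation(41, 0.43, 0.05)
  expect_equal(p, 0.80, tolerance = 0.025)

  # null case: power tends to alpha as r -> 0
  expect_equal(power_correlation(41, 1e-9, 0.05), 0.05, tolerance = 1e-6)

  # Monte-Carlo oracle: simulate bivariate-normal datasets, test r at alpha
  set.seed(77)
  n <- 41; r <- 0.43
  tcrit <- qt(0.975, n - 2)
  rej <- vapply(1:10000, function(i) {
    x <- rnorm(n)
    y <- r * x + sqrt(1 - r^2) * rnorm(n)
    rr <- cor(x, y)
    abs(rr * sqrt(n - 2) / sqrt(1 - rr^2)) > tcrit
  }, logical(1))
  expect_lt(abs(p - mean(rej)), 0.02)

  ns <- c(20, 30, 41, 60, 100)
  expect_true(all(diff(vapply(ns, power_correlation, 1, r = 0.43)) > 0))
  rs <- c(0.2, 0.3, 0.43, 0.6, 0.8)
  expect_true(all(diff(vapply(rs, function(r)
    power_correlation(41, r), numeric(1))) > 0))
  expect_error(power_correlation(3, 0.4), "exceed")
  expect_error(power_correlation(41, 1.2), "lie in")
})

test_that("association model equals OLS when subject variance is zero", {
  set.seed(21)
  n_subj <- 20
  df <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:n_subj), each = 2),
    laterality = rep(c("OD", "OS"), n_subj),
    map = rep(rnorm(n_subj, 95, 10), each = 2),
    trbf_ul_min = rnorm(2 * n_subj, 55, 20))
  # antithetic within-subject residuals force the subject variance to its
  # zero boundary
  e <- rnorm(n_subj, 0, 0.08)
  df$vti <- 0.3 + 0.5 * df$trbf_ul_min / 100 + as.vector(rbind(e, -e))
  fit <- fit_association_model(df, "vti")
  ols <- lm(vti ~ I(trbf_ul_min / 100) + map + laterality, df)
  expect_equal(fit$beta, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_lt(fit$var_subject, 1e-8)
})

test_that("association beta scales exactly with the predictor's units", {
  co <- make_cohort(seed = 14)
  f1 <- fit_association_model(co$eyes, "vti")
  eyes2 <- co$eyes
  eyes2$trbf_ul_min <- eyes2$trbf_ul_min / 100
  f2 <- suppressWarnings(fit_association_model(eyes2, "vti"))
  expect_equal(f2$beta, f1$beta * 100, tolerance = 1e-6)
})

test_that("singular designs are rejected naming the collinear columns", {
  co <- make_cohort(seed = 15)
  eyes <- co$eyes
  eyes$map <- 100                      # constant: collinear with intercept
  expect_error(fit_association_model(eyes, "vti"), "singular design")
  expect_error(fit_association_model(eyes, "vti"), "map")
})

test_that("group model is symmetric and null for identical groups", {
  set.seed(33)
  base <- data.frame(
    subject_id = rep(sprintf("N%02d", 1:15), each = 2),
    laterality = rep(c("OD", "OS"), 15),
    map = rep(rnorm(15, 95, 8), each = 2),
    vti = rnorm(30, 0.5, 0.1))
  dup <- base
  dup$subject_id <- sub("N", "X", dup$subject_id)
  both <- rbind(cbind(base, group = "NC"), cbind(dup, group = "SCR"))
  g <- fit_group_model(both, "vti")
  expect_equal(g$beta, 0, tolerance = 1e-8)
  expect_gt(g$p_value, 0.99)

  co <- make_cohort(seed = 16)
  g1 <- fit_group_model(co$eyes, "vti")
  flipped <- co$eyes
  flipped$group <- ifelse(flipped$group == "SCR", "NC", "SCR")
  g2 <- fit_group_model(flipped, "vti")
  expect_equal(g2$beta, -g1$beta, tolerance = 1e-6)
  expect_equal(g1$mean_scr, g2$mean_nc)
})

test_that("group model recovers the generating VTI difference", {
  hits <- vapply(1:30, function(s) {
    co <- make_cohort(seed = 300 + s)
    g <- fit_group_model(co$eyes, "vti")
    se <- (g$ci_high - g$ci_low) / (2 * qt(0.975, g$df))
    abs(g$beta - 0.19) <= 2 * se
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
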