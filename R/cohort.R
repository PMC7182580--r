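#' Mean arterial pressure from blood-pressure readings
#'
#' MAP of each reading is `1/3 * systolic + 2/3 * diastolic`; readings
#' (typically three) are averaged.
#'
#' @param readings Two-column matrix or data frame of (systolic, diastolic)
#'   mmHg, one row per reading, or a length-2 vector for a single reading.
#' @return MAP in mmHg.
#' @export
mean_arterial_pressure <- function(readings) {
  if (is.null(dim(readings))) readings <- matrix(readings, ncol = 2L, byrow = TRUE)
  readings <- as.matrix(readings)
  if (ncol(readings) != 2L || nrow(readings) < 1L)
    stop("readings must be (systolic, diastolic) pairs")
  sbp <- readings[, 1L]; dbp <- readings[, 2L]
  if (any(dbp <= 0) || any(sbp <= 0)) stop("blood pressures must be positive")
  if (any(dbp >= sbp)) stop("diastolic must be below systolic")
  mean(sbp / 3 + 2 * dbp / 3)
}

#' Check normality and variance-equality assumptions for two samples
#'
#' Shapiro-Wilk test per sample plus the folded F-test
#' `F = s_max^2 / s_min^2` with a two-sided p-value from the F distribution
#' (numerator df from the higher-variance sample).
#'
#' @param a,b Numeric samples, each of length >= 3.
#' @param alpha Significance level for the pass flags.
#' @return List with `shapiro_a`, `shapiro_b` (each `W`, `p`), `folded_f`
#'   (`F`, `df1`, `df2`, `p`) and logical flags `normal_a`, `normal_b`,
#'   `equal_var`.
#' @export
check_assumptions <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L) stop("need at least 3 values per sample")
  sa <- stats::shapiro.test(a)
  sb <- stats::shapiro.test(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va >= vb) {
    f <- va / vb; df1 <- length(a) - 1L; df2 <- length(b) - 1L
  } else {
    f <- vb / va; df1 <- length(b) - 1L; df2 <- length(a) - 1L
  }
  pf2 <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  list(shapiro_a = list(W = unname(sa$statistic), p = sa$p.value),
       shapiro_b = list(W = unname(sb$statistic), p = sb$p.value),
       folded_f = list(F = f, df1 = df1, df2 = df2, p = pf2),
       normal_a = sa$p.value > alpha, normal_b = sb$p.value > alpha,
       equal_var = pf2 > alpha)
}

#' Pooled-variance unpaired t-test from summary statistics
#'
#' Two-sided test with `df = n1 + n2 - 2`, usable directly on published
#' mean +/- SD group summaries.
#'
#' @param m1,s1,n1 Mean, SD and size of sample 1.
#' @param m2,s2,n2 Mean, SD and size of sample 2.
#' @return List with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' P-value by summation of hypergeometric probabilities of all tables (with
#' the observed margins) no more probable than the observed one.
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` on row 1, `(c, d)` on row 2.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("all table margins must be positive")
  stats::fisher.test(matrix(counts, 2L, 2L, byrow = TRUE))$p.value
}

#' Power to detect a correlation coefficient
#'
#' Closed form via the Fisher z transform:
#' `power = Phi(sqrt(n - 3) * atanh(r) - z_{1 - alpha/2})` plus the (usually
#' negligible) opposite tail.
#'
#' @param n Sample size (> 3).
#' @param r True correlation in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in (0, 1).
#' @export
power_correlation <- function(n, r, alpha = 0.05) {
  if (n <= 3) stop("n must exceed 3")
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  za <- stats::qnorm(1 - alpha / 2)
  zr <- sqrt(n - 3) * atanh(r)
  stats::pnorm(zr - za) + stats::pnorm(-zr - za)
}

# Shared fitting core: REML random-intercept model with Satterthwaite t
# inference on one focal fixed effect.
fit_mixed <- function(data, outcome, focal, covariates) {
  needed <- c(outcome, focal, covariates, "subject_id")
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[, needed]), , drop = FALSE]
  if (length(unique(data$subject_id)) < 2L) stop("need >= 2 subjects")

  fixed <- c(focal, covariates)
  X <- stats::model.matrix(stats::reformulate(fixed), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design: collinear columns ", paste(bad, collapse = ", "))
  }

  fml <- stats::reformulate(c(fixed, "(1 | subject_id)"), response = outcome)
  fit <- suppressMessages(lmerTest::lmer(
    fml, data = data, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  co <- stats::coef(summary(fit))
  row <- co[grep(paste0("^", focal), rownames(co))[1L], ]
  beta <- row[["Estimate"]]; se <- row[["Std. Error"]]; df <- row[["df"]]
  tcrit <- stats::qt(0.975, df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fit = fit, data = data,
       beta = beta, se = se, df = df,
       ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
       p_value = row[["Pr(>|t|)"]],
       var_subject = vc$vcov[vc$grp == "subject_id"],
       var_residual = vc$vcov[vc$grp == "Residual"],
       n_obs = nrow(data), n_subjects = length(unique(data$subject_id)))
}

#' Mixed-model association between TRBF and a morphology metric
#'
#' Variance-components linear mixed model
#' `outcome ~ trbf/100 + map + laterality + (1 | subject)` fitted by REML;
#' the focal effect is the change in the outcome per 100 uL/min of total
#' retinal blood flow, adjusted for mean arterial pressure and eye
#' (laterality), with a subject random intercept absorbing intra-subject
#' correlation between fellow eyes. Inference is Wald-type with Satterthwaite
#' degrees of freedom.
#'
#' @param eyes Data frame of eye records joined to subject covariates; must
#'   contain `subject_id`, `laterality`, `map`, `trbf_ul_min` and the outcome
#'   column. Rows with missing values in any used column are dropped.
#' @param outcome One of `"vti"`, `"vd"`, `"ssv"`, `"slv"` (any numeric
#'   column works).
#' @param covariates Adjustment covariates (fixed effects).
#' @return Object of class `model_fit`: list with `beta`, `ci_low`,
#'   `ci_high`, `p_value`, `var_subject`, `var_residual`, `df`, `n_obs`,
#'   `n_subjects`.
#' @export
fit_association_model <- function(eyes, outcome,
                                  covariates = c("map", "laterality")) {
  eyes <- as.data.frame(eyes)
  if (!"trbf_ul_min" %in% names(eyes)) stop("missing columns: trbf_ul_min")
  eyes$trbf100 <- eyes$trbf_ul_min / 100
  res <- fit_mixed(eyes, outcome, "trbf100", covariates)
  structure(res[c("beta", "ci_low", "ci_high", "p_value", "var_subject",
                  "var_residual", "df", "n_obs", "n_subjects")],
            class = "model_fit")
}

#' Mixed-model group comparison (SCR vs NC)
#'
#' Same model as [fit_association_model()] with disease group (NC as the
#' reference level) replacing TRBF as the focal fixed effect. Also reports
#' the unadjusted per-group mean and SD of the outcome.
#'
#' @inheritParams fit_association_model
#' @param outcome Outcome column (`"vti"`, `"vd"`, `"ssv"`, `"slv"`,
#'   `"trbf_ul_min"`, ...).
#' @return Object of class `group_comparison`: list with `mean_scr`,
#'   `sd_scr`, `mean_nc`, `sd_nc`, `beta`, `ci_low`, `ci_high`, `p_value`,
#'   `var_subject`, `var_residual`.
#' @export
fit_group_model <- function(eyes, outcome,
                            covariates = c("map", "laterality")) {
  eyes <- as.data.frame(eyes)
  if (!"group" %in% names(eyes)) stop("missing columns: group")
  eyes$group <- factor(eyes$group, levels = c("NC", "SCR"))
  res <- fit_mixed(eyes, outcome, "group", covariates)
  used <- res$data
  structure(c(list(mean_scr = mean(used[[outcome]][used$group == "SCR"]),
                   sd_scr = stats::sd(used[[outcome]][used$group == "SCR"]),
                   mean_nc = mean(used[[outcome]][used$group == "NC"]),
                   sd_nc = stats::sd(used[[outcome]][used$group == "NC"])),
              res[c("beta", "ci_low", "ci_high", "p_value", "var_subject",
                    "var_residual", "df", "n_obs", "n_subjects")]),
            class = "group_comparison")
}
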