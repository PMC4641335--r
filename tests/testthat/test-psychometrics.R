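test_that("Cronbach's alpha closed-form cases", {
  # two perfectly correlated items with equal positive variance -> 1
  x <- cbind(a = c(0, 1, 2, 3), b = c(1, 2, 3, 4))
  expect_equal(cronbach_alpha(x)$alpha, 1.0)
  # pairwise uncorrelated items with equal variance -> 0
  x <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  expect_equal(cronbach_alpha(x)$alpha, 0.0)
})

test_that("alpha equals the covariance-trace evaluation on random matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:6, 1)
    x <- matrix(sample(0:4, 10 * k, replace = TRUE), nrow = 10)
    a <- cronbach_alpha(x)$alpha
    C <- stats::cov(x)
    oracle <- (k / (k - 1)) * (1 - sum(diag(C)) / sum(C))
    if (!is.finite(oracle)) next
    expect_equal(a, oracle, tolerance = 1e-12)
  }
})

test_that("alpha is invariant to item shifts and reordering", {
  set.seed(99)
  x <- matrix(sample(0:4, 40, replace = TRUE), nrow = 10)
  a0 <- cronbach_alpha(x)$alpha
  x_shift <- x
  x_shift[, 2] <- x_shift[, 2] + 7
  expect_equal(cronbach_alpha(x_shift)$alpha, a0, tolerance = 1e-12)
  expect_equal(cronbach_alpha(x[, c(3, 1, 4, 2)])$alpha, a0, tolerance = 1e-12)
})

test_that("alpha is undefined with a stated reason in degenerate cases", {
  expect_match(cronbach_alpha(matrix(1:5, ncol = 1))$reason, "fewer than 2 items")
  expect_match(cronbach_alpha(matrix(c(1, NA, NA, 2, NA, NA), ncol = 2))$reason,
               "complete cases")
  x <- cbind(c(1, 2, 3), c(3, 2, 1))  # total score constant
  expect_match(cronbach_alpha(x)$reason, "zero total-score variance")
})

test_that("PPV/NPV follow the contingency-table definitions", {
  # table (tp=5, fp=5, fn=1, tn=9) -> ppv 0.5, npv 0.9
  s <- c(rep(TRUE, 10), rep(FALSE, 10))
  cr <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 1), rep(FALSE, 9))
  r <- ppv_npv(s, cr)
  expect_equal(r$table[c("tp", "fp", "fn", "tn")],
               list(tp = 5L, fp = 5L, fn = 1L, tn = 9L))
  expect_equal(r$ppv, 0.5)
  expect_equal(r$npv, 0.9)
  # self-consistency with the returned table
  expect_equal(r$ppv, r$table$tp / (r$table$tp + r$table$fp))
  expect_equal(r$npv, r$table$tn / (r$table$tn + r$table$fn))
  # all flagged and confirmed: ppv 1, npv undefined with reason (never 0)
  r <- ppv_npv(rep(TRUE, 8), rep(TRUE, 8))
  expect_equal(r$ppv, 1.0)
  expect_true(is.na(r$npv))
  expect_match(r$npv_reason, "cleared")
  # identity channel: both perfect
  set.seed(4)
  f <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  r <- ppv_npv(f, f)
  expect_equal(r$ppv, 1.0)
  expect_equal(r$npv, 1.0)
  # not-scorable respondents are excluded and counted
  s <- c(TRUE, NA, FALSE, TRUE)
  cr <- c(TRUE, TRUE, NA, FALSE)
  r <- ppv_npv(s, cr)
  expect_equal(r$table$n_excluded, 2L)
  expect_equal(r$n + r$table$n_excluded, 4L)
})

test_that("correlation method is chosen by normality and matches rank oracle", {
  # exact identity: coefficient 1 under either method
  x <- 1:30
  expect_equal(semas_correlation(x, x)$coefficient, 1.0)
  # monotone nonlinear transform with heavy ties -> spearman, equal to the
  # rank-then-pearson oracle with average ranks
  set.seed(12)
  x <- sample(0:6, 200, replace = TRUE)
  y <- floor(exp(x / 2)) + sample(0:1, 200, replace = TRUE)
  r <- semas_correlation(x, y)
  expect_equal(r$method, "spearman")
  oracle <- stats::cor(rank(x), rank(y))
  expect_equal(r$coefficient, oracle, tolerance = 1e-12)
  # two clean normal vectors -> pearson
  set.seed(13)
  a <- rnorm(200); b <- 0.5 * a + rnorm(200)
  r <- semas_correlation(a, b)
  expect_equal(r$method, "pearson")
  expect_equal(r$coefficient, stats::cor(a, b), tolerance = 1e-12)
  # pearson and spearman coincide on strictly monotone linear data, no ties
  x <- seq(1, 10, by = 0.5)
  y <- 3 * x - 2
  expect_equal(stats::cor(x, y), stats::cor(x, y, method = "spearman"))
  # constant vector -> undefined with reason
  expect_match(semas_correlation(rep(1, 10), 1:10)$reason, "constant")
})

test_that("sample correlation recovers the population value at n = 5000", {
  set.seed(77)
  rho <- 0.6
  z <- MASS::mvrnorm(5000, c(0, 0), matrix(c(1, rho, rho, 1), 2))
  r <- semas_correlation(z[, 1], z[, 2])
  expect_equal(r$method, "pearson")
  expect_lt(abs(r$coefficient - rho), 0.03)  # ~ (1 - rho^2)/sqrt(n)
})

test_that("the ANOVA screen retains real group differences and drops null ones", {
  profiles <- data.frame(x_cat = rep(c("none", "minor"), each = 20))
  class(profiles) <- c("semas_profiles", class(profiles))
  # identical PAM in both groups: F ~ 0, not retained
  scr <- anova_screen(profiles, rep(60, 40), "x")
  expect_false(scr$retained)
  expect_lt(scr$f_value, 1e-20)
  # means 60 vs 40, sd 5, n = 20 each: overwhelming F, retained
  set.seed(5)
  pam <- c(rnorm(20, 60, 5), rnorm(20, 40, 5))
  pam <- pam[order(rep(c(1, 2), each = 20))]
  scr <- anova_screen(profiles, c(rnorm(20, 60, 5), rnorm(20, 40, 5)), "x")
  expect_true(scr$retained)
  expect_gt(scr$f_value, 50)
  # F equals the squared two-sample t statistic
  g1 <- rnorm(20, 60, 5); g0 <- rnorm(20, 40, 5)
  scr <- anova_screen(profiles, c(g1, g0), "x")
  tt <- stats::t.test(g1, g0, var.equal = TRUE)
  expect_equal(scr$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(scr$p_value, tt$p.value, tolerance = 1e-10)
  # a group with < 2 members is skipped with a log entry
  profiles2 <- data.frame(x_cat = c("none", rep("minor", 9)))
  class(profiles2) <- c("semas_profiles", class(profiles2))
  scr <- anova_screen(profiles2, rnorm(10), "x")
  expect_equal(nrow(scr), 0L)
  expect_match(attr(scr, "skipped"), "fewer than 2")
})

test_that("single-predictor regression equals the two-group closed form", {
  set.seed(21)
  free <- rep(c(1L, 0L), each = 30)
  pam <- 40 + 15 * free + rnorm(60, sd = 8)
  profiles <- data.frame(
    se_cat = ifelse(free == 1, "none", sample(c("minor", "major"), 60, TRUE)))
  class(profiles) <- c("semas_profiles", class(profiles))
  reg <- convergent_regression(profiles, pam, "se")
  expect_equal(reg$coefficients$beta,
               mean(pam[free == 1]) - mean(pam[free == 0]), tolerance = 1e-10)
  # r-squared equals the squared point-biserial correlation
  expect_equal(reg$r_squared, stats::cor(pam, free)^2, tolerance = 1e-10)
})

test_that("regression coefficients match the normal-equations solution", {
  set.seed(31)
  n <- 120
  profiles <- data.frame(
    a_cat = sample(c("none", "minor", "major"), n, TRUE),
    b_cat = sample(c("none", "minor"), n, TRUE),
    c_cat = sample(c("none", "major"), n, TRUE))
  class(profiles) <- c("semas_profiles", class(profiles))
  X <- cbind(1,
             as.numeric(profiles$a_cat == "none"),
             as.numeric(profiles$b_cat == "none"),
             as.numeric(profiles$c_cat == "none"))
  pam <- X %*% c(35, 12, 5, -3) + rnorm(n, sd = 6)
  reg <- convergent_regression(profiles, as.numeric(pam), c("a", "b", "c"))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% pam)
  expect_equal(c(reg$intercept, reg$coefficients$beta), c(beta_oracle),
               tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear predictor", {
  profiles <- data.frame(a_cat = rep(c("none", "minor"), 20),
                         b_cat = rep(c("none", "minor"), 20))
  class(profiles) <- c("semas_profiles", class(profiles))
  expect_error(convergent_regression(profiles, rnorm(40), c("a", "b")),
               "collinear.*(a|b)")
})

test_that("r-squared vanishes when predictors are independent of the outcome", {
  set.seed(41)
  n <- 5000
  profiles <- data.frame(
    a_cat = sample(c("none", "minor"), n, TRUE),
    b_cat = sample(c("none", "major"), n, TRUE))
  class(profiles) <- c("semas_profiles", class(profiles))
  reg <- convergent_regression(profiles, rnorm(n, 50, 10), c("a", "b"))
  expect_lt(reg$r_squared, 0.01)
})

test_that("the end-to-end validation report has the expected shape", {
  coh <- simulate_cohort(cohort_config(n = 204, seed = 8))
  instr <- the_instrument()
  rep <- validation_report(coh$semas_responses, coh$criterion_responses,
                           coh$pam_scores, instr, example_criterion_rules())
  expect_s3_class(rep, "semas_validation_report")
  expect_equal(nrow(rep$rows), 7L)  # one row per characteristic
  expect_setequal(rep$rows$characteristic,
                  c("self_efficacy", "coping", "depression", "anxiety",
                    "locus", "social_support", "burden"))
  # burden and social support carry no criterion rule: PPV/NPV not applicable
  na_rows <- rep$rows[rep$rows$characteristic %in%
                        c("burden", "social_support"), ]
  expect_true(all(is.na(na_rows$ppv)) && all(is.na(na_rows$npv)))
  expect_equal(nrow(rep$coping_styles), 3L)
  # PPV/NPV self-consistency against the stored contingency tables
  for (ch in names(rep$contingency)) {
    tab <- rep$contingency[[ch]]
    row <- rep$rows[rep$rows$characteristic == ch, ]
    if (!is.na(row$ppv)) expect_equal(row$ppv, tab$tp / (tab$tp + tab$fp))
    if (!is.na(row$npv)) expect_equal(row$npv, tab$tn / (tab$tn + tab$fn))
    expect_equal(row$n + tab$n_excluded, 204L)
  }
  # defined proportions live in [0, 1]
  expect_true(all(rep$rows$ppv >= 0 & rep$rows$ppv <= 1, na.rm = TRUE))
  expect_true(all(rep$rows$npv >= 0 & rep$rows$npv <= 1, na.rm = TRUE))
  expect_true(all(abs(rep$rows$corr) <= 1, na.rm = TRUE))
  if (!is.null(rep$regression)) {
    expect_true(rep$regression$r_squared >= 0 && rep$regression$r_squared <= 1)
  }
})
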