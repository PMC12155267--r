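test_that("spearman rho has the textbook monotone limits", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^3)$rho, 1)          # monotone transform
  expect_equal(spearman_rho(x, rev(x))$rho, -1)
  expect_error(spearman_rho(x, rep(1, 10)), "constant")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("spearman rho equals rank-then-Pearson on the clinical table", {
  tab <- flexicurve_table()
  got <- spearman_rho(tab$actual_angle_deg, tab$predicted_angle_deg)
  oracle <- stats::cor(rank(tab$actual_angle_deg),
                       rank(tab$predicted_angle_deg), method = "pearson")
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  # p from the t approximation, recomputed directly
  n <- nrow(tab)
  tstat <- oracle * sqrt((n - 2) / (1 - oracle^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
  base <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, base)
  expect_equal(spearman_rho(x, 3 * y - 100)$rho, base)
  expect_equal(spearman_rho(x, atan(y))$rho, base)
})

test_that("ICC forms behave on identical, shifted and hand-checked tables", {
  a <- c(20, 25, 30, 35, 40, 45)
  expect_equal(icc(cbind(a, a))$icc, 1)
  # constant offset: consistency ignores it, agreement penalizes it
  shifted <- icc(cbind(a, a + 5), form = "consistency")
  expect_equal(shifted$icc, 1)
  expect_lt(icc(cbind(a, a + 5), form = "agreement")$icc, 1)
  # 6-subject table vs independent aov mean-squares arithmetic
  set.seed(8)
  tab <- cbind(a, a + rnorm(6, 0, 3))
  got <- icc(tab, form = "agreement")
  expect_equal(got$icc, oracle_icc_agreement(tab), tolerance = 1e-10,
               ignore_attr = TRUE)
  # estimate inside its own CI
  expect_lte(got$ci_low, got$icc)
  expect_gte(got$ci_high, got$icc)
})

test_that("ICC confidence interval narrows with sample size", {
  set.seed(9)
  width <- sapply(c(20, 200), function(n) {
    truth <- rnorm(n, 32, 10)
    tab <- cbind(truth + rnorm(n, 0, 2), truth + rnorm(n, 0, 2))
    r <- icc(tab)
    r$ci_high - r$ci_low
  })
  expect_lt(width[2], width[1])
})

test_that("ICC rejects degenerate input", {
  expect_error(icc(cbind(rep(1, 5), rep(1, 5))), "degenerate")
  expect_error(icc(cbind(1:2, 2:1)), "at least 3")
})

test_that("cronbach alpha: identical items, closed form at k = 2, independent noise", {
  a <- c(10, 20, 30, 25, 15)
  expect_equal(cronbach_alpha(cbind(a, a)), 1)
  # two-item closed form 2 * (1 - (s1^2 + s2^2) / s_total^2)
  b <- a + c(1, -2, 0, 3, -1)
  tab <- cbind(a, b)
  closed <- 2 * (1 - (var(a) + var(b)) / var(a + b))
  expect_equal(cronbach_alpha(tab), closed, tolerance = 1e-12)
  # independent items: alpha near zero
  set.seed(14)
  noise <- cbind(rnorm(500), rnorm(500))
  expect_lt(abs(cronbach_alpha(noise)), 0.15)
  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))), "variance")
})

test_that("descriptives use the sample (n-1) standard deviation", {
  expect_equal(describe_values(c(20, 30, 40)), c(mean = 30, sd = 10))
  expect_equal(describe_values(rep(7, 5)), c(mean = 7, sd = 0))
  single <- describe_values(42)
  expect_equal(unname(single["mean"]), 42)
  expect_true(is.na(single["sd"]))
})

test_that("reliability recovery on a synthetic agreement cohort", {
  # two methods measuring the same truth with small independent errors:
  # both agreement statistics should be high
  set.seed(31)
  truth <- pmin(pmax(rnorm(125, 32, 10), 15), 55)
  m1 <- truth + rnorm(125, 0, 2)
  m2 <- truth + rnorm(125, 0, 2)
  rep <- reliability_report(m1, m2)
  expect_gt(rep$icc, 0.9)
  expect_gt(rep$cronbach_alpha, 0.9)
  expect_gt(rep$spearman_rho, 0.9)
  expect_true(rep$icc_ci_low <= rep$icc && rep$icc <= rep$icc_ci_high)
})
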