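test_that("overall variance matches its definition and a brute-force oracle", {
  # constant sample and hand arithmetic
  em <- tiny_expr(matrix(c(3, 3, 3, 0, 2, 1), 3, 2))
  v <- overall_variance(em)
  expect_equal(v$overall_variance[1], 0)
  em2 <- tiny_expr(matrix(c(0, 2), 2, 1))
  expect_error(overall_variance(tiny_expr(matrix(1, 1, 2))), "2 probes")
  expect_equal(overall_variance(tiny_expr(cbind(c(0, 2), c(0, 2))))$overall_variance,
               c(1, 1))

  # independent two-pass summation oracle on a random 1000-probe sample
  em3 <- rand_expr(1000, 3, seed = 20)
  got <- overall_variance(em3)$overall_variance
  oracle <- vapply(1:3, function(s) {
    x <- em3$values[, s]
    m <- 0
    for (xi in x) m <- m + xi
    m <- m / length(x)
    ss <- 0
    for (xi in x) ss <- ss + (xi - m)^2
    ss / length(x)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-10)

  # divisor flag
  expect_equal(overall_variance(em3, divisor = "sample")$overall_variance,
               unname(apply(em3$values, 2, var)))
  expect_error(overall_variance(tiny_expr(matrix(1:4, 2, 2), scale = "linear")),
               "log2")
})

test_that("overall variance is shift-invariant and scales quadratically", {
  em <- rand_expr(400, 4, seed = 21)
  v0 <- overall_variance(em)$overall_variance
  shifted <- expression_matrix(em$values + 7.3, "log2")
  expect_equal(overall_variance(shifted)$overall_variance, v0)
  scaled <- expression_matrix(em$values * 2.5, "log2")
  expect_equal(overall_variance(scaled)$overall_variance, v0 * 2.5^2)
})

test_that("standardization honours the reference set and divisor conventions", {
  z <- standardize(1:3, divisor = "population")
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2))
  z2 <- standardize(1:3)  # sample divisor
  expect_equal(mean(z2), 0)
  expect_equal(sd(z2), 1)
  expect_equal(standardize(2, reference = c(1, 2, 3)), 0)
  expect_error(standardize(1:3, reference = c(4, 4)), "zero")
  expect_error(standardize(1:3, reference = 4), ">= 2")
})

test_that("two-group comparison reproduces the pooled-t closed form", {
  res <- compare_groups(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  a <- c(0, 0, 1, 1); b <- c(1, 1, 2, 2)
  res2 <- compare_groups(c(a, b), rep(c("case", "ctrl"), each = 4), case = "case")
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res2$statistic, t_hand)
  expect_equal(res2$estimate, -1)
  expect_equal(res2$df, 6)

  # welch variant defers to the Welch test
  set.seed(2)
  x <- rnorm(10); y <- rnorm(14, 0, 3)
  res3 <- compare_groups(c(x, y), rep(c("g1", "g2"), c(10, 14)),
                         variant = "welch")
  ref <- t.test(x, y)
  expect_equal(res3$p_value, ref$p.value)
  expect_equal(res3$df, unname(ref$parameter))
  expect_error(compare_groups(1:4, rep("a", 4)), "two groups")
})

test_that("null cohorts reject at the nominal rate", {
  p <- vapply(1:400, function(i) {
    co <- simulate_cohort(sim_config(n_probes = 300, n_autism = 20,
                                     n_control = 16, seed = 3000 + i))
    ph <- overall_variance(co$expression)
    compare_groups(standardize(ph$overall_variance), co$metadata$diagnosis,
                   case = "autism")$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("effect-coded ANCOVA matches the normal-equations oracle", {
  md <- toy_metadata(3, 3)
  md$subject_age <- c(5, 6, 7, 8, 9, 10)
  md$scan_batch <- c(1, 2, 1, 2, 1, 2)
  y <- c(1.2, 0.8, 1.1, 2.0, 2.2, 1.9)
  fit <- variance_ancova(y, md, terms = c("diagnosis", "subject_age"),
                         interactions = FALSE)
  dx <- ifelse(md$diagnosis == "autism", -1, 1)
  X <- cbind(1, dx, md$subject_age)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  # an autism sample contributes -1 in the diagnosis column
  expect_identical(fit$coding$diagnosis, c(autism = -1, control = 1))
  # implied group difference = -2 * diagnosis coefficient
  expect_equal(fit$diagnosis_difference,
               -2 * fit$coefficients$estimate[fit$coefficients$term == "diagnosis"])
})

test_that("ANCOVA without covariates reduces to the two-group t-test", {
  set.seed(33)
  md <- toy_metadata(8, 8)
  y <- rnorm(16) + ifelse(md$diagnosis == "autism", -0.5, 0)
  fit <- variance_ancova(y, md, terms = "diagnosis")
  tt <- compare_groups(y, md$diagnosis, case = "autism")
  p_dx <- fit$coefficients$p_value[fit$coefficients$term == "diagnosis"]
  expect_equal(p_dx, tt$p_value, tolerance = 1e-12)
  expect_equal(fit$diagnosis_difference, tt$estimate, tolerance = 1e-12)
})

test_that("ANCOVA full-interaction model on balanced null data recovers nothing", {
  cfg <- sim_config(n_probes = 800, n_autism = 30, n_control = 30, seed = 77)
  co <- simulate_cohort(cfg)
  ph <- overall_variance(co$expression)
  fit <- variance_ancova(standardize(ph$overall_variance), co$metadata)
  est <- fit$coefficients$estimate[fit$coefficients$term == "diagnosis"]
  se <- fit$coefficients$std_error[fit$coefficients$term == "diagnosis"]
  expect_lt(abs(est), 3 * se)
  expect_length(fit$aliased, 0)
})

test_that("ANCOVA reports aliased terms on rank-deficient designs", {
  md <- toy_metadata(3, 3)
  md$scan_batch <- ifelse(md$diagnosis == "autism", 1, 2)  # batch == diagnosis
  expect_warning(
    fit <- variance_ancova(rnorm(6), md, terms = c("diagnosis", "scan_batch"),
                           interactions = FALSE),
    "aliased"
  )
  expect_gt(length(fit$aliased), 0)
})

test_that("Fisher-transform correlation inference matches the normal-tail oracle", {
  pr <- make_pair_with_cor(0.5, 30)
  res <- correlation_fisher(pr$x, pr$y)
  expect_equal(res$r, 0.5, tolerance = 1e-12)
  expect_equal(res$p_two_tailed, 2 * pnorm(-atanh(0.5) * sqrt(27)),
               tolerance = 1e-10)
  expect_equal(res$r_squared, res$r^2)

  pr0 <- make_pair_with_cor(0, 20)
  expect_equal(correlation_fisher(pr0$x, pr0$y)$p_two_tailed, 1,
               tolerance = 1e-10)
  expect_error(correlation_fisher(1:3, 1:3), ">= 4")
  expect_error(correlation_fisher(rep(1, 5), 1:5), "zero variance")
})

test_that("Fisher-transform p agrees with a permutation p on synthetic data", {
  pr <- make_pair_with_cor(0.35, 40, seed = 5)
  res <- correlation_fisher(pr$x, pr$y)
  set.seed(6)
  nperm <- 10000
  robs <- abs(cor(pr$x, pr$y))
  exceed <- vapply(seq_len(nperm), function(i) {
    abs(cor(pr$x, sample(pr$y))) >= robs
  }, logical(1))
  p_perm <- mean(exceed)
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(res$p_two_tailed - p_perm), 2 * se + 1e-4)
})

test_that("Spearman correlation reports plain and tie-corrected forms", {
  expect_equal(spearman_corr(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_corr(1:8, -(1:8))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5, 5, 7)
  y <- c(2, 1, 4, 4, 6, 8, 7, 9)
  res <- spearman_corr(x, y)
  # textbook tie-corrected formula: (A + B - sum d^2) / (2 sqrt(A B)),
  # A = (n^3 - n)/12 - sum(tx^3 - tx)/12 over tie groups (likewise B)
  n <- length(x)
  tie_term <- function(v) sum(table(v)^3 - table(v)) / 12
  A <- (n^3 - n) / 12 - tie_term(x)
  B <- (n^3 - n) / 12 - tie_term(y)
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(res$rho_tie_corrected, (A + B - d2) / (2 * sqrt(A * B)),
               tolerance = 1e-12)
  expect_equal(res$rho, 1 - 6 * d2 / (n * (n^2 - 1)))
  expect_error(spearman_corr(rep(2, 5), 1:5), "constant")
})

test_that("Shapiro-Wilk gate reproduces the reference W and flags skewness", {
  expect_error(shapiro_normality(c(1, 2)), "between 3 and 5000")
  # reference value computed with an independent implementation
  x <- c(2.1, 3.4, 1.9, 5.6, 4.4, 2.8, 3.9, 4.1, 2.2, 3.3)
  expect_equal(shapiro_normality(x)$statistic, 0.9525, tolerance = 5e-5)
  hits <- vapply(1:60, function(i) {
    set.seed(4000 + i)
    shapiro_normality(rexp(100))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("median split sends boundary values to the older group", {
  s <- median_split(c(25, 30, 32, 40))
  expect_equal(attr(s, "median"), 31)
  expect_identical(as.character(s), c("younger", "younger", "older", "older"))
  s2 <- median_split(c(28, 31, 34))
  expect_identical(as.character(s2)[2], "older")  # value == median
  expect_identical(unique(as.character(median_split(rep(31, 4)))), "older")
  expect_true(is.na(median_split(c(20, NA, 40))[2]))
  expect_error(median_split(c(NA_real_, NA_real_)), "missing")
})

test_that("planted contraction deficits are recovered in SD units", {
  cfg <- sim_config(n_probes = 1500)
  b <- dx_effect_for_sd_deficit(cfg, 0.45)
  ests <- vapply(1:40, function(i) {
    co <- simulate_cohort(sim_config(n_probes = 1500, dx_effect = b,
                                     seed = 6000 + i))
    ph <- overall_variance(co$expression)
    compare_groups(standardize(ph$overall_variance), co$metadata$diagnosis,
                   case = "autism")$estimate
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - (-0.45)), 3 * se)
})
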