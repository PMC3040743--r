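test_that("expected group variance matches its closed form", {
  cfg <- sim_config(probe_mean_scale = 2, residual_sd = 1)
  expect_equal(expected_group_variance(cfg, "control"), 5.0)
  cfg2 <- sim_config(probe_mean_scale = 2, residual_sd = 1, dx_effect = -0.1)
  expect_equal(expected_group_variance(cfg2, "autism"), 0.9^2 * 4 + 1)
  expect_equal(expected_group_variance(cfg2, "control"), 5.0)
  expect_error(expected_group_variance(cfg, "treated"), "unknown group")
})

test_that("a null configuration gives equal expected variance across groups", {
  cfg <- sim_config(dx_effect = 0, pa_effect = 0, regulator_coupling = 0)
  expect_equal(expected_group_variance(cfg, "autism"),
               expected_group_variance(cfg, "control"))
  co <- simulate_cohort(sim_config(n_probes = 2000, seed = 5))
  ph <- overall_variance(co$expression)
  means <- tapply(ph$overall_variance, co$metadata$diagnosis, mean)
  ses <- tapply(ph$overall_variance, co$metadata$diagnosis,
                function(v) sd(v) / sqrt(length(v)))
  expect_lt(abs(means["autism"] - means["control"]), 3 * sqrt(sum(ses^2)))
})

test_that("identical seeds reproduce cohorts bit-for-bit, different seeds differ", {
  cfg <- sim_config(n_probes = 300, n_autism = 8, n_control = 8, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 100
  c_ <- simulate_cohort(cfg2)
  expect_false(identical(a$expression$values, c_$expression$values))
})

test_that("non-positive contraction factors are rejected with the offending parameters", {
  cfg <- sim_config(n_probes = 100, n_autism = 4, n_control = 4,
                    dx_effect = -1.5, seed = 1)
  expect_error(simulate_cohort(cfg), "dx_effect=-1.5")
})

test_that("simulated cohort tables agree in shape and carry ground truth", {
  cfg <- sim_config(n_probes = 500, n_autism = 10, n_control = 8, seed = 2,
                    batch_effect_sd = 0.2)
  co <- simulate_cohort(cfg)
  expect_identical(dim(co$expression$values), dim(co$presence))
  expect_identical(sample_ids(co$expression), co$metadata$sample_id)
  expect_length(co$truth$lambda, 18)
  expect_true(all(co$truth$lambda > 0))
  expect_identical(names(co$truth$lambda), co$metadata$sample_id)
  # presence thresholding on the linear scale
  expect_identical(unname(co$presence),
                   unname(2^co$expression$values > cfg$presence_threshold))
})

test_that("Monte-Carlo mean of the variance phenotype converges to the analytic value", {
  # average over cohorts so the shared per-probe means are resampled too
  cfg0 <- sim_config(n_probes = 3000, n_autism = 12, n_control = 12,
                     dx_effect = -0.08, pa_effect = 0.02,
                     batch_effect_sd = 0.3)
  per_cohort <- vapply(1:25, function(i) {
    cfg <- cfg0; cfg$seed <- 500 + i
    co <- simulate_cohort(cfg)
    ph <- overall_variance(co$expression)
    tapply(ph$overall_variance, co$metadata$diagnosis, mean)[c("autism", "control")]
  }, numeric(2))
  for (grp in c("autism", "control")) {
    mc <- per_cohort[grp, ]
    se <- sd(mc) / sqrt(length(mc))
    expect_lt(abs(mean(mc) - expected_group_variance(cfg0, grp)), 3 * se)
  }
})

test_that("expected variance decreases monotonically with the contraction effect", {
  vals <- vapply(seq(0, -0.3, by = -0.05), function(b) {
    expected_group_variance(sim_config(dx_effect = b), "autism")
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("regulator coupling lowers both regulator expression and overall variance in cases", {
  base <- simulate_cohort(sim_config(n_probes = 2000, seed = 31,
                                     regulator_coupling = 0))
  coupled <- simulate_cohort(sim_config(n_probes = 2000, seed = 31,
                                        regulator_coupling = 0.3))
  aut <- coupled$metadata$diagnosis == "autism"
  reg <- coupled$truth$regulator_probes
  reg_means <- colMeans(coupled$expression$values[reg, ])
  expect_lt(mean(reg_means[aut]), mean(reg_means[!aut]) - 0.15)
  ph <- overall_variance(coupled$expression)$overall_variance
  expect_lt(mean(ph[aut]), mean(ph[!aut]))
  # and monotone in the coupling at the analytic level
  v <- vapply(c(0, 0.1, 0.2, 0.3), function(cc) {
    expected_group_variance(sim_config(regulator_coupling = cc), "autism")
  }, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("cohort-level present-call rate sits near the configured detection regime", {
  co <- simulate_cohort(sim_config(n_probes = 4000, seed = 8))
  expect_gt(mean(co$presence), 0.38)
  expect_lt(mean(co$presence), 0.50)
})

test_that("inhibitor experiments map conditions to contraction strengths", {
  cfg <- sim_config(n_probes = 1500, n_per_condition = 3,
                    inhibitor_contraction = 0.15, seed = 21)
  exp12 <- simulate_inhibitor_experiment(cfg)
  expect_identical(ncol(exp12$expression$values), 12L)
  expect_identical(table(exp12$metadata$condition)[["mannitol"]], 3L)
  # closed form: reduced conditions have strictly lower expected variance
  ev <- exp12$truth$expected_variance
  expect_lt(ev[["sapphyrin_high"]], ev[["mannitol"]])
  expect_lt(ev[["actinomycin_d"]], ev[["sapphyrin_low"]])
  expect_equal(ev[["sapphyrin_high"]], (1 - 0.15)^2 * 4 + 1)
  # observed variances follow the planted ordering
  ph <- overall_variance(exp12$expression)
  mm <- tapply(ph$overall_variance, exp12$metadata$condition, mean)
  expect_lt(mm[["sapphyrin_high"]], mm[["mannitol"]])

  # null mapping: equal contraction everywhere
  cfg0 <- sim_config(inhibitor_contraction = 0)
  ev0 <- vapply(cfg0$conditions, function(cc) expected_group_variance(cfg0, cc),
                numeric(1))
  expect_true(all(ev0 == ev0[1]))

  expect_error(
    simulate_inhibitor_experiment(sim_config(n_per_condition = 1)),
    "n_per_condition"
  )
})

test_that("the contraction-to-deficit helper plants the requested effect size", {
  cfg <- sim_config(n_probes = 1000)
  b <- dx_effect_for_sd_deficit(cfg, 0.45)
  expect_lt(b, 0)
  cfg$dx_effect <- b
  deficit <- expected_group_variance(cfg, "control") -
    expected_group_variance(cfg, "autism")
  expect_equal(deficit / expected_phenotype_sd(cfg, "control"), 0.45,
               tolerance = 1e-8)
})
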