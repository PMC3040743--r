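# Synthetic cohort generator. The generative model produces a pure change in
# the variance of each sample's log2 expression distribution while leaving the
# grand mean unchanged:
#
#   x_gs = m + lambda_s * (mu_g - delta_s * reg_g - m + b_{g, batch(s)}) + eps_gs
#
# with per-probe baseline means mu_g ~ N(location, scale), residual noise
# eps ~ N(0, sigma), probe-by-batch offsets b ~ N(0, batch_effect_sd), and a
# per-sample contraction factor
#
#   lambda_s = (lambda0 + beta_dx * I(autism_s) + beta_pa * z(paternal_age_s))
#              * (1 - coupling * I(autism_s)).
#
# Regulator probes (flag reg_g) are additionally shifted down by
# delta_s = coupling log2 units in affected samples, so one coupling parameter
# yields both a down-regulated regulator signature and a contracted
# distribution. Closed form: E[variance_s] = E[lambda_s^2] * S + sigma^2 with
# S = scale^2 + f(1-f) delta^2 + batch_sd^2.

#' Simulation configuration
#'
#' Full generative description of a synthetic two-group microarray cohort
#' (and of the four-condition transcription-inhibitor experiment). Defaults
#' describe a null cohort shaped like a two-batch, 82 affected / 64 control
#' blood study on ~log-normal probe intensities with ~44% present calls.
#'
#' @param n_probes number of probes per array.
#' @param n_autism,n_control samples per cohort arm (each >= 2).
#' @param probe_mean_location,probe_mean_scale location/scale of the per-probe
#'   baseline log2 means `mu_g`.
#' @param residual_sd per-observation noise SD (log2 units).
#' @param baseline_contraction baseline contraction factor `lambda0`
#'   (unitless; 1 = no compression of the distribution).
#' @param dx_effect additive shift of `lambda` for the affected (autism)
#'   group; negative values compress the affected distribution.
#' @param pa_effect additive shift of `lambda` per standardized year of
#'   paternal age.
#' @param batch_effect_sd SD of probe-by-scan-batch offsets (log2 units).
#' @param regulator_fraction fraction of probes tagged as transcriptional
#'   regulators, in `[0, 1]`.
#' @param regulator_coupling coupling `c` of regulator downregulation to the
#'   contraction: affected samples have regulator probes shifted down by `c`
#'   log2 units and `lambda` multiplied by `1 - c`.
#' @param presence_threshold linear-scale intensity cut-off for present calls.
#' @param presence_flip_prob probability of flipping a present call
#'   (measurement noise in the detection algorithm).
#' @param paternal_age_mean,paternal_age_sd,paternal_age_range parameters of
#'   the truncated-normal paternal age distribution (years; rounded to
#'   integers).
#' @param missing_paternal_age named per-group fractions of samples with
#'   unrecorded paternal age.
#' @param subject_age_mean,subject_age_sd named per-group subject-age
#'   parameters (years).
#' @param n_batches number of scan batches; samples are balanced across
#'   batches within each group.
#' @param conditions labels for the inhibitor experiment.
#' @param reduced_conditions conditions whose contraction is reduced below
#'   `baseline_contraction`.
#' @param n_per_condition samples per inhibitor condition (>= 2).
#' @param inhibitor_contraction amount subtracted from `lambda0` for the
#'   `reduced_conditions`.
#' @param seed integer master seed; identical seeds give bit-identical
#'   cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 5000,
                       n_autism = 82,
                       n_control = 64,
                       probe_mean_location = 6,
                       probe_mean_scale = 2,
                       residual_sd = 1,
                       baseline_contraction = 1,
                       dx_effect = 0,
                       pa_effect = 0,
                       batch_effect_sd = 0,
                       regulator_fraction = 0.05,
                       regulator_coupling = 0,
                       presence_threshold = 82,
                       presence_flip_prob = 0,
                       paternal_age_mean = 31,
                       paternal_age_sd = 5,
                       paternal_age_range = c(18, 55),
                       missing_paternal_age = c(autism = 4 / 82, control = 7 / 64),
                       subject_age_mean = c(autism = 5.5, control = 7.9),
                       subject_age_sd = c(autism = 2.1, control = 2.2),
                       n_batches = 2,
                       conditions = c("mannitol", "sapphyrin_low",
                                      "sapphyrin_high", "actinomycin_d"),
                       reduced_conditions = c("sapphyrin_high", "actinomycin_d"),
                       n_per_condition = 3,
                       inhibitor_contraction = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_probes < 2) stop("n_probes must be >= 2")
  if (cfg$n_autism < 2 || cfg$n_control < 2) stop("group sizes must be >= 2")
  if (cfg$regulator_fraction < 0 || cfg$regulator_fraction > 1) {
    stop("regulator_fraction must be in [0, 1]")
  }
  if (cfg$residual_sd < 0 || cfg$probe_mean_scale < 0 || cfg$batch_effect_sd < 0) {
    stop("scale parameters must be non-negative")
  }
  if (!all(cfg$reduced_conditions %in% cfg$conditions)) {
    stop("reduced_conditions must be a subset of conditions")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d probes; %d autism / %d control; lambda0=%g dx=%g pa=%g coupling=%g; seed=%d\n",
    x$n_probes, x$n_autism, x$n_control, x$baseline_contraction,
    x$dx_effect, x$pa_effect, x$regulator_coupling, as.integer(x$seed)
  ))
  invisible(x)
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

.check_lambda <- function(lambda, cfg) {
  if (any(lambda <= 0)) {
    stop(sprintf(
      paste0("non-positive contraction factor lambda (min %.4g) for ",
             "baseline_contraction=%g, dx_effect=%g, pa_effect=%g, ",
             "regulator_coupling=%g"),
      min(lambda), cfg$baseline_contraction, cfg$dx_effect, cfg$pa_effect,
      cfg$regulator_coupling
    ))
  }
  invisible(lambda)
}

# Core matrix builder shared by cohort and inhibitor simulations.
.simulate_expression <- function(cfg, lambda, reg_shift, batch_of) {
  g <- cfg$n_probes
  n <- length(lambda)
  mu <- stats::rnorm(g, cfg$probe_mean_location, cfg$probe_mean_scale)
  reg <- rep(FALSE, g)
  n_reg <- round(cfg$regulator_fraction * g)
  if (n_reg > 0) reg[sample.int(g, n_reg)] <- TRUE
  b <- matrix(0, g, cfg$n_batches)
  if (cfg$batch_effect_sd > 0) {
    b[] <- stats::rnorm(g * cfg$n_batches, 0, cfg$batch_effect_sd)
  }
  m <- cfg$probe_mean_location
  x <- matrix(stats::rnorm(g * n, 0, cfg$residual_sd), g, n)
  for (s in seq_len(n)) {
    dev <- mu - reg_shift[s] * reg - m + b[, batch_of[s]]
    x[, s] <- m + lambda[s] * dev + x[, s]
  }
  list(x = x, mu = mu, regulator = reg)
}

.presence_calls <- function(cfg, x) {
  calls <- 2^x > cfg$presence_threshold
  if (cfg$presence_flip_prob > 0) {
    flip <- matrix(stats::runif(length(x)) < cfg$presence_flip_prob,
                   nrow(x), ncol(x))
    calls <- xor(calls, flip)
  }
  calls
}

#' Simulate a two-group microarray cohort
#'
#' Draws a cohort under the global-contraction model (see [sim_config()]):
#' each sample's log2 expression distribution is compressed toward the grand
#' mean by its contraction factor `lambda_s`, which depends on diagnosis,
#' standardized paternal age, and the regulator-coupling mechanism. Ground
#' truth (`lambda_s` per sample, the analytic expected variance per group,
#' and the planted regulator probe set) is recorded alongside the data.
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   (log2-scale [expression_matrix()]), `presence` (logical matrix),
#'   `metadata` (data.frame), and `truth` (per-sample lambda, per-group
#'   expected variance, regulator probe ids).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(as.integer(cfg$seed))
  n <- cfg$n_autism + cfg$n_control
  dx <- c(rep("autism", cfg$n_autism), rep("control", cfg$n_control))
  ids <- sprintf("S%03d", seq_len(n))
  batch <- unlist(lapply(c(cfg$n_autism, cfg$n_control), function(k) {
    rep_len(seq_len(cfg$n_batches), k)
  }), use.names = FALSE)

  subject_age <- round(pmax(2, stats::rnorm(
    n, cfg$subject_age_mean[dx], cfg$subject_age_sd[dx]
  )), 1)
  pa <- round(.rtruncnorm(n, cfg$paternal_age_mean, cfg$paternal_age_sd,
                          cfg$paternal_age_range[1], cfg$paternal_age_range[2]))
  for (grp in c("autism", "control")) {
    idx <- which(dx == grp)
    k <- round(cfg$missing_paternal_age[[grp]] * length(idx))
    if (k > 0) pa[sample(idx, k)] <- NA
  }
  z <- rep(0, n)
  if (sum(!is.na(pa)) >= 2 && stats::sd(pa, na.rm = TRUE) > 0) {
    z[!is.na(pa)] <- (pa[!is.na(pa)] - mean(pa, na.rm = TRUE)) /
      stats::sd(pa, na.rm = TRUE)
  }

  is_aut <- dx == "autism"
  lambda <- (cfg$baseline_contraction + cfg$dx_effect * is_aut +
               cfg$pa_effect * z) * (1 - cfg$regulator_coupling * is_aut)
  .check_lambda(lambda, cfg)

  sim <- .simulate_expression(cfg, lambda,
                              reg_shift = cfg$regulator_coupling * is_aut,
                              batch_of = batch)
  dimnames(sim$x) <- list(sprintf("probe_%05d", seq_len(cfg$n_probes)), ids)

  metadata <- data.frame(
    sample_id = ids, diagnosis = dx, subject_age = subject_age,
    paternal_age = pa, scan_batch = batch, stringsAsFactors = FALSE
  )
  truth <- list(
    lambda = stats::setNames(lambda, ids),
    expected_variance = c(
      autism = expected_group_variance(cfg, "autism"),
      control = expected_group_variance(cfg, "control")
    ),
    regulator_probes = rownames(sim$x)[sim$regulator]
  )
  structure(list(
    expression = expression_matrix(sim$x, "log2"),
    presence = .presence_calls(cfg, sim$x),
    metadata = metadata,
    truth = truth
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d probes x %d samples\n",
              nrow(x$expression$values), ncol(x$expression$values)))
  invisible(x)
}

#' Simulate a transcription-inhibitor experiment
#'
#' Four treatment conditions, `n_per_condition` arrays each. Control and
#' low-dose conditions keep the baseline contraction `lambda0`; conditions in
#' `reduced_conditions` (by default the high-dose inhibitors) have `lambda0`
#' reduced by `inhibitor_contraction`, compressing their expression
#' distributions.
#'
#' @param config a [sim_config()].
#' @return A `synthetic_cohort` whose metadata carries a `condition` column.
#' @export
simulate_inhibitor_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_per_condition < 2) {
    stop("n_per_condition must be >= 2 (variance comparison undefined otherwise)")
  }
  set.seed(as.integer(cfg$seed))
  cond <- rep(cfg$conditions, each = cfg$n_per_condition)
  n <- length(cond)
  ids <- sprintf("T%03d", seq_len(n))
  lam_by_cond <- stats::setNames(
    ifelse(cfg$conditions %in% cfg$reduced_conditions,
           cfg$baseline_contraction - cfg$inhibitor_contraction,
           cfg$baseline_contraction),
    cfg$conditions
  )
  lambda <- lam_by_cond[cond]
  .check_lambda(lambda, cfg)

  sim <- .simulate_expression(cfg, lambda, reg_shift = rep(0, n),
                              batch_of = rep(1L, n))
  dimnames(sim$x) <- list(sprintf("probe_%05d", seq_len(cfg$n_probes)), ids)
  metadata <- data.frame(
    sample_id = ids, diagnosis = NA_character_, subject_age = NA_real_,
    paternal_age = NA_real_, scan_batch = 1L, condition = cond,
    stringsAsFactors = FALSE
  )
  truth <- list(
    lambda = stats::setNames(unname(lambda), ids),
    expected_variance = vapply(cfg$conditions, function(cc)
      expected_group_variance(cfg, cc), numeric(1)),
    regulator_probes = rownames(sim$x)[sim$regulator]
  )
  structure(list(
    expression = expression_matrix(sim$x, "log2"),
    presence = .presence_calls(cfg, sim$x),
    metadata = metadata,
    truth = truth
  ), class = "synthetic_cohort")
}

# Per-group mean and variance of lambda, and the probe-level spread S.
.lambda_moments <- function(cfg, group) {
  if (group %in% c("autism", "control")) {
    is_aut <- group == "autism"
    mult <- 1 - cfg$regulator_coupling * is_aut
    lam_mean <- (cfg$baseline_contraction + cfg$dx_effect * is_aut) * mult
    # standardized paternal age has unit variance within group (both arms
    # share the age distribution), so Var(lambda) = (pa_effect * mult)^2
    lam_var <- (cfg$pa_effect * mult)^2
    shift <- cfg$regulator_coupling * is_aut
  } else if (group %in% cfg$conditions) {
    lam_mean <- if (group %in% cfg$reduced_conditions) {
      cfg$baseline_contraction - cfg$inhibitor_contraction
    } else {
      cfg$baseline_contraction
    }
    lam_var <- 0
    shift <- 0
  } else {
    stop(sprintf("unknown group label '%s'", group))
  }
  f <- cfg$regulator_fraction
  s2 <- cfg$probe_mean_scale^2 + f * (1 - f) * shift^2 + cfg$batch_effect_sd^2
  list(mean = lam_mean, var = lam_var, s2 = s2)
}

#' Analytic expected overall variance for a simulated group
#'
#' The closed-form expectation of the per-sample overall variance of log2
#' values under the contraction model:
#' `E[lambda^2] * (Var(mu) + f(1-f) shift^2 + batch_sd^2) + sigma^2`.
#' Serves as the oracle for Monte-Carlo recovery tests.
#'
#' @param config a [sim_config()].
#' @param group `"autism"`, `"control"`, or an inhibitor condition label.
#' @return Expected overall variance (squared log2 units).
#' @examples
#' cfg <- sim_config(probe_mean_scale = 2, residual_sd = 1)
#' expected_group_variance(cfg, "control")  # 1 * 4 + 1 = 5
#' @export
expected_group_variance <- function(config, group) {
  stopifnot(inherits(config, "sim_config"))
  mo <- .lambda_moments(config, group)
  (mo$mean^2 + mo$var) * mo$s2 + config$residual_sd^2
}

#' Analytic within-group SD of the variance phenotype
#'
#' Combines the finite-probe sampling noise of the per-sample variance with
#' the between-sample spread induced by paternal-age-dependent contraction:
#' `Var(V) = (4 lam^2 S sigma^2 + 2 sigma^4) / G + (4 lam^2 tau^2 + 2 tau^4) S^2`
#' for `lambda ~ N(lam, tau^2)`.
#'
#' @inheritParams expected_group_variance
#' @return SD of the per-sample overall variance within the group.
#' @export
expected_phenotype_sd <- function(config, group) {
  stopifnot(inherits(config, "sim_config"))
  mo <- .lambda_moments(config, group)
  s2 <- mo$s2
  sig2 <- config$residual_sd^2
  meas <- (4 * (mo$mean^2 + mo$var) * s2 * sig2 + 2 * sig2^2) / config$n_probes
  betw <- (4 * mo$mean^2 * mo$var + 2 * mo$var^2) * s2^2
  sqrt(meas + betw)
}

#' Diagnosis effect planting a target deficit in SD units
#'
#' Returns the `dx_effect` value for which the affected group's expected
#' overall variance sits `sd_units` within-group phenotype SDs below the
#' control group's, under an otherwise-null configuration. Used to simulate
#' cohorts with a known standardized effect size for power studies.
#'
#' @param config a [sim_config()] (its `dx_effect` is ignored).
#' @param sd_units target deficit in within-group SD units (positive number;
#'   affected group lower).
#' @return The (negative) `dx_effect` to plug into the configuration.
#' @export
dx_effect_for_sd_deficit <- function(config, sd_units = 0.45) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$dx_effect <- 0
  mo <- .lambda_moments(cfg, "control")
  sd_v <- expected_phenotype_sd(cfg, "control")
  target <- mo$mean^2 - sd_units * sd_v / mo$s2
  if (target <= 0) {
    stop("requested deficit implies a non-positive contraction factor")
  }
  sqrt(target) - mo$mean
}
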