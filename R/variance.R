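# The variance phenotype: one scalar per array, the variance of all log2
# expression values in that array's distribution, plus every statistical test
# applied to it.

#' Per-sample overall variance of the log2 expression distribution
#'
#' For each sample `s`, `V_s = (1/G) * sum_g (x_gs - mean_s)^2` over all `G`
#' probes — the average of the squared deviations from the sample mean
#' (population divisor by default; the `n-1` divisor is available and is
#' negligibly different at array scale). Computed on the full,
#' non-normalized probe set: no present-call filtering is applied to this
#' branch.
#'
#' @param x a log2-scale [expression_matrix()] with at least 2 probes.
#' @param divisor `"population"` (divide by `G`, the definitional form) or
#'   `"sample"` (divide by `G - 1`).
#' @return data.frame with columns `sample_id` and `overall_variance`.
#' @examples
#' m <- matrix(c(0, 2, 1, 3), 2, 2, dimnames = list(c("p1", "p2"), c("a", "b")))
#' overall_variance(expression_matrix(m, "log2"))  # both samples: 1
#' @export
overall_variance <- function(x, divisor = c("population", "sample")) {
  stopifnot(inherits(x, "expr_matrix"))
  divisor <- match.arg(divisor)
  if (x$scale != "log2") {
    stop("overall_variance is defined on log2-scale data; run log2_transform first")
  }
  v <- x$values
  g <- nrow(v)
  if (g < 2) stop("overall_variance needs at least 2 probes")
  centered <- v - rep(colMeans(v), each = g)
  denom <- if (divisor == "population") g else g - 1
  data.frame(
    sample_id = colnames(v),
    overall_variance = colSums(centered^2) / denom,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Standardize values against a reference set
#'
#' `z = (v - mean(reference)) / sd(reference)`. Used to express the variance
#' phenotype (and effect estimates derived from it) in SD units of a declared
#' reference population — by default the full analyzed sample set.
#'
#' @param values numeric vector to standardize.
#' @param reference numeric vector defining the mean/SD (>= 2 values,
#'   non-zero SD); defaults to `values` itself.
#' @param divisor `"sample"` (n-1, default) or `"population"` (n) SD.
#' @return Numeric vector of standardized values.
#' @export
standardize <- function(values, reference = values,
                        divisor = c("sample", "population")) {
  divisor <- match.arg(divisor)
  reference <- reference[!is.na(reference)]
  if (length(reference) < 2) stop("reference set needs >= 2 values")
  m <- mean(reference)
  s <- stats::sd(reference)
  if (divisor == "population") {
    s <- s * sqrt((length(reference) - 1) / length(reference))
  }
  if (!is.finite(s) || s == 0) stop("reference SD is zero; cannot standardize")
  (values - m) / s
}

#' Two-group comparison of the variance phenotype
#'
#' Unpaired two-sample t-test (Student pooled-variance by default, Welch by
#' flag). The estimate is the difference of group means, `case - reference`;
#' pass standardized values to report it in SD units.
#'
#' @param values numeric phenotype vector.
#' @param labels group labels, exactly two distinct values.
#' @param case label of the case group (default: first distinct label).
#' @param variant `"student"` or `"welch"`.
#' @return List of class `gexvar_test`: `statistic`, `df`, `p_value`,
#'   `estimate` (case minus reference mean), `estimate_units`, `method`.
#' @export
compare_groups <- function(values, labels, case = NULL,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels)[keep]
  lv <- unique(labels)
  if (length(lv) != 2) stop("compare_groups needs exactly two groups")
  if (is.null(case)) case <- lv[1]
  if (!case %in% lv) stop(sprintf("case label '%s' not present", case))
  ref <- setdiff(lv, case)
  a <- values[labels == case]
  b <- values[labels == ref]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  tt <- stats::t.test(a, b, var.equal = variant == "student")
  structure(list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    estimate = mean(a) - mean(b),
    estimate_units = sprintf("difference of means (%s - %s)", case, ref),
    n = c(length(a), length(b)),
    method = sprintf("unpaired t-test (%s)", variant)
  ), class = "gexvar_test")
}

#' @export
print.gexvar_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  if (!is.null(x$estimate)) {
    cat(sprintf("  estimate = %.4g [%s]\n", x$estimate, x$estimate_units))
  }
  invisible(x)
}

#' Effect-coded ANCOVA on the variance phenotype
#'
#' Ordinary least squares with diagnosis coded `-1 = autism, +1 = control`
#' and scan batch coded `-1 = batch 1, +1 = batch 2`; subject age enters as
#' a continuous covariate. All interaction terms among the requested terms
#' are included by default. Per-term p-values are two-tailed Wald t-tests on
#' the OLS coefficients. With effect coding the implied autism-minus-control
#' group difference equals `-2` times the diagnosis coefficient; pass a
#' standardized phenotype to obtain it in SD units.
#'
#' @param values numeric phenotype vector, aligned with `metadata` rows.
#' @param metadata validated metadata data.frame.
#' @param terms model terms, a subset of
#'   `c("diagnosis", "subject_age", "scan_batch")`.
#' @param interactions include all interaction terms (default `TRUE`).
#' @return List of class `gexvar_ancova`: `coefficients` (term, estimate,
#'   std_error, t, p_value), `coding` map, `diagnosis_difference` (implied
#'   autism - control difference, when diagnosis is in the model),
#'   `aliased` (names of rank-deficient terms, if any), and the `fit`.
#' @export
variance_ancova <- function(values, metadata,
                            terms = c("diagnosis", "subject_age", "scan_batch"),
                            interactions = TRUE) {
  terms <- match.arg(terms, several.ok = TRUE)
  metadata <- validate_metadata(metadata)
  if (length(values) != nrow(metadata)) {
    stop("`values` and `metadata` must have the same length")
  }
  batches <- sort(unique(metadata$scan_batch))
  df <- data.frame(y = values)
  coding <- list()
  if ("diagnosis" %in% terms) {
    df$diagnosis <- ifelse(metadata$diagnosis == "autism", -1, 1)
    coding$diagnosis <- c(autism = -1, control = 1)
  }
  if ("subject_age" %in% terms) df$subject_age <- metadata$subject_age
  if ("scan_batch" %in% terms) {
    if (length(batches) != 2) stop("scan_batch coding requires exactly 2 batches")
    df$scan_batch <- ifelse(metadata$scan_batch == batches[1], -1, 1)
    coding$scan_batch <- stats::setNames(c(-1, 1), paste0("batch", batches))
  }
  rhs <- paste(terms, collapse = if (interactions) " * " else " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df)
  sm <- summary(fit)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    warning("rank-deficient design; aliased term(s): ",
            paste(aliased, collapse = ", "))
  }
  co <- sm$coefficients
  coefs <- data.frame(
    term = rownames(co), estimate = co[, 1], std_error = co[, 2],
    t = co[, 3], p_value = co[, 4], row.names = NULL,
    stringsAsFactors = FALSE
  )
  dx_diff <- if ("diagnosis" %in% coefs$term) {
    # autism (-1) minus control (+1) difference in fitted means
    -2 * coefs$estimate[coefs$term == "diagnosis"]
  } else {
    NULL
  }
  structure(list(coefficients = coefs, coding = coding,
                 diagnosis_difference = dx_diff, aliased = aliased,
                 fit = fit), class = "gexvar_ancova")
}

#' @export
print.gexvar_ancova <- function(x, ...) {
  cat("Effect-coded ANCOVA (OLS)\n")
  print(x$coefficients, digits = 4)
  if (!is.null(x$diagnosis_difference)) {
    cat(sprintf("implied autism - control difference: %.4g\n",
                x$diagnosis_difference))
  }
  invisible(x)
}

#' Pearson correlation with Fisher-transform inference
#'
#' Pearson's `r` with a two-tailed p-value from the Fisher z-transform:
#' `z = atanh(r) * sqrt(n - 3)` referred to the standard normal. Pairs with
#' a missing value in either vector are dropped.
#'
#' @param x,y paired numeric vectors (>= 4 complete pairs).
#' @return List of class `gexvar_cor`: `r`, `r_squared`, `n`, `p_two_tailed`.
#' @examples
#' # the slope of a noisy negative trend
#' set.seed(1)
#' a <- rnorm(30); b <- -0.5 * a + rnorm(30)
#' correlation_fisher(a, b)
#' @export
correlation_fisher <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("correlation_fisher needs >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input; correlation undefined")
  }
  r <- stats::cor(x, y)
  z <- atanh(r) * sqrt(n - 3)
  structure(list(
    r = r, r_squared = r^2, n = n,
    p_two_tailed = 2 * stats::pnorm(-abs(z)),
    method = "pearson (Fisher z)"
  ), class = "gexvar_cor")
}

#' @export
print.gexvar_cor <- function(x, ...) {
  if (!is.null(x$r)) {
    cat(sprintf("%s: r = %.4g, R^2 = %.4g, n = %d, p = %.4g\n",
                x$method, x$r, x$r_squared, x$n, x$p_two_tailed))
  } else {
    cat(sprintf(
      "%s: rho = %.4g (p = %.4g), tie-corrected rho = %.4g (p = %.4g), n = %d\n",
      x$method, x$rho, x$p_two_tailed, x$rho_tie_corrected,
      x$p_tie_corrected, x$n
    ))
  }
  invisible(x)
}

#' Spearman rank correlation, plain and tie-corrected
#'
#' The plain statistic is the classical `1 - 6 * sum(d^2) / (n (n^2 - 1))`
#' on mid-ranks; the tie-corrected statistic is the Pearson correlation of
#' the mid-ranks (equivalent to the textbook tie-term formula). Both are
#' reported, each with a two-tailed p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y paired numeric vectors (>= 4 complete pairs, non-constant).
#' @return List of class `gexvar_cor` with `rho`, `rho_tie_corrected`, `n`,
#'   `p_two_tailed`, `p_tie_corrected`.
#' @export
spearman_corr <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("spearman_corr needs >= 4 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant input vector; rank correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho_plain <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  rho_tie <- stats::cor(rx, ry)
  p_of <- function(rho) {
    if (abs(rho) >= 1) return(0)
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  structure(list(
    rho = rho_plain, rho_tie_corrected = rho_tie, n = n,
    p_two_tailed = p_of(rho_plain), p_tie_corrected = p_of(rho_tie),
    method = "spearman"
  ), class = "gexvar_cor")
}

#' Shapiro-Wilk normality test
#'
#' Gates the choice between parametric and rank-based reporting for each
#' experimental group: groups with evidence of non-normality are also
#' reported with non-parametric statistics.
#'
#' @param values numeric vector, 3 to 5000 non-missing values.
#' @return List of class `gexvar_test` with the `W` statistic and p-value.
#' @export
shapiro_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    stop("shapiro_normality requires between 3 and 5000 values")
  }
  sw <- stats::shapiro.test(values)
  structure(list(
    statistic = unname(sw$statistic), df = NA_real_, p_value = sw$p.value,
    estimate = NULL, estimate_units = NULL, n = length(values),
    method = "Shapiro-Wilk"
  ), class = "gexvar_test")
}

#' Median split of a continuous covariate
#'
#' Dichotomizes at the median of the non-missing values; values at or above
#' the median are labelled `"older"` (the boundary value belongs to the
#' older group), values below `"younger"`. Missing values get `NA`.
#'
#' @param values numeric vector (e.g. paternal age in years).
#' @return Factor with levels `younger`, `older`, plus the split point in
#'   the `median` attribute.
#' @examples
#' median_split(c(25, 30, 32, 40))  # median 31: younger, younger, older, older
#' @export
median_split <- function(values) {
  if (all(is.na(values))) stop("median_split: all values are missing")
  med <- stats::median(values, na.rm = TRUE)
  out <- factor(ifelse(values >= med, "older", "younger"),
                levels = c("younger", "older"))
  attr(out, "median") <- med
  out
}
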