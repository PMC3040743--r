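# Per-probe two-group differential expression on quantile-normalized log2
# data, with raw-p and fold-change thresholds producing directional gene
# lists. The row-wise t statistics are vectorized in-package; they agree with
# stats::t.test per probe (checked in the test suite).

.row_t <- function(xa, xb, variant) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  d <- ma - mb
  if (variant == "student") {
    df <- rep(na + nb - 2, length(d))
    se2 <- ((na - 1) * va + (nb - 1) * vb) / df * (1 / na + 1 / nb)
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, Inf * sign(d)))
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df),
              ifelse(tstat == 0, 1, 0))
  p[se2 == 0 & d == 0] <- 1
  list(t = tstat, df = df, p = p, mean_a = ma, mean_b = mb)
}

#' Per-probe differential expression table
#'
#' For every background probe: group means of log2 expression, their
#' difference (`delta_log2 = case - reference`), the linear fold change
#' `2^|delta_log2|` with a direction field, a two-tailed t-test p-value, and
#' the pass flag `p < p_threshold & fold_change >= fc_threshold` (raw p by
#' default; Benjamini-Hochberg adjustment behind the `adjust` flag).
#'
#' @param x a log2-scale [expression_matrix()], typically quantile-normalized.
#' @param labels per-sample group labels (two groups, each n >= 2).
#' @param case label of the case group; direction is defined relative to it
#'   (`"down"` = lower in the case group).
#' @param background probe ids to test (default: all probes); must all be
#'   present in the matrix.
#' @param variant `"student"` (pooled, default) or `"welch"`.
#' @param p_threshold significance cut-off on the (possibly adjusted) p-value.
#' @param fc_threshold fold-change cut-off, inclusive ("at least").
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per background probe: `probe_id`,
#'   `mean_case`, `mean_ref`, `delta_log2`, `fold_change`, `direction`,
#'   `p_value` (plus `p_adjusted` when `adjust = "BH"`), `passes`.
#' @export
de_table <- function(x, labels, case = NULL, background = NULL,
                     variant = c("student", "welch"),
                     p_threshold = 0.05, fc_threshold = 1.1,
                     adjust = c("none", "BH")) {
  stopifnot(inherits(x, "expr_matrix"))
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  labels <- as.character(labels)
  if (length(labels) != ncol(x$values)) {
    stop("`labels` must have one entry per sample")
  }
  lv <- unique(labels[!is.na(labels)])
  if (length(lv) != 2) stop("de_table needs exactly two groups")
  if (is.null(case)) case <- lv[1]
  if (!case %in% lv) stop(sprintf("case label '%s' not present", case))
  ref <- setdiff(lv, case)

  v <- x$values
  if (is.null(background)) background <- rownames(v)
  missing_probes <- setdiff(background, rownames(v))
  if (length(missing_probes)) {
    stop("background probe(s) missing from matrix: ",
         paste(utils::head(missing_probes, 5), collapse = ", "))
  }
  v <- v[background, , drop = FALSE]
  xa <- v[, labels %in% case, drop = FALSE]
  xb <- v[, labels %in% ref, drop = FALSE]
  if (ncol(xa) < 2 || ncol(xb) < 2) stop("each group needs >= 2 samples")

  rt <- .row_t(xa, xb, variant)
  delta <- rt$mean_a - rt$mean_b
  fc <- 2^abs(delta)
  p_eff <- if (adjust == "BH") stats::p.adjust(rt$p, "BH") else rt$p
  out <- data.frame(
    probe_id = background,
    mean_case = rt$mean_a, mean_ref = rt$mean_b,
    delta_log2 = delta, fold_change = fc,
    direction = ifelse(delta < 0, "down", ifelse(delta > 0, "up", "none")),
    p_value = rt$p,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (adjust == "BH") out$p_adjusted <- p_eff
  out$passes <- p_eff < p_threshold & fc >= fc_threshold
  attr(out, "case") <- case
  attr(out, "reference") <- ref
  out
}

#' Directional significant gene lists
#'
#' @param records a [de_table()] result.
#' @param direction `"down"` (lower in the case group) or `"up"`.
#' @return Character vector of passing probe ids with the given direction.
#' @export
significant_sets <- function(records, direction = c("down", "up")) {
  direction <- match.arg(direction)
  records$probe_id[records$passes & records$direction == direction]
}
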