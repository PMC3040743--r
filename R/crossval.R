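# Within-study replication: split each experimental group in half, balanced
# on paternal age and scan batch, and rerun the analyses on the halves.

#' Covariate-balanced half-split of a sample group
#'
#' Within each scan-batch stratum, samples are sorted by paternal age and
#' assigned to the two halves in a serpentine pattern (A, B, B, A, ...), a
#' deterministic rule that balances both the age means and the batch
#' composition of the halves. When a stratum has an odd size, its mid-ranked
#' sample is set aside into the currently smaller half before the serpentine
#' runs (a singleton stratum therefore joins the smaller half, with a
#' warning); taking the leftover from the centre of the age ranking keeps
#' the half means close. The seed is used only to break exact-age ties;
#' without it, ties keep their input order.
#'
#' @param metadata metadata rows for one group (>= 4 samples with
#'   non-missing balance variables; rows with missing values are dropped
#'   with a warning).
#' @param age_col,batch_col names of the balance columns.
#' @param seed optional integer used to break exact-age ties.
#' @return List of class `split_plan`: `half1`, `half2` (sample-id vectors
#'   whose sizes differ by at most 1), and `balance` (per-half mean age and
#'   batch counts).
#' @examples
#' md <- data.frame(sample_id = paste0("s", 1:4), diagnosis = "control",
#'                  subject_age = 8, paternal_age = c(20, 25, 30, 35),
#'                  scan_batch = 1)
#' balanced_split(md)  # halves {20, 35} and {25, 30}, both mean 27.5
#' @export
balanced_split <- function(metadata, age_col = "paternal_age",
                           batch_col = "scan_batch", seed = NULL) {
  md <- as.data.frame(metadata)
  if (!all(c("sample_id", age_col, batch_col) %in% names(md))) {
    stop("metadata must contain sample_id, ", age_col, " and ", batch_col)
  }
  ok <- !is.na(md[[age_col]]) & !is.na(md[[batch_col]])
  if (any(!ok)) {
    warning(sprintf("%d sample(s) dropped from split: missing balance variables",
                    sum(!ok)))
    md <- md[ok, , drop = FALSE]
  }
  if (nrow(md) < 4) stop("balanced_split needs >= 4 samples with balance variables")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tiebreak <- if (is.null(seed)) seq_len(nrow(md)) else stats::runif(nrow(md))

  halves <- integer(nrow(md))
  n_half <- c(0L, 0L)
  for (b in sort(unique(md[[batch_col]]))) {
    idx <- which(md[[batch_col]] == b)
    idx <- idx[order(md[[age_col]][idx], tiebreak[idx])]
    k <- length(idx)
    smaller <- if (n_half[1] <= n_half[2]) 1L else 2L
    if (k %% 2 == 1) {
      # odd stratum: the mid-ranked sample (closest to the stratum centre)
      # is the leftover and joins the currently smaller half, so half sizes
      # stay within one and neither age extreme is orphaned into one half
      mid <- (k + 1L) %/% 2L
      halves[idx[mid]] <- smaller
      n_half[smaller] <- n_half[smaller] + 1L
      if (k == 1) {
        warning(sprintf(
          "batch stratum %s has a single sample; assigned to the smaller half", b))
      }
      idx <- idx[-mid]
      start <- c(2L, 1L)[smaller]
    } else {
      start <- smaller
    }
    other <- c(2L, 1L)[start]
    assign_b <- rep_len(c(start, other, other, start), length(idx))
    halves[idx] <- assign_b
    n_half[1] <- n_half[1] + sum(assign_b == 1L)
    n_half[2] <- n_half[2] + sum(assign_b == 2L)
  }
  balance <- do.call(rbind, lapply(1:2, function(h) {
    sel <- halves == h
    data.frame(
      half = h, n = sum(sel),
      mean_age = mean(md[[age_col]][sel]),
      batch_counts = paste(
        vapply(sort(unique(md[[batch_col]])), function(b)
          sprintf("%s:%d", b, sum(sel & md[[batch_col]] == b)), character(1)),
        collapse = " "),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(half1 = md$sample_id[halves == 1L],
                 half2 = md$sample_id[halves == 2L],
                 balance = balance, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> halves of %d / %d\n",
              length(x$half1), length(x$half2)))
  print(x$balance)
  invisible(x)
}

.subset_samples <- function(x, ids) {
  expression_matrix(x$values[, ids, drop = FALSE], x$scale)
}

.try_analysis <- function(expr) {
  tryCatch(expr, error = function(e) {
    list(skipped = TRUE, reason = conditionMessage(e))
  })
}

#' Run the analyses on balanced half-sample replicates
#'
#' Splits the case and control groups into covariate-balanced halves
#' ([balanced_split()]) and reruns the requested analyses on each replicate
#' pair (case half r vs control half r). A replicate analysis that cannot
#' run (too few samples, empty list) is recorded as skipped with its reason,
#' never a crash.
#'
#' @param cohort a `synthetic_cohort` or equivalent list with `expression`
#'   (log2 `expr_matrix`), `presence`, `metadata`.
#' @param case_ids,control_ids sample ids of the two groups being
#'   contrasted.
#' @param analyses any of `"variance"` (standardized-phenotype t-test),
#'   `"correlation"` (paternal age vs phenotype in the control half),
#'   `"de"` (differential expression per replicate), `"overlap"`
#'   (chi-square between the replicates' down-regulated lists).
#' @param background probe universe for DE/overlap (default: all probes).
#' @param p_threshold,fc_threshold DE thresholds.
#' @param seed passed to [balanced_split()] for tie-breaking.
#' @return List of class `crossval_result`: `plans` (case/control split
#'   plans), `replicates` (per-replicate analysis results), `overlap`
#'   (between-replicate down-list chi-square, when requested), and
#'   `concordance` (per-replicate estimates and p-values with agreement
#'   flags).
#' @export
crossval_run <- function(cohort, case_ids, control_ids,
                         analyses = c("variance", "de", "overlap"),
                         background = NULL,
                         p_threshold = 0.05, fc_threshold = 1.1,
                         seed = NULL) {
  analyses <- match.arg(analyses,
                        c("variance", "correlation", "de", "overlap"),
                        several.ok = TRUE)
  md <- cohort$metadata
  pheno <- overall_variance(cohort$expression)
  std <- stats::setNames(standardize(pheno$overall_variance), pheno$sample_id)

  plan_case <- balanced_split(md[md$sample_id %in% case_ids, ], seed = seed)
  plan_ctrl <- balanced_split(md[md$sample_id %in% control_ids, ], seed = seed)

  qn <- if ("de" %in% analyses) quantile_normalize(cohort$expression) else NULL
  if (is.null(background)) background <- probe_ids(cohort$expression)

  replicates <- lapply(1:2, function(r) {
    ids_a <- if (r == 1) plan_case$half1 else plan_case$half2
    ids_b <- if (r == 1) plan_ctrl$half1 else plan_ctrl$half2
    out <- list(case_ids = ids_a, control_ids = ids_b)
    if ("variance" %in% analyses) {
      out$variance <- .try_analysis({
        ids <- c(ids_a, ids_b)
        compare_groups(std[ids],
                       rep(c("case", "control"), c(length(ids_a), length(ids_b))),
                       case = "case")
      })
    }
    if ("correlation" %in% analyses) {
      out$correlation <- .try_analysis({
        rows <- match(ids_b, md$sample_id)
        correlation_fisher(md$paternal_age[rows], std[ids_b])
      })
    }
    if ("de" %in% analyses) {
      out$de <- .try_analysis({
        ids <- c(ids_a, ids_b)
        tab <- de_table(.subset_samples(qn, ids),
                        rep(c("case", "control"), c(length(ids_a), length(ids_b))),
                        case = "case", background = background,
                        p_threshold = p_threshold, fc_threshold = fc_threshold)
        list(table = tab,
             down = significant_sets(tab, "down"),
             up = significant_sets(tab, "up"))
      })
    }
    out
  })

  overlap <- NULL
  if ("overlap" %in% analyses && "de" %in% analyses) {
    overlap <- .try_analysis({
      d1 <- replicates[[1]]$de$down
      d2 <- replicates[[2]]$de$down
      if (is.null(d1) || is.null(d2)) stop("down-regulated lists unavailable")
      overlap_chi_square(d1, d2, background)
    })
  }

  concordance <- NULL
  if ("variance" %in% analyses) {
    rows <- lapply(1:2, function(r) {
      v <- replicates[[r]]$variance
      if (isTRUE(v$skipped)) {
        data.frame(replicate = r, estimate = NA_real_, p_value = NA_real_,
                   skipped = TRUE, stringsAsFactors = FALSE)
      } else {
        data.frame(replicate = r, estimate = v$estimate, p_value = v$p_value,
                   skipped = FALSE, stringsAsFactors = FALSE)
      }
    })
    concordance <- do.call(rbind, rows)
    est <- concordance$estimate
    attr(concordance, "signs_agree") <-
      all(!is.na(est)) && (all(est > 0) || all(est < 0))
    attr(concordance, "both_significant") <-
      all(!is.na(concordance$p_value)) && all(concordance$p_value < p_threshold)
  }

  structure(list(plans = list(case = plan_case, control = plan_ctrl),
                 replicates = replicates, overlap = overlap,
                 concordance = concordance),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("<crossval_result>\n")
  if (!is.null(x$concordance)) {
    print(x$concordance)
    cat(sprintf("  signs agree: %s; both significant: %s\n",
                attr(x$concordance, "signs_agree"),
                attr(x$concordance, "both_significant")))
  }
  if (!is.null(x$overlap) && !isTRUE(x$overlap$skipped)) {
    cat(sprintf("  down-list overlap chi^2 = %.4g (p = %.3g)\n",
                x$overlap$statistic, x$overlap$p_value))
  }
  invisible(x)
}
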