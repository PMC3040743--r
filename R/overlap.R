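# Gene-list overlap (Yates-corrected 2x2 chi-square) and local gene-set
# enrichment (one-sided hypergeometric, Fisher or the conservative EASE
# variant) against a user-supplied background universe.

.yates_chisq <- function(a, b, c_, d) {
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(cells < 0)) stop("contingency cells must be non-negative")
  n <- sum(cells)
  margins <- c("a+b" = a + b, "c+d" = c_ + d, "a+c" = a + c_, "b+d" = b + d)
  if (any(margins == 0)) {
    stop("degenerate margin (", names(margins)[margins == 0][1],
         " = 0); chi-square undefined")
  }
  # continuity correction term clamps at zero for near-independent tables
  num <- max(abs(a * d - b * c_) - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Yates-corrected chi-square for the overlap of two gene lists
#'
#' Builds the 2x2 table (in both lists / A only / B only / background
#' remainder) and computes
#' `chi^2 = N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))`
#' with the upper-tail 1-df p-value (the standard two-sided test for a 2x2
#' table). Symmetric in its two lists.
#'
#' @param list_a,list_b character vectors of probe/gene ids, both subsets of
#'   `background`.
#' @param background character vector: the probe universe.
#' @return List of class `gexvar_overlap`: `table` (named counts a, b, c, d),
#'   `statistic`, `df`, `p_value`.
#' @export
overlap_chi_square <- function(list_a, list_b, background) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  background <- unique(background)
  out_a <- setdiff(list_a, background)
  out_b <- setdiff(list_b, background)
  if (length(out_a) || length(out_b)) {
    stop("list members missing from background: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "))
  }
  a <- length(intersect(list_a, list_b))
  b <- length(list_a) - a
  c_ <- length(list_b) - a
  d <- length(background) - a - b - c_
  res <- .yates_chisq(a, b, c_, d)
  structure(c(list(table = c(a = a, b = b, c = c_, d = d)), res),
            class = "gexvar_overlap")
}

#' Overlap chi-square from printed list sizes
#'
#' Same statistic as [overlap_chi_square()], computed from summary counts
#' (list sizes, overlap and background size) rather than the lists
#' themselves — the form needed to re-analyze published overlap tables.
#'
#' @param n_a,n_b sizes of the two lists.
#' @param n_overlap number of ids in both lists.
#' @param n_background size of the background universe.
#' @return List of class `gexvar_overlap` (see [overlap_chi_square()]).
#' @examples
#' overlap_counts_chi_square(641, 764, 145, 25146)
#' @export
overlap_counts_chi_square <- function(n_a, n_b, n_overlap, n_background) {
  if (n_overlap > min(n_a, n_b)) stop("overlap exceeds a list size")
  a <- n_overlap
  b <- n_a - a
  c_ <- n_b - a
  d <- n_background - a - b - c_
  if (d < 0) stop("background smaller than the union of the lists")
  res <- .yates_chisq(a, b, c_, d)
  structure(c(list(table = c(a = a, b = b, c = c_, d = d)), res),
            class = "gexvar_overlap")
}

#' @export
print.gexvar_overlap <- function(x, ...) {
  cat(sprintf("2x2 overlap (Yates): chi^2 = %.4g, df = 1, p = %.3g\n",
              x$statistic, x$p_value))
  cat(sprintf("  a=%d b=%d c=%d d=%d\n", x$table["a"], x$table["b"],
              x$table["c"], x$table["d"]))
  invisible(x)
}

#' Gene-set enrichment of a list against a background
#'
#' For each set, the one-sided hypergeometric upper-tail probability of
#' observing at least the seen overlap between the list and the set, both
#' intersected with the background. `method = "ease"` is the conservative
#' variant that removes one member from the observed overlap before testing.
#' Optional Benjamini-Hochberg adjustment across sets.
#'
#' @param list character vector of ids, a subset of `background`.
#' @param background character vector: the probe universe.
#' @param genesets a [gene_sets()] collection.
#' @param method `"fisher"` or `"ease"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per set: `set`, `overlap`,
#'   `set_size` (within background), `list_size`, `p_value`
#'   (plus `p_adjusted` with BH), `method`.
#' @export
enrich_sets <- function(list, background, genesets,
                        method = c("fisher", "ease"),
                        adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot(inherits(genesets, "gene_sets"))
  list <- unique(list); background <- unique(background)
  if (!length(list)) stop("empty gene list")
  if (!length(background)) stop("empty background")
  outside <- setdiff(list, background)
  if (length(outside)) {
    stop("list members missing from background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  n_bg <- length(background)
  n_list <- length(list)
  rows <- lapply(seq_along(genesets$sets), function(i) {
    set_bg <- intersect(genesets$sets[[i]], background)
    k <- length(intersect(set_bg, list))
    k_eff <- if (method == "ease") max(k - 1L, 0L) else k
    p <- stats::phyper(k_eff - 1L, length(set_bg), n_bg - length(set_bg),
                       n_list, lower.tail = FALSE)
    data.frame(set = names(genesets$sets)[i], overlap = k,
               set_size = length(set_bg), list_size = n_list,
               p_value = p, method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(), overlap = integer(),
                      set_size = integer(), list_size = integer(),
                      p_value = numeric(), method = character(),
                      stringsAsFactors = FALSE)
  }
  if (adjust == "BH" && nrow(out)) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
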