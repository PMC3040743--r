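#' Construct an expression matrix
#'
#' The central container of the package: a probes x samples matrix of
#' expression values together with a scale flag. Per-sample distributions of
#' the log2-scale matrix are the unit of analysis for the variance phenotype.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param scale either `"linear"` (summarized signal intensities) or `"log2"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `scale`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' expression_matrix(m, "linear")
#' @export
expression_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have probe ids as rownames and sample ids as colnames")
  }
  .check_unique(rownames(values), "probe id")
  .check_unique(colnames(values), "sample id")
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d probes x %d samples, %s scale\n",
    nrow(x$values), ncol(x$values), x$scale
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Probe and sample identifiers
#'
#' @param x an `expr_matrix` or a presence matrix.
#' @return Character vector of identifiers, in storage order.
#' @export
probe_ids <- function(x) {
  if (inherits(x, "expr_matrix")) rownames(x$values) else rownames(x)
}

#' @rdname probe_ids
#' @export
sample_ids <- function(x) {
  if (inherits(x, "expr_matrix")) colnames(x$values) else colnames(x)
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s(s): %s", what, paste(dup, collapse = ", ")))
  }
  invisible(ids)
}

#' Validate a presence-call matrix
#'
#' Presence calls (MAS 5.0 style present/absent flags) are stored as a plain
#' logical matrix with probe/sample dimnames. When paired with an expression
#' matrix the dimensions and identifiers must agree.
#'
#' @param calls logical matrix of present calls.
#' @param expression optional companion `expr_matrix` to check against.
#' @return `calls`, invisibly, after validation.
#' @export
validate_presence <- function(calls, expression = NULL) {
  if (!is.matrix(calls) || !is.logical(calls)) {
    stop("presence calls must be a logical matrix")
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("presence matrix must have probe and sample ids as dimnames")
  }
  .check_unique(rownames(calls), "probe id")
  .check_unique(colnames(calls), "sample id")
  if (!is.null(expression)) {
    if (!identical(dim(calls), dim(expression$values)) ||
        !identical(rownames(calls), probe_ids(expression)) ||
        !identical(colnames(calls), sample_ids(expression))) {
      stop("presence matrix does not match its companion expression matrix")
    }
  }
  invisible(calls)
}

.DIAGNOSIS_LEVELS <- c("autism", "control")

#' Validate and normalize a sample metadata table
#'
#' Canonicalizes diagnosis labels (case-insensitive), checks identifier
#' uniqueness, age positivity and batch membership. Missing paternal ages are
#' kept as `NA` and later excluded from paternal-age analyses, never imputed.
#'
#' @param metadata data.frame with columns `sample_id`, `diagnosis`
#'   (`autism`/`control`, may be `NA` for treatment experiments),
#'   `subject_age`, `paternal_age` (may be `NA`), `scan_batch`, and
#'   optionally `condition`.
#' @return The normalized data.frame.
#' @export
validate_metadata <- function(metadata) {
  req <- c("sample_id", "diagnosis", "subject_age", "paternal_age", "scan_batch")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  .check_unique(metadata$sample_id, "sample id")

  dx <- tolower(trimws(as.character(metadata$diagnosis)))
  dx[dx == ""] <- NA_character_
  bad <- setdiff(stats::na.omit(unique(dx)), .DIAGNOSIS_LEVELS)
  if (length(bad)) {
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  }
  metadata$diagnosis <- dx

  for (col in c("subject_age", "paternal_age")) {
    v <- suppressWarnings(as.numeric(metadata[[col]]))
    if (any(!is.na(v) & v <= 0)) {
      stop(sprintf("non-positive %s for sample(s): %s", col,
                   paste(metadata$sample_id[!is.na(v) & v <= 0], collapse = ", ")))
    }
    metadata[[col]] <- v
  }
  metadata$scan_batch <- as.integer(metadata$scan_batch)
  if (anyNA(metadata$scan_batch)) stop("scan_batch must be integer-valued")
  metadata
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of probe/gene identifiers.
#' @param descriptions optional character vector of per-set descriptions.
#' @return Object of class `gene_sets`.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets)) stop("`sets` must be a named list of character vectors")
  if (length(sets)) {
    if (is.null(names(sets)) || any(names(sets) == "")) {
      stop("every gene set must be named")
    }
    .check_unique(names(sets), "gene-set name")
    if (any(lengths(sets) == 0)) {
      stop("empty gene set(s): ",
           paste(names(sets)[lengths(sets) == 0], collapse = ", "))
    }
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets, descriptions = descriptions), class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d set(s)\n", length(x$sets)))
  invisible(x)
}

#' @export
length.gene_sets <- function(x) length(x$sets)
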