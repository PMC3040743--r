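# Tab-delimited interchange readers/writers. Parsing is done line-by-line so
# that malformed input is reported with its row/column location; files at desk
# scale (tens of MB) parse in seconds.

.read_table_lines <- function(path) {
  lines <- readLines(path)
  # trailing blank lines are tolerated
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  lines
}

.parse_rectangular <- function(path, what) {
  lines <- .read_table_lines(path)
  if (!length(lines)) stop(sprintf("%s file '%s' is empty", what, path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_header <- length(cells[[1]])
  widths <- lengths(cells)
  if (any(widths[-1] != ncol_header)) {
    bad <- which(widths[-1] != ncol_header)[1] + 1L
    stop(sprintf(
      "ragged row in %s file '%s': line %d has %d field(s), header has %d",
      what, path, bad, widths[bad], ncol_header
    ))
  }
  cells
}

#' Read an expression matrix from a tab-delimited file
#'
#' Expects a header row of sample ids; each following row is a probe id and
#' its values. Round-trips bit-exactly with [write_expression_matrix()] for
#' finite values.
#'
#' @param path file path.
#' @param scale scale of the stored values, `"linear"` or `"log2"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  cells <- .parse_rectangular(path, "expression")
  samples <- cells[[1]][-1]
  n <- length(samples)
  if (n < 1) stop(sprintf("expression file '%s' has no sample columns", path))
  probes <- vapply(cells[-1], `[[`, character(1), 1L)
  vals <- matrix(NA_real_, length(probes), n,
                 dimnames = list(probes, samples))
  for (i in seq_along(probes)) {
    row <- suppressWarnings(as.numeric(cells[[i + 1L]][-1]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1]
      stop(sprintf(
        "non-numeric cell in expression file '%s' at line %d, column %d ('%s')",
        path, i + 1L, j + 1L, cells[[i + 1L]][j + 1L]
      ))
    }
    vals[i, ] <- row
  }
  expression_matrix(vals, scale)
}

#' Write an expression matrix to a tab-delimited file
#'
#' Values are serialized at full double precision (`%.17g`) so the file
#' round-trips bit-exactly through [read_expression_matrix()].
#'
#' @param x an `expr_matrix`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("probe_id", colnames(v)), collapse = "\t"), body), path)
  invisible(path)
}

#' Read and write presence-call matrices
#'
#' Calls are stored as `P` (present) / `A` (absent); `TRUE`/`FALSE` and
#' `1`/`0` are also accepted on input.
#'
#' @param path file path.
#' @return `read_presence_matrix()` returns a logical matrix with probe and
#'   sample dimnames; `write_presence_matrix()` returns `path` invisibly.
#' @export
read_presence_matrix <- function(path) {
  cells <- .parse_rectangular(path, "presence")
  samples <- cells[[1]][-1]
  probes <- vapply(cells[-1], `[[`, character(1), 1L)
  calls <- matrix(NA, length(probes), length(samples),
                  dimnames = list(probes, samples))
  map <- c(P = TRUE, A = FALSE, "TRUE" = TRUE, "FALSE" = FALSE,
           "1" = TRUE, "0" = FALSE)
  for (i in seq_along(probes)) {
    row <- map[toupper(cells[[i + 1L]][-1])]
    if (anyNA(row)) {
      j <- which(is.na(row))[1]
      stop(sprintf(
        "invalid presence call in '%s' at line %d, column %d",
        path, i + 1L, j + 1L
      ))
    }
    calls[i, ] <- row
  }
  validate_presence(calls)
  calls
}

#' @rdname read_presence_matrix
#' @param calls logical matrix of present calls.
#' @export
write_presence_matrix <- function(calls, path) {
  validate_presence(calls)
  body <- vapply(seq_len(nrow(calls)), function(i) {
    paste(c(rownames(calls)[i], ifelse(calls[i, ], "P", "A")), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("probe_id", colnames(calls)), collapse = "\t"), body),
             path)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Tab-delimited with columns `sample_id`, `diagnosis`, `subject_age`,
#' `paternal_age`, `scan_batch` and optionally `condition`. An empty
#' `paternal_age` field is read as missing (`NA`) and such samples are
#' excluded from paternal-age analyses downstream, never imputed.
#'
#' @param path file path.
#' @return `read_sample_metadata()` returns a validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("", "NA"))
  validate_metadata(df)
}

#' @rdname read_sample_metadata
#' @param metadata a metadata data.frame (see [validate_metadata()]).
#' @export
write_sample_metadata <- function(metadata, path) {
  metadata <- validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member identifiers, all
#' tab-separated.
#'
#' @param path file path.
#' @return A [gene_sets()] collection; an empty file yields an empty
#'   collection.
#' @export
read_gene_sets <- function(path) {
  lines <- .read_table_lines(path)
  if (!length(lines)) return(gene_sets(list()))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(cells) < 3L)
  if (length(short)) {
    stop(sprintf(
      "GMT parse error in '%s': line %d has %d field(s), need name, description and at least one member",
      path, short[1], lengths(cells)[short[1]]
    ))
  }
  sets <- lapply(cells, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(cells, `[[`, character(1), 1L)
  gene_sets(sets, vapply(cells, `[[`, character(1), 2L))
}

#' @rdname read_gene_sets
#' @param x a `gene_sets` collection.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  lines <- vapply(seq_along(x$sets), function(i) {
    paste(c(names(x$sets)[i], x$descriptions[i], x$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
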