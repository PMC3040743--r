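# Shared fixtures, all built in code at test time.

tiny_expr <- function(values, scale = "log2") {
  g <- nrow(values)
  n <- ncol(values)
  dimnames(values) <- list(sprintf("p%d", seq_len(g)), sprintf("s%d", seq_len(n)))
  expression_matrix(values, scale)
}

rand_expr <- function(g, n, seed = 1, scale = "log2", mean = 6, sd = 2) {
  set.seed(seed)
  tiny_expr(matrix(rnorm(g * n, mean, sd), g, n), scale)
}

# Construct a pair of vectors whose Pearson correlation is exactly `r`
# (Gram-Schmidt: the noise component is orthogonalized against x).
make_pair_with_cor <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  xs <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  e <- e - mean(e)
  e <- e - sum(e * xs) * xs
  es <- e / sqrt(sum(e^2))
  list(x = x, y = r * xs + sqrt(1 - r^2) * es)
}

# Minimal valid metadata table.
toy_metadata <- function(n_autism = 3, n_control = 3, paternal_age = NULL) {
  n <- n_autism + n_control
  if (is.null(paternal_age)) paternal_age <- seq(25, length.out = n, by = 2)
  data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    diagnosis = rep(c("autism", "control"), c(n_autism, n_control)),
    subject_age = round(runif(n, 4, 10), 1),
    paternal_age = paternal_age,
    scan_batch = rep_len(1:2, n),
    stringsAsFactors = FALSE
  )
}
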