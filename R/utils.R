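# Internal helpers shared across modules.

# Flatten k x 2 x n array to n x 2k matrix (x-block then y-block).
flatten_shapes <- function(a) {
  k <- dim(a)[1L]
  n <- dim(a)[3L]
  m <- matrix(aperm(a, c(3L, 1L, 2L)), nrow = n, ncol = 2L * k)
  rownames(m) <- dimnames(a)[[3L]]
  m
}

# Inverse of flatten_shapes.
unflatten_shapes <- function(m, k) {
  n <- nrow(m)
  aperm(array(m, dim = c(n, k, 2L)), c(2L, 3L, 1L))
}

as_config <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("a configuration must be a k x 2 matrix")
  storage.mode(x) <- "double"
  x
}

# Center a configuration and scale it to unit centroid size.
center_scale_config <- function(x) {
  x <- as_config(x)
  x <- sweep(x, 2L, colMeans(x))
  cs <- sqrt(sum(x^2))
  if (cs < .Machine$double.eps * nrow(x))
    stop("degenerate configuration: all landmarks coincident")
  x / cs
}

# round-half-up, used for subsample bin sizes (72 * 0.1 -> 7, 81 * 0.1 -> 8)
round_half_up <- function(x) floor(x + 0.5)

# Permutation p-value: proportion of the permutation distribution
# (observed case included) at or above the observed statistic.
perm_pvalue <- function(observed, permuted) {
  sum(permuted >= observed - 1e-12) / length(permuted)
}

perm_zscore <- function(observed, permuted_null) {
  s <- stats::sd(permuted_null)
  if (!is.finite(s) || s == 0) return(NA_real_)
  (observed - mean(permuted_null)) / s
}

new_perm_test_result <- function(statistic_name, observed, permuted,
                                 n_perm, seed, r_squared = NA_real_) {
  structure(
    list(statistic_name = statistic_name,
         observed = observed,
         p_value = perm_pvalue(observed, permuted),
         n_perm = n_perm,
         effect_size_z = perm_zscore(observed, permuted[-1L]),
         r_squared = r_squared,
         permuted = permuted,
         seed = seed),
    class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat("Permutation test: ", x$statistic_name, "\n", sep = "")
  cat(sprintf("  observed = %.6g, p = %.4g (n_perm = %d, seed = %s)\n",
              x$observed, x$p_value, x$n_perm, format(x$seed)))
  if (is.finite(x$effect_size_z))
    cat(sprintf("  effect size Z = %.3f\n", x$effect_size_z))
  if (!is.na(x$r_squared))
    cat(sprintf("  R-squared = %.4f\n", x$r_squared))
  invisible(x)
}
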