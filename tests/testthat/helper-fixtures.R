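# Fixtures built in code; all randomness under explicit seeds.

# A random non-degenerate configuration.
rand_config <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(stats::rnorm(k), stats::rnorm(k))
}

# Apply a random similarity transform (rotation, scaling, translation)
# to every specimen of a k x 2 x n array.
random_similarity <- function(a, seed = 1) {
  set.seed(seed)
  for (i in seq_len(dim(a)[3])) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    a[, , i] <- a[, , i] %*% R * runif(1, 0.2, 5) +
      matrix(runif(2, -10, 10), dim(a)[1], 2, byrow = TRUE)
  }
  a
}

# Small default-structure dataset for quick tests.
tiny_dataset <- function(n = c(F = 8, M = 8), seed = 1, ...) {
  generate_dataset(generator_spec(n = n, seed = seed, ...))
}

# Pairwise partial Procrustes distances between aligned specimens.
aligned_pairwise_dists <- function(aligned) {
  n <- dim(aligned)[3]
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sqrt(sum((aligned[, , i] - aligned[, , j])^2))
  d
}

# Estimated allometry vector: multivariate regression of the aligned
# shapes on log10 centroid size, rotated from the consensus frame into
# the template frame so it is comparable with the generator's truth.
recover_allometry <- function(g, template, sliders = NULL) {
  k <- dim(g$aligned)[1]
  Y <- t(apply(g$aligned, 3, function(m) c(m[, 1], m[, 2])))
  beta <- coef(lm(Y ~ log10(g$centroid_sizes)))[2, ]
  cons <- g$consensus / sqrt(sum(g$consensus^2))
  tpl <- sweep(template, 2, colMeans(template))
  tpl <- tpl / sqrt(sum(tpl^2))
  R <- opa_align(cons, tpl)$rotation
  bm <- cbind(beta[1:k], beta[k + 1:k]) %*% R
  est <- c(bm[, 1], bm[, 2])
  # tangential semilandmark position is nuisance under sliding:
  # compare in the informative (slide-orthogonal) subspace
  U <- morphsample:::nuisance_basis(template, sliders)
  drop(est - U %*% crossprod(U, est))
}

# Independent brute-force rotation search: minimum distance over a fine
# angle grid (both inputs centered, unit size).
grid_search_opa_distance <- function(target, reference, step = 1e-5) {
  th <- seq(0, 2 * pi, by = step)
  best <- Inf
  # coarse-to-fine to keep runtime sane at step 1e-5
  coarse <- seq(0, 2 * pi, length.out = 721)
  d2 <- vapply(coarse, function(t) {
    R <- matrix(c(cos(t), -sin(t), sin(t), cos(t)), 2, 2)
    sum((target %*% R - reference)^2)
  }, numeric(1))
  t0 <- coarse[which.min(d2)]
  fine <- seq(t0 - 0.02, t0 + 0.02, by = step)
  d2f <- vapply(fine, function(t) {
    R <- matrix(c(cos(t), -sin(t), sin(t), cos(t)), 2, 2)
    sum((target %*% R - reference)^2)
  }, numeric(1))
  sqrt(min(d2f))
}
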