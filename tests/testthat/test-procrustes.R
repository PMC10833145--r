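test_that("centroid size: closed cases, homogeneity, and term-by-term oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  x <- rand_config(14, seed = 4)
  expect_equal(centroid_size(2 * x), 2 * centroid_size(x), tolerance = 1e-12)
  # brute-force direct summation oracle
  cen <- colMeans(x)
  oracle <- 0
  for (i in seq_len(nrow(x)))
    oracle <- oracle + (x[i, 1] - cen[1])^2 + (x[i, 2] - cen[2])^2
  expect_equal(centroid_size(x), sqrt(oracle), tolerance = 1e-12)
  expect_equal(centroid_size(matrix(1, 5, 2)), 0)
})

test_that("opa_align: rotation invariance, reflection semantics, grid-search oracle", {
  ref <- center_scale_config(rand_config(12, seed = 5))
  th <- pi / 6
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  al <- opa_align(ref %*% R, ref)
  expect_lt(al$distance, 1e-12)
  expect_equal(det(al$rotation), 1, tolerance = 1e-12)

  mir <- ref %*% diag(c(-1, 1))
  expect_gt(opa_align(mir, ref, allow_reflection = FALSE)$distance, 0.1)
  expect_lt(opa_align(mir, ref, allow_reflection = TRUE)$distance, 1e-12)

  for (s in 1:3) {
    a <- center_scale_config(rand_config(10, seed = 20 + s))
    b <- center_scale_config(rand_config(10, seed = 30 + s))
    expect_equal(opa_align(a, b)$distance,
                 grid_search_opa_distance(a, b), tolerance = 1e-8)
  }
})

test_that("GPA is invariant to similarity transforms of the input", {
  d <- tiny_dataset(seed = 6)
  g0 <- gpa(d)
  g1 <- gpa(random_similarity(d$coords, seed = 99), sliders = d$sliders)
  expect_lt(max(abs(aligned_pairwise_dists(g0$aligned) -
                    aligned_pairwise_dists(g1$aligned))), 1e-9)
})

test_that("GPA degenerate and small cases behave as the geometry dictates", {
  base <- center_scale_config(rand_config(8, seed = 7))
  copies <- array(rep(base, 10), dim = c(8, 2, 10))
  g <- gpa(random_similarity(copies, seed = 1))
  expect_lt(max(aligned_pairwise_dists(g$aligned)), 1e-9)
  expect_lte(g$iterations, 3L)
  # two specimens: consensus equidistant from both
  two <- tiny_dataset(seed = 8)$coords[, , 1:2]
  g2 <- gpa(two)
  d1 <- sqrt(sum((g2$aligned[, , 1] - g2$consensus)^2))
  d2 <- sqrt(sum((g2$aligned[, , 2] - g2$consensus)^2))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("GPA output satisfies its contract: centering, unit size, mean consensus", {
  d <- tiny_dataset(seed = 9)
  g <- gpa(d)
  cents <- apply(g$aligned, 3, function(m) max(abs(colMeans(m))))
  sizes <- apply(g$aligned, 3, function(m) sqrt(sum(m^2)))
  expect_lt(max(cents), 1e-9)
  expect_lt(max(abs(sizes - 1)), 1e-9)
  expect_equal(g$consensus, mean_shape(g$aligned), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gte(g$iterations, 1L)
  # centroid sizes come from the raw coordinates: identical slide on/off
  g_noslide <- gpa(d, slide = FALSE)
  expect_identical(g$centroid_sizes, g_noslide$centroid_sizes)
  expect_equal(unname(g$centroid_sizes),
               apply(d$coords, 3, centroid_size), ignore_attr = TRUE)
})

test_that("consensus is locally optimal for summed squared Procrustes distance", {
  d <- tiny_dataset(n = c(F = 6, M = 6), seed = 10)
  g <- gpa(d)
  ssd_to <- function(target) sum(apply(g$aligned, 3, function(m)
    procrustes_distance(m, target)^2))
  base <- ssd_to(g$consensus)
  set.seed(42)
  for (r in 1:10) {
    pert <- g$consensus + matrix(rnorm(length(g$consensus), 0, 1e-3),
                                 ncol = 2)
    expect_gte(ssd_to(pert), base - 1e-12)
  }
})

test_that("mean_shape is the coordinate-wise mean", {
  a <- array(rnorm(10 * 2 * 7), dim = c(10, 2, 7))
  m <- mean_shape(a)
  expect_equal(unname(m), apply(a, c(1, 2), mean), tolerance = 1e-15)
  expect_equal(unname(mean_shape(a[, , 1, drop = FALSE])), a[, , 1])
  x <- rand_config(6, seed = 1)
  sym <- array(c(x + 0.3, x - 0.3), dim = c(6, 2, 2))
  expect_equal(unname(mean_shape(sym)), x, tolerance = 1e-12)
})

test_that("procrustes_distance is a similarity-invariant metric", {
  x <- rand_config(9, seed = 11)
  expect_equal(procrustes_distance(x, x), 0, tolerance = 1e-12)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  y <- 3.7 * x %*% R + matrix(c(5, -2), 9, 2, byrow = TRUE)
  expect_equal(procrustes_distance(x, y), 0, tolerance = 1e-12)
  expect_error(procrustes_distance(x, rand_config(8)), "landmark count")
  # symmetry and triangle inequality over random triples
  set.seed(12)
  for (r in 1:100) {
    a <- rand_config(7); b <- rand_config(7); cc <- rand_config(7)
    dab <- procrustes_distance(a, b)
    expect_equal(dab, procrustes_distance(b, a), tolerance = 1e-12)
    expect_lte(dab, procrustes_distance(a, cc) +
                 procrustes_distance(cc, b) + 1e-10)
  }
})
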