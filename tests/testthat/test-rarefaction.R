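test_that("rarefaction records obey the design contracts", {
  d <- generate_dataset(generator_spec(n = c(F = 10, M = 6), seed = 30))
  rec <- run_rarefaction(d, fractions = c(1, 0.5, 0.25), T = 4,
                         base_seed = 5)
  expect_s3_class(rec, "rarefaction_records")
  expect_identical(nrow(rec), 12L)
  # 100% bin: identical records, zero distance, all members
  full <- rec[rec$fraction == 1, ]
  expect_true(all(full$dist_to_true == 0))
  expect_equal(length(unique(full$mean_log_cs)), 1L)
  ms <- attr(rec, "mean_shapes")
  expect_lt(max(abs(ms[, , 1] - ms[, , 4])), 1e-15)
  # subsample sizes round half-up and members are drawn without replacement
  expect_identical(unique(rec$m[rec$fraction == 0.25]), 4L)
  members <- attr(rec, "members")
  expect_true(all(vapply(members, anyDuplicated, integer(1)) == 0L))
  # seed schedule is recorded and reproducible
  expect_identical(rec$seed[5], 5 * 1e6 + 2 * 1e4 + 1)
  rec2 <- run_rarefaction(d, fractions = c(1, 0.5, 0.25), T = 4,
                          base_seed = 5)
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
  expect_identical(attr(rec, "members"), attr(rec2, "members"))
  expect_error(run_rarefaction(d, fractions = c(0.1), T = 2), "fewer than 3")
  expect_error(run_rarefaction(d[1:5], T = 2), "at least 10")
})

test_that("the 10% bin has 7 of 72 and 8 of 81 specimens", {
  d72 <- generate_dataset(generator_spec(seed = 31))
  d81 <- generate_dataset(generator_spec(n = c(F = 39, M = 42), seed = 32))
  r72 <- run_rarefaction(d72, fractions = 0.1, T = 1, do_shapes = FALSE)
  r81 <- run_rarefaction(d81, fractions = 0.1, T = 1, do_shapes = FALSE)
  expect_identical(r72$m, 7L)
  expect_identical(r81$m, 8L)
})

test_that("without shape variation every subsample mean is the true mean", {
  d <- generate_dataset(generator_spec(n = c(F = 8, M = 8), noise_sd = 0,
                                       sex_shape_norm = 0,
                                       allometry_slope = 0, seed = 33))
  rec <- run_rarefaction(d, fractions = c(1, 0.5, 0.25), T = 3,
                         base_seed = 1)
  expect_lt(max(rec$dist_to_true), 1e-8)
})

test_that("summary battery reproduces the qualitative sample-size effects", {
  d <- generate_dataset(generator_spec(seed = 34))
  rec <- run_rarefaction(d, T = 30, base_seed = 2)
  summ <- summarize_rarefaction(rec, n_perm = 100, seed = 3)
  bt <- summ$bin_table[order(-summ$bin_table$fraction), ]
  # mean distance to the true mean grows as the fraction shrinks
  expect_true(all(diff(bt$mean_dist) > 0))
  # so does the dispersion of the subsample means, and the hull areas
  v <- summ$dispersion$variances[as.character(bt$bin)]
  expect_true(all(diff(v) >= 0))
  expect_true(all(diff(bt$hull_area) >= 0))
  # centroid size is estimated without bias: bin means near the truth
  true_mlcs <- bt$mean_mlcs[bt$fraction == 1]
  for (r in which(bt$fraction < 1)) {
    se <- bt$sd_mlcs[r] / sqrt(bt$n_records[r])
    expect_lt(abs(bt$mean_mlcs[r] - true_mlcs), 4 * se)
  }
  # degenerate 100% bin excluded from the distance ANOVA by default
  expect_false(any(grepl("100%", summ$dist_anova$tukey$pair)))
  expect_equal(nrow(summ$dist_anova$tukey), 6L)
  expect_error(summarize_rarefaction(
    run_rarefaction(d, fractions = 1, T = 2)), "at least 2 bins")
})

test_that("PC1 deformation grids: identity without variation, 100% equals full", {
  d0 <- generate_dataset(generator_spec(n = c(F = 6, M = 6), noise_sd = 0,
                                        sex_shape_norm = 0,
                                        allometry_slope = 0, seed = 35))
  rec0 <- run_rarefaction(d0, fractions = c(1, 0.5), T = 2, base_seed = 1)
  expect_error(pc1_grids_for_iterations(rec0, data.frame(fraction = 0.75,
                                                         iteration = 1)),
               "no record")
  gr0 <- pc1_grids_for_iterations(rec0, data.frame(fraction = 1,
                                                   iteration = 1))
  # noise-free: the warp along PC1 is numerically an identity map
  g <- gr0$full$pos
  expect_lt(max(abs(c(g$wx - g$x, g$wy - g$y))), 1e-6)
  # a 100% "subsample" reproduces the full-sample grids
  expect_equal(gr0$subsets[[1]]$pos, gr0$full$pos, tolerance = 1e-9)

  d <- generate_dataset(generator_spec(n = c(F = 12, M = 12), seed = 36))
  rec <- run_rarefaction(d, fractions = c(1, 0.5), T = 2, base_seed = 1)
  gr <- pc1_grids_for_iterations(rec, data.frame(fraction = 0.5,
                                                 iteration = 2))
  expect_s3_class(gr$subsets[[1]]$pos, "deformation_grid")
  expect_identical(gr$subsets[[1]]$fraction, 0.5)
})

test_that("convex hull helpers: area, hull, and Jaccard overlap", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(1, 1))
  h <- convex_hull(sq)
  expect_identical(nrow(h), 4L)
  expect_equal(polygon_area(h), 4)
  sq2 <- sq; sq2[, 1] <- sq2[, 1] + 1  # shifted square, overlap area 2
  expect_equal(hull_jaccard(sq, sq2), 2 / 6, tolerance = 1e-9)
  expect_equal(hull_jaccard(sq, sq), 1, tolerance = 1e-9)
})
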