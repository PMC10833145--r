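test_that("shape PCA: rank-1 case, SVD oracle, centering, orthonormality", {
  d <- tiny_dataset(seed = 14)
  g <- gpa(d)
  p <- pca_shape(g)
  expect_lt(max(abs(crossprod(p$rotation) - diag(ncol(p$rotation)))), 1e-9)
  expect_lt(max(abs(colMeans(p$scores))), 1e-9)
  expect_true(all(diff(p$explained) <= 1e-12))
  # explained fractions match an independent svd of the centered matrix
  Y <- t(apply(g$aligned, 3, function(m) c(m[, 1], m[, 2])))
  Yc <- sweep(Y, 2, colMeans(Y))
  ev <- svd(Yc)$d^2
  ev <- ev[ev > max(ev) * 1e-18]
  expect_equal(p$explained, (ev / sum(ev))[seq_along(p$explained)],
               tolerance = 1e-10)
  # consensus projects to the origin of score space
  expect_lt(max(abs(project_shapes(p, mean_shape(g)))), 1e-9)
  # reconstruction from all components is exact
  rec <- shape_from_scores(p, p$scores[3, ])
  expect_lt(max(abs(rec - g$aligned[, , 3])), 1e-9)

  # rank-1 data: PC1 explains everything
  base <- center_scale_config(rand_config(6, seed = 15))
  dir <- rand_config(6, seed = 16)
  a <- array(NA_real_, dim = c(6, 2, 5))
  for (i in 1:5) a[, , i] <- base + (i - 3) * 0.01 * dir
  p1 <- pca_shape(a)
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)
  expect_error(pca_shape(a[, , 1:2]), "at least 3")
})

test_that("RRPP ANOVA: perfect separation, scalar equivalence, hat-matrix oracle", {
  # pure group shape offset, zero noise: p at its floor, R^2 ~ 1
  k <- 8
  base <- center_scale_config(rand_config(k, seed = 17))
  off <- 0.05 * rand_config(k, seed = 18)
  a <- array(NA_real_, dim = c(k, 2, 12))
  for (i in 1:12) a[, , i] <- base + if (i <= 6) off else -off
  grp <- factor(rep(c("A", "B"), each = 6))
  # tiny jitter so the within-group covariance is nonsingular
  set.seed(19)
  a <- a + array(rnorm(length(a), 0, 1e-9), dim = dim(a))
  g <- gpa(a)
  tab <- proc_anova_rrpp(g, data.frame(grp = grp), n_perm = 100, seed = 1)
  expect_equal(tab["grp", "p"], 1 / 100)
  expect_gt(tab["grp", "R2"], 0.999)

  # scalar response with one factor reduces to classical one-way ANOVA
  set.seed(20)
  y <- rnorm(30)
  f <- factor(rep(letters[1:3], each = 10))
  tab2 <- proc_anova_rrpp(y, data.frame(f = f), n_perm = 50, seed = 2)
  cl <- anova(aov(y ~ f))
  expect_equal(tab2["f", "F"], cl$`F value`[1], tolerance = 1e-12)
  expect_equal(tab2["f", "SS"], cl$`Sum Sq`[1], tolerance = 1e-12)
  expect_equal(tab2["Residuals", "df"], cl$Df[2])

  # sequential SS against a direct projection-matrix computation
  set.seed(21)
  n <- 10
  Y <- matrix(rnorm(n * 6), n)
  x1 <- rnorm(n)
  x2 <- factor(rep(c("u", "v"), each = 5))
  tab3 <- proc_anova_rrpp(Y, data.frame(x1 = x1, x2 = x2), n_perm = 10,
                          seed = 3)
  hat <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  H0 <- hat(matrix(1, n))
  H1 <- hat(cbind(1, x1))
  H2 <- hat(cbind(1, x1, as.numeric(x2 == "v")))
  expect_equal(tab3["x1", "SS"], sum(((H1 - H0) %*% Y)^2), tolerance = 1e-8)
  expect_equal(tab3["x2", "SS"], sum(((H2 - H1) %*% Y)^2), tolerance = 1e-8)
  expect_equal(tab3["Residuals", "SS"], sum(((diag(n) - H2) %*% Y)^2),
               tolerance = 1e-8)
  expect_equal(sum(tab3[c("x1", "x2", "Residuals"), "SS"]),
               tab3["Total", "SS"], tolerance = 1e-8)

  # reproducible given a seed
  tab4 <- proc_anova_rrpp(Y, data.frame(x1 = x1, x2 = x2), n_perm = 10,
                          seed = 3)
  expect_identical(as.data.frame(tab3), as.data.frame(tab4))
  expect_error(proc_anova_rrpp(Y, data.frame(x1 = x1, x1b = x1),
                               n_perm = 10), "collinear")
})

test_that("dispersion test: exact zero for duplicated groups, power at large effect", {
  set.seed(22)
  A <- matrix(rnorm(40 * 6), 40)
  dup <- rbind(A, A)
  gdup <- factor(rep(c("g1", "g2"), each = 40))
  t0 <- dispersion_test(dup, gdup, n_perm = 50, seed = 1)
  expect_equal(t0$pairwise["g1", "g2"], 0)

  B <- sweep(A, 2, colMeans(A)) * 3
  x <- rbind(A, sweep(B, 2, colMeans(A), `+`))
  n50 <- factor(rep(c("a", "b"), each = 40))
  t1 <- dispersion_test(x, n50, n_perm = 200, seed = 2)
  expect_lte(t1$p["a", "b"], 0.01)
  expect_gt(t1$variances["b"], t1$variances["a"] * 5)

  # equal spread: no signal at this fixed seed
  set.seed(23)
  eq <- matrix(rnorm(100 * 4), 100)
  t2 <- dispersion_test(eq, factor(rep(1:2, each = 50)), n_perm = 200,
                        seed = 3)
  expect_gt(t2$p[1, 2], 0.05)
  expect_error(dispersion_test(eq, factor(c(1, rep(2, 99)))), "at least 2")
})

test_that("two-block PLS: self-association, SVD oracle, rotation invariance", {
  set.seed(24)
  X <- matrix(rnorm(10 * 4), 10)
  pl <- two_block_pls(X, X, n_perm = 10, seed = 1)
  expect_equal(pl$observed, 1, tolerance = 1e-12)

  Y <- matrix(rnorm(10 * 6), 10)
  pl2 <- two_block_pls(X, Y, n_perm = 10, seed = 2)
  # independent oracle: direct cross-covariance decomposition
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(t(Xc) %*% Yc / 9)
  r_oracle <- drop(abs(cor(Xc %*% sv$u[, 1], Yc %*% sv$v[, 1])))
  expect_equal(pl2$observed, r_oracle, tolerance = 1e-10)
  expect_gte(pl2$observed, 0)
  expect_lte(pl2$observed, 1)

  # invariant under orthogonal rotation of either block
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  pl3 <- two_block_pls(X, Y %*% Q, n_perm = 10, seed = 2)
  expect_equal(pl3$observed, pl2$observed, tolerance = 1e-10)

  # deterministic under a fixed seed
  pl4 <- two_block_pls(X, Y, n_perm = 200, seed = 7)
  pl5 <- two_block_pls(X, Y, n_perm = 200, seed = 7)
  expect_identical(pl4$p_value, pl5$p_value)
  expect_error(two_block_pls(X, Y[1:5, ]), "differ")
  expect_error(two_block_pls(X[1:3, ], Y[1:3, ]), "at least 4")
  expect_error(two_block_pls(X, matrix(1, 10, 3)), "zero-variance")
})

test_that("one-way ANOVA + Tukey match a hand-computed textbook fixture", {
  # three unbalanced groups, worked by direct formulas
  y <- c(6.9, 5.4, 5.8, 4.6, 4.0,
         8.3, 6.8, 7.8, 9.2, 6.5,
         8.0, 10.5, 8.1, 6.9)
  g <- rep(c("g1", "g2", "g3"), c(5, 5, 4))
  res <- anova_tukey(y, g)
  ni <- tapply(y, g, length)
  mi <- tapply(y, g, mean)
  gm <- mean(y)
  ss_b <- sum(ni * (mi - gm)^2)
  ss_w <- sum((y - mi[g])^2)
  df_b <- 2; df_w <- length(y) - 3
  f_hand <- (ss_b / df_b) / (ss_w / df_w)
  expect_equal(res$anova$F[1], f_hand, tolerance = 1e-6)
  expect_equal(res$anova$p[1], pf(f_hand, df_b, df_w, lower.tail = FALSE),
               tolerance = 1e-6)
  # Tukey-Kramer for one pair by hand
  mse <- ss_w / df_w
  se <- sqrt(mse / 2 * (1 / ni["g1"] + 1 / ni["g3"]))
  q_obs <- abs(mi["g3"] - mi["g1"]) / se
  p_hand <- ptukey(q_obs, nmeans = 3, df = df_w, lower.tail = FALSE)
  row <- res$tukey[res$tukey$pair == "g3-g1", ]
  expect_equal(row$p_adj, unname(p_hand), tolerance = 1e-6)
  expect_equal(row$diff, unname(mi["g3"] - mi["g1"]), tolerance = 1e-9)

  # two groups: Tukey p equals the pooled-variance two-sample p
  set.seed(25)
  y2 <- rnorm(20)
  g2 <- rep(c("a", "b"), each = 10)
  res2 <- anova_tukey(y2, g2)
  tt <- t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(res2$tukey$p_adj, tt$p.value, tolerance = 1e-9)

  # degenerate inputs
  expect_warning(rc <- anova_tukey(rep(1, 8), rep(c("a", "b"), 4)),
                 "identical")
  expect_equal(rc$anova$p[1], 1)
  expect_warning(r0 <- anova_tukey(rep(c(1, 2), each = 4),
                                   rep(c("a", "b"), each = 4)),
                 "zero residual")
  expect_equal(r0$anova$p[1], 0)
})

test_that("dimorphism suite recovers generated size and shape effects", {
  # size offset only: SSD detected, sex shape R^2 near zero
  d_size <- generate_dataset(generator_spec(
    n = c(F = 40, M = 40), sex_size_offset = 0.06, sex_shape_norm = 0,
    seed = 26))
  s1 <- sexual_dimorphism_suite(d_size, n_perm = 100, seed = 1)
  expect_lte(s1$SSD$anova$p[1], 0.01)
  expect_lt(s1$SShD["sex", "R2"], 0.02)

  # sex shape R^2 increases with the injected offset norm
  r2 <- vapply(c(0, 0.03, 0.09), function(nrm) {
    d <- generate_dataset(generator_spec(n = c(F = 25, M = 25),
                                         sex_shape_norm = nrm, seed = 27))
    sexual_dimorphism_suite(d, n_perm = 50, seed = 2)$SShD["sex", "R2"]
  }, numeric(1))
  expect_true(all(diff(r2) > 0))

  # single-sex data is refused
  d1 <- generate_dataset(generator_spec(n = c(F = 10), seed = 28))
  expect_error(sexual_dimorphism_suite(d1), "single-sex")

  # balanced resampling reports counts out of T
  d_b <- generate_dataset(generator_spec(n = c(F = 20, M = 10), seed = 29))
  sb <- sexual_dimorphism_suite(d_b, n_perm = 50, seed = 3, balance = TRUE,
                                balance_T = 5)
  expect_lte(sb$balance$n_sig_sshd, 5L)
  expect_identical(sb$balance$T, 5)
})
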