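test_that("bending energy matrix: symmetric, PSD, annihilates affine terms", {
  for (s in 1:10) {
    ref <- rand_config(8 + s, seed = 40 + s)
    B <- bending_energy_matrix(ref)$matrix
    expect_lt(max(abs(B - t(B))), 1e-10)
    expect_gt(min(eigen(B, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
    expect_lt(max(abs(B %*% cbind(1, ref))), 1e-8)
  }
  # any affine transform of the reference carries zero bending energy
  ref <- rand_config(10, seed = 50)
  A <- matrix(c(1.2, 0.3, -0.1, 0.8), 2, 2)
  aff <- ref %*% A + matrix(c(2, -1), 10, 2, byrow = TRUE)
  expect_lt(bending_energy(ref, aff), 1e-8)
  expect_error(bending_energy_matrix(cbind(1:6, 2 * (1:6) + 1)), "collinear")
})

test_that("single-point displacement energy matches an independent L-matrix solve", {
  ref <- rand_config(12, seed = 51)
  h <- rep(0, 12); h[5] <- 0.37          # displace one landmark height
  B <- bending_energy_matrix(ref)$matrix
  e_quad <- drop(h %*% B %*% h)
  # independent route: solve the interpolation system for weights w and
  # use E = w' K w
  rs <- rowSums(ref^2)
  d2 <- outer(rs, rs, `+`) - 2 * tcrossprod(ref)
  K <- ifelse(d2 < 1e-300, 0, d2 * log(pmax(d2, 1e-300)))
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  w <- solve(L, c(h, 0, 0, 0))[1:12]
  expect_equal(e_quad, drop(w %*% K %*% w), tolerance = 1e-10)
})

test_that("TPS warp interpolates exactly and is affine-exact", {
  ref <- rand_config(9, seed = 52)
  tgt <- ref + 0.2 * rand_config(9, seed = 53)
  w <- tps_warp(ref, tgt)
  expect_lt(max(abs(predict(w, ref) - tgt)), 1e-9)
  # identity warp
  wid <- tps_warp(ref, ref)
  grid <- as.matrix(expand.grid(seq(-2, 2, length.out = 8),
                                seq(-2, 2, length.out = 8)))
  expect_lt(max(abs(predict(wid, grid) - grid)), 1e-9)
  # affine target: warp equals the affine map everywhere
  A <- matrix(c(0.9, -0.2, 0.4, 1.1), 2, 2)
  b <- c(0.5, -1)
  waff <- tps_warp(ref, ref %*% A + matrix(b, 9, 2, byrow = TRUE))
  expect_lt(max(abs(predict(waff, grid) -
                    (grid %*% A + matrix(b, nrow(grid), 2, byrow = TRUE)))),
            1e-8)
})

test_that("warped grid matches a directly coded radial-basis evaluation", {
  ref <- rand_config(11, seed = 54)
  tgt <- ref + 0.15 * rand_config(11, seed = 55)
  w <- tps_warp(ref, tgt)
  g <- as.matrix(expand.grid(seq(-1.5, 1.5, length.out = 20),
                             seq(-1.5, 1.5, length.out = 20)))
  direct <- matrix(NA_real_, nrow(g), 2)
  for (i in seq_len(nrow(g))) {
    out <- w$affine[1, ] + g[i, 1] * w$affine[2, ] + g[i, 2] * w$affine[3, ]
    for (j in seq_len(nrow(ref))) {
      r2 <- sum((g[i, ] - ref[j, ])^2)
      u <- if (r2 > 0) r2 * log(r2) else 0
      out <- out + u * w$weights[j, ]
    }
    direct[i, ] <- out
  }
  expect_lt(max(abs(predict(w, g) - direct)), 1e-10)
})

test_that("sliding: fixed points untouched, zero move at the optimum, oracle agreement", {
  d <- tiny_dataset(seed = 12)
  g <- gpa(d, slide = FALSE)
  fixed <- setdiff(seq_len(d$k), d$sliders$slide)
  slid <- slide_semilandmarks(g$aligned, g$consensus, d$sliders)
  expect_identical(unname(slid[fixed, , ]), unname(g$aligned[fixed, , ]))

  # a specimen identical to the consensus does not slide
  a1 <- array(rep(center_scale_config(g$consensus), 2), dim = c(d$k, 2, 2))
  out <- slide_semilandmarks(a1, center_scale_config(g$consensus), d$sliders)
  expect_lt(max(abs(out - a1)), 1e-10)

  # single slider: closed form equals a fine 1D line search on the energy
  cons <- center_scale_config(g$consensus)
  one <- d$sliders[3, ]
  spec1 <- g$aligned[, , 1, drop = FALSE]
  res <- slide_semilandmarks(spec1, cons, one)
  B <- bending_energy_matrix(cons)$matrix
  xi <- g$aligned[, , 1]
  dvec <- xi[one$after, ] - xi[one$before, ]
  dvec <- dvec / sqrt(sum(dvec^2))
  energy_at <- function(t) {
    z <- xi
    z[one$slide, ] <- z[one$slide, ] + t * dvec
    bending_energy(cons, z - cons, be = list(matrix = B))
  }
  # coarse-to-fine search down to 1e-6 displacement resolution
  ts <- seq(-0.2, 0.2, by = 1e-3)
  t0 <- ts[which.min(vapply(ts, energy_at, numeric(1)))]
  ts <- seq(t0 - 2e-3, t0 + 2e-3, by = 1e-6)
  t_star <- ts[which.min(vapply(ts, energy_at, numeric(1)))]
  t_closed <- unname((res[one$slide, 1, 1] - xi[one$slide, 1]) / dvec[1])
  expect_lt(abs(t_closed - t_star), 1e-6)
})

test_that("each sliding pass is non-increasing in bending energy", {
  d <- tiny_dataset(n = c(F = 10, M = 10), seed = 13)
  g <- gpa(d, slide = FALSE)
  cons <- center_scale_config(g$consensus)
  be <- bending_energy_matrix(cons)
  cur <- g$aligned
  for (pass in 1:3) {
    nxt <- slide_semilandmarks(cur, cons, d$sliders)
    for (i in seq_len(dim(cur)[3])) {
      expect_lte(bending_energy(cons, nxt[, , i] - cons, be = be),
                 bending_energy(cons, cur[, , i] - cons, be = be) + 1e-12)
    }
    cur <- nxt
  }
  # coincident neighbours are reported with specimen and slider row
  bad <- g$aligned
  bad[d$sliders$before[1], , 2] <- bad[d$sliders$after[1], , 2]
  expect_error(slide_semilandmarks(bad, cons, d$sliders),
               "specimen 2, slider row 1")
})
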