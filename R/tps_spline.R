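#' Thin-plate-spline bending energy matrix
#'
#' Builds the bending-energy matrix of a 2D reference configuration
#' under the thin-plate-spline model with kernel `U(r) = r^2 log r^2`:
#' the upper-left `k x k` block of the inverse of the TPS system matrix
#' `L = [[K, Q], [Q', 0]]`, where `K[i,j] = U(|p_i - p_j|)` and
#' `Q = [1 | x | y]`. The quadratic form `h' B h` is the bending energy
#' of a deformation whose component heights at the landmarks are `h`;
#' it is zero exactly for affine deformations.
#'
#' @param reference a `k x 2` matrix, not collinear.
#' @return An object of class `bending_energy_matrix` with elements
#'   `matrix` (`k x k`, symmetric positive semidefinite) and
#'   `reference`.
#' @export
bending_energy_matrix <- function(reference) {
  reference <- as_config(reference)
  k <- nrow(reference)
  if (k < 3L) stop("TPS requires at least 3 landmarks")
  L <- tps_system_matrix(reference)
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system: reference landmarks are collinear or coincident",
         call. = FALSE))
  B <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  B <- (B + t(B)) / 2
  structure(list(matrix = B, reference = reference),
            class = "bending_energy_matrix")
}

tps_kernel <- function(r2) {
  u <- r2 * log(r2)
  u[r2 < .Machine$double.eps] <- 0
  u
}

tps_system_matrix <- function(reference) {
  k <- nrow(reference)
  rs <- rowSums(reference^2)
  d2 <- outer(rs, rs, `+`) - 2 * tcrossprod(reference)
  d2[d2 < 0] <- 0
  K <- tps_kernel(d2)
  Q <- cbind(1, reference)
  rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
}

#' Bending energy of a deformation between two configurations
#'
#' @param reference,target `k x 2` matrices in correspondence.
#' @param be optionally a precomputed [bending_energy_matrix()] of
#'   `reference`.
#' @return The summed bending energy of the x and y height functions of
#'   the deformation carrying `reference` to `target` (non-negative;
#'   zero for affine deformations).
#' @export
bending_energy <- function(reference, target, be = NULL) {
  if (is.null(be)) be <- bending_energy_matrix(reference)
  B <- be$matrix
  target <- as_config(target)
  sum(target[, 1L] %*% B %*% target[, 1L],
      target[, 2L] %*% B %*% target[, 2L])
}

#' Thin-plate-spline warp between two configurations
#'
#' Solves the TPS interpolation problem mapping `reference` exactly onto
#' `target`; the returned warp can be evaluated at arbitrary points with
#' `predict()`, which is how deformation grids are produced.
#'
#' @param reference,target `k x 2` matrices in correspondence;
#'   `reference` must not be collinear.
#' @return An object of class `tps_warp` with elements `reference`,
#'   `target`, `weights` (`k x 2`) and `affine` (`3 x 2`; constant, x
#'   and y rows).
#' @export
tps_warp <- function(reference, target) {
  reference <- as_config(reference)
  target <- as_config(target)
  if (nrow(reference) != nrow(target))
    stop("reference and target differ in landmark count")
  k <- nrow(reference)
  L <- tps_system_matrix(reference)
  rhs <- rbind(target, matrix(0, 3L, 2L))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system: reference landmarks are collinear or coincident",
         call. = FALSE))
  structure(list(reference = reference, target = target,
                 weights = sol[seq_len(k), , drop = FALSE],
                 affine = sol[k + 1:3, , drop = FALSE]),
            class = "tps_warp")
}

#' Evaluate a TPS warp at arbitrary points
#'
#' @param object a [tps_warp()].
#' @param points an `m x 2` matrix of evaluation points.
#' @param ... unused.
#' @return An `m x 2` matrix of warped points; at the reference
#'   landmarks the warp interpolates the target exactly.
#' @export
predict.tps_warp <- function(object, points, ...) {
  pts <- as_config(points)
  ref <- object$reference
  # squared distances from each evaluation point to each reference landmark
  d2 <- outer(rowSums(pts^2), rowSums(ref^2), `+`) - 2 * pts %*% t(ref)
  d2[d2 < 0] <- 0
  U <- tps_kernel(d2)
  U %*% object$weights + cbind(1, pts) %*% object$affine
}

#' Slide semilandmarks by the bending-energy criterion
#'
#' Displaces each sliding semilandmark along its tangent direction (the
#' unit chord from its `before` to its `after` neighbour) by the amount
#' that minimizes the thin-plate-spline bending energy of the
#' specimen-to-consensus deformation. The displacement is solved jointly
#' for all sliders of a specimen as one linear system in the
#' bending-energy matrix of the consensus. Fixed landmarks are never
#' moved by the sliding step itself.
#'
#' @param aligned `k x 2 x n` array of superimposed configurations.
#' @param consensus `k x 2` consensus shape the bending energy is
#'   measured against.
#' @param sliders slider table (`before`, `slide`, `after`; 1-based).
#' @param iterations number of sliding passes.
#' @param resuperimpose re-center, re-scale and re-rotate specimens onto
#'   a recomputed consensus between passes (on by default for more than
#'   one pass; [gpa()] interleaves its own superimposition instead).
#' @param cap trust-region bound: the fraction of a semilandmark's
#'   smallest half-chord it may move in one pass. Guards the
#'   near-zero-energy collective drift mode of the bending-energy
#'   criterion; ordinary (small) slides are unaffected.
#' @return The updated `k x 2 x n` array.
#' @export
slide_semilandmarks <- function(aligned, consensus, sliders,
                                iterations = 1,
                                resuperimpose = iterations > 1,
                                cap = 0.5) {
  if (!is.array(aligned) || length(dim(aligned)) != 3L)
    stop("'aligned' must be a k x 2 x n array")
  k <- dim(aligned)[1L]
  sliders <- validate_sliders(sliders, k)
  consensus <- as_config(consensus)
  for (pass in seq_len(iterations)) {
    aligned <- slide_pass(aligned, consensus, sliders, cap = cap)
    if (resuperimpose && pass < iterations) {
      n <- dim(aligned)[3L]
      for (i in seq_len(n)) {
        ci <- center_scale_config(aligned[, , i])
        aligned[, , i] <- opa_align(ci, consensus)$aligned
      }
      consensus <- mean_shape(aligned)
      consensus <- consensus / sqrt(sum(consensus^2))
    }
  }
  aligned
}

# One joint bending-energy sliding pass for all specimens against a
# fixed consensus. For specimen displacement v (per coordinate block)
# and tangent matrix T, minimizes (v + T t)' (B (+) B) (v + T t) in t.
slide_pass <- function(aligned, consensus, sliders, cap = 0.5) {
  k <- dim(aligned)[1L]
  n <- dim(aligned)[3L]
  X <- matrix(aligned[, 1L, ], k, n)
  Y <- matrix(aligned[, 2L, ], k, n)
  out <- slide_core(X, Y, consensus[, 1L], consensus[, 2L],
                    sliders$slide, sliders$before, sliders$after,
                    cap = cap)
  aperm(array(c(out$X, out$Y), dim = c(k, n, 2L)), c(1L, 3L, 2L))
}

# Vectorized sliding core on k x n coordinate matrices; B is computed
# from the consensus unless supplied. The joint bending-energy
# minimizer has a near-zero-energy mode (collective drift of a whole
# curve along itself), so the Newton step is trust-regioned: each
# specimen's slide vector is scaled uniformly so that no semilandmark
# moves more than `cap` times its smallest half-chord in one pass.
# Scaling a Newton step on a convex quadratic keeps the step a strict
# descent direction, so per-pass energy monotonicity is preserved;
# small slides (the usual regime) are unaffected.
slide_core <- function(X, Y, cx, cy, si, bi, ai, B = NULL, cap = 0.5) {
  if (is.null(B)) B <- bending_energy_matrix(cbind(cx, cy))$matrix
  DX <- X[ai, , drop = FALSE] - X[bi, , drop = FALSE]
  DY <- Y[ai, , drop = FALSE] - Y[bi, , drop = FALSE]
  LEN <- sqrt(DX^2 + DY^2)
  if (any(LEN < 1e-12)) {
    bad <- which(LEN < 1e-12, arr.ind = TRUE)[1L, ]
    stop("zero-length tangent for specimen ", bad[2L], ", slider row ",
         bad[1L], " (coincident neighbours)")
  }
  DX <- DX / LEN
  DY <- DY / LEN
  BVx <- (B %*% X - B %*% cx %*% matrix(1, 1L, ncol(X)))[si, , drop = FALSE]
  BVy <- (B %*% Y - B %*% cy %*% matrix(1, 1L, ncol(Y)))[si, , drop = FALSE]
  Bs <- B[si, si, drop = FALSE]
  ridge <- diag(1e-10 * mean(diag(Bs)), length(si))
  moved <- 0
  for (i in seq_len(ncol(X))) {
    dx <- DX[, i]; dy <- DY[, i]
    g <- dx * BVx[, i] + dy * BVy[, i]
    H <- Bs * (tcrossprod(dx) + tcrossprod(dy))
    t_hat <- tryCatch(-solve(H, g), error = function(e) -solve(H + ridge, g))
    tmax <- max(abs(t_hat))
    if (tmax > 0) {
      alpha <- min(1, cap * min(LEN[, i]) / 2 / tmax)
      t_hat <- alpha * t_hat
    }
    X[si, i] <- X[si, i] + dx * t_hat
    Y[si, i] <- Y[si, i] + dy * t_hat
    moved <- moved + sum(t_hat^2)
  }
  list(X = X, Y = Y, moved = moved)
}

#' Deformation grid under a TPS warp
#'
#' Builds a rectangular grid spanning the reference configuration (with
#' a proportional margin) and warps it, the classic D'Arcy Thompson
#' style visualization of shape change.
#'
#' @param warp a [tps_warp()].
#' @param nx,ny grid resolution.
#' @param margin fractional margin added around the reference bounding
#'   box.
#' @return A data frame with columns `x`, `y` (grid before warping) and
#'   `wx`, `wy` (after), of class `deformation_grid`.
#' @export
deformation_grid <- function(warp, nx = 20, ny = 20, margin = 0.1) {
  ref <- warp$reference
  rx <- range(ref[, 1L]); ry <- range(ref[, 2L])
  mx <- diff(rx) * margin; my <- diff(ry) * margin
  g <- expand.grid(x = seq(rx[1L] - mx, rx[2L] + mx, length.out = nx),
                   y = seq(ry[1L] - my, ry[2L] + my, length.out = ny))
  w <- predict(warp, as.matrix(g))
  out <- data.frame(x = g$x, y = g$y, wx = w[, 1L], wy = w[, 2L])
  class(out) <- c("deformation_grid", "data.frame")
  out
}

#' Correlation of two deformation-grid displacement fields
#'
#' @param g1,g2 `deformation_grid` data frames over the same grid.
#' @return Pearson correlation of the concatenated x/y displacement
#'   fields; the sign of `g2`'s field is chosen to give the larger
#'   magnitude (PC orientations are arbitrary).
#' @export
grid_field_correlation <- function(g1, g2) {
  d1 <- c(g1$wx - g1$x, g1$wy - g1$y)
  d2 <- c(g2$wx - g2$x, g2$wy - g2$y)
  r <- stats::cor(d1, d2)
  if (is.na(r)) return(NA_real_)
  max(r, -r)
}
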