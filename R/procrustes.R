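#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of
#' the summed squared distances of the landmarks from their centroid.
#' It is geometrically independent of shape and is the quantity that
#' generalized Procrustes analysis divides out.
#'
#' @param config a `k x 2` coordinate matrix.
#' @return A non-negative number; 0 only if all landmarks coincide.
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(config) {
  x <- as_config(config)
  if (!all(is.finite(x))) stop("non-finite coordinates")
  sqrt(sum(sweep(x, 2L, colMeans(x))^2))
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Finds the rotation (optionally allowing a reflection) minimizing the
#' summed squared coordinate differences between `target` and
#' `reference`, via the singular value decomposition of the 2 x 2
#' cross-product matrix with determinant sign correction. Both inputs
#' are expected centered and at unit centroid size; use
#' [procrustes_distance()] for raw configurations.
#'
#' @param target,reference centered, unit-centroid-size `k x 2` matrices.
#' @param allow_reflection if `TRUE` the optimal orthogonal matrix may
#'   have determinant -1; if `FALSE` (default) a proper rotation is
#'   enforced.
#' @return A list with `aligned` (the rotated target), `rotation` (the
#'   2 x 2 matrix applied on the right) and `distance` (the minimized
#'   root-sum-of-squares, i.e. the partial Procrustes distance).
#' @export
opa_align <- function(target, reference, allow_reflection = FALSE) {
  target <- as_config(target)
  reference <- as_config(reference)
  if (nrow(target) != nrow(reference))
    stop("configurations differ in landmark count")
  M <- crossprod(target, reference)
  sv <- svd(M)
  if (max(sv$d) < 1e-14) stop("degenerate cross-product matrix")
  s <- c(1, 1)
  if (!allow_reflection && det(sv$u) * det(sv$v) < 0) s[2L] <- -1
  R <- sv$u %*% diag(s) %*% t(sv$v)
  aligned <- target %*% R
  list(aligned = aligned, rotation = R,
       distance = sqrt(sum((aligned - reference)^2)))
}

# Closed-form 2D rotation of every specimen onto the consensus; X, Y are
# k x n matrices of x and y coordinates, cx, cy the consensus columns.
# Equivalent to the SVD solution of opa_align for proper rotations.
rotate_all_to <- function(X, Y, cx, cy) {
  a <- colSums(X * cx + Y * cy)
  b <- colSums(Y * cx - X * cy)
  h <- sqrt(a^2 + b^2)
  if (any(h < 1e-14)) stop("degenerate configuration during rotation")
  co <- rep(a / h, each = nrow(X))
  si <- rep(b / h, each = nrow(X))
  list(X = co * X + si * Y, Y = co * Y - si * X)
}

#' Generalized Procrustes analysis
#'
#' Translates every configuration to the origin, scales it to unit
#' centroid size, and iteratively rotates all configurations onto their
#' consensus (partial Procrustes superimposition: no per-specimen
#' rescaling during rotation, reflections disallowed), recomputing the
#' consensus until its summed squared change falls below `tol`. With
#' `slide = TRUE` and a slider table present, bending-energy sliding of
#' the semilandmarks ([slide_semilandmarks()]) is interleaved with full
#' GPA passes until the joint procedure converges or `slide_passes` is
#' reached.
#'
#' @param x a [landmark_dataset] or a `k x 2 x n` array.
#' @param sliders optional slider table; defaults to the dataset's own.
#' @param slide logical; slide semilandmarks by the bending-energy
#'   criterion. Defaults to `TRUE` when a slider table is available.
#' @param max_iter maximum consensus iterations per GPA pass.
#' @param tol convergence tolerance on the summed squared change of the
#'   consensus between iterations.
#' @param slide_passes number of sliding passes interleaved with GPA.
#' @return An object of class `gpa_result`: `aligned` (`k x 2 x n`,
#'   centered, unit centroid size, consensus-registered),
#'   `centroid_sizes` (original units, computed from the raw
#'   coordinates, identical whether or not sliding is enabled),
#'   `consensus` (the coordinate-wise mean of the aligned specimens),
#'   `iterations`, `final_change`, `slid`, and the `sliders` used.
#' @examples
#' d <- generate_dataset(generator_spec(n = c(F = 10, M = 10), seed = 1))
#' g <- gpa(d)
#' g$iterations
#' @export
gpa <- function(x, sliders = NULL, slide = NULL, max_iter = 100,
                tol = 1e-10, slide_passes = 5) {
  if (inherits(x, "landmark_dataset")) {
    if (is.null(sliders)) sliders <- x$sliders
    a <- x$coords
  } else {
    a <- x
    if (!is.array(a) || length(dim(a)) != 3L || dim(a)[2L] != 2L)
      stop("'x' must be a landmark_dataset or a k x 2 x n array")
  }
  k <- dim(a)[1L]
  n <- dim(a)[3L]
  if (n < 2L) stop("GPA needs at least 2 specimens")
  if (is.null(slide)) slide <- !is.null(sliders) && nrow(sliders) > 0L
  if (slide && (is.null(sliders) || !nrow(sliders))) {
    warning("slide = TRUE but no sliders defined; proceeding without sliding",
            call. = FALSE)
    slide <- FALSE
  }
  if (slide) sliders <- validate_sliders(sliders, k)

  cs <- apply(a, 3L, centroid_size)
  if (any(cs < .Machine$double.eps * k))
    stop("degenerate specimen (zero centroid size)")
  X <- matrix(a[, 1L, ], k, n)
  Y <- matrix(a[, 2L, ], k, n)
  X <- X - rep(colMeans(X), each = k)
  Y <- Y - rep(colMeans(Y), each = k)
  sc <- rep(cs, each = k)
  X <- X / sc
  Y <- Y / sc

  unit_consensus <- function(X, Y) {
    cx <- rowMeans(X); cy <- rowMeans(Y)
    s <- sqrt(sum(cx^2 + cy^2))
    list(cx = cx / s, cy = cy / s)
  }

  total_iter <- 0L
  final_change <- Inf
  cons <- list(cx = X[, 1L], cy = Y[, 1L])

  gpa_pass <- function() {
    for (it in seq_len(max_iter)) {
      r <- rotate_all_to(X, Y, cons$cx, cons$cy)
      X <<- r$X; Y <<- r$Y
      new_cons <- unit_consensus(X, Y)
      final_change <<- sum((new_cons$cx - cons$cx)^2 +
                           (new_cons$cy - cons$cy)^2)
      cons <<- new_cons
      total_iter <<- total_iter + 1L
      if (final_change < tol) return(invisible(TRUE))
    }
    stop(sprintf(
      "GPA failed to converge in %d iterations (last change %.3e)",
      max_iter, final_change))
  }

  gpa_pass()
  if (slide) {
    si <- sliders$slide
    bi <- sliders$before
    ai <- sliders$after
    for (pass in seq_len(slide_passes)) {
      out <- slide_core(X, Y, cons$cx, cons$cy, si, bi, ai)
      X <- out$X
      Y <- out$Y
      # sliding changes centroids/sizes slightly; re-center, re-scale
      X <- X - rep(colMeans(X), each = k)
      Y <- Y - rep(colMeans(Y), each = k)
      s <- rep(sqrt(colSums(X^2) + colSums(Y^2)), each = k)
      X <- X / s
      Y <- Y / s
      gpa_pass()
      if (out$moved < tol) break
    }
  }

  aligned <- aperm(array(c(X, Y), dim = c(k, n, 2L)), c(1L, 3L, 2L))
  ids <- dimnames(a)[[3L]]
  dimnames(aligned) <- list(NULL, c("x", "y"), ids)
  names(cs) <- ids
  consensus <- cbind(x = rowMeans(X), y = rowMeans(Y))
  structure(
    list(aligned = aligned, centroid_sizes = cs, consensus = consensus,
         iterations = total_iter, final_change = final_change,
         slid = slide, sliders = if (slide) sliders else NULL),
    class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  n <- dim(x$aligned)[3L]
  cat("GPA result: ", n, " specimens, ", dim(x$aligned)[1L],
      " landmarks\n", sep = "")
  cat(sprintf("  iterations: %d, final change: %.2e, semilandmarks slid: %s\n",
              x$iterations, x$final_change, x$slid))
  invisible(x)
}

#' Mean (consensus) shape of superimposed configurations
#'
#' @param x a `gpa_result`, or a `k x 2 x n` array of superimposed
#'   configurations.
#' @return The coordinate-wise mean, a `k x 2` matrix.
#' @export
mean_shape <- function(x) {
  if (inherits(x, "gpa_result")) x <- x$aligned
  if (is.matrix(x)) return(as_config(x))
  if (!is.array(x) || length(dim(x)) != 3L) stop("expected a k x 2 x n array")
  if (dim(x)[3L] < 1L) stop("empty input")
  m <- apply(x, c(1L, 2L), mean)
  colnames(m) <- c("x", "y")
  m
}

#' Procrustes distance between two shapes
#'
#' Centers and scales both configurations to unit centroid size,
#' optimally rotates one onto the other, and returns the minimized
#' root-sum-of-squared coordinate differences (the partial Procrustes
#' distance; `type = "full"` gives the full Procrustes distance, the
#' sine of the Procrustes angle, as an option).
#'
#' @param a,b `k x 2` coordinate matrices with the same `k`.
#' @param type `"partial"` (default) or `"full"`.
#' @param allow_reflection passed to [opa_align()].
#' @return A non-negative number; 0 iff the shapes are identical up to
#'   translation, rotation and scale.
#' @export
procrustes_distance <- function(a, b, type = c("partial", "full"),
                                allow_reflection = FALSE) {
  type <- match.arg(type)
  a <- center_scale_config(a)
  b <- center_scale_config(b)
  if (nrow(a) != nrow(b)) stop("shapes differ in landmark count")
  al <- opa_align(a, b, allow_reflection = allow_reflection)
  if (type == "partial") return(al$distance)
  cosr <- min(1, max(-1, sum(al$aligned * b)))
  sqrt(max(0, 1 - cosr^2))
}
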