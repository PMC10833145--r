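# Convex hull helpers for morphospace occupation summaries.

#' Convex hull of 2D points
#'
#' @param points an `m x 2` matrix or data frame.
#' @return The hull vertices in counter-clockwise order (`h x 2` matrix).
#' @export
convex_hull <- function(points) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  h <- rev(grDevices::chull(p))  # chull returns clockwise; reverse to CCW
  p[h, , drop = FALSE]
}

#' Area of a simple polygon
#'
#' Shoelace formula; vertices in order (either orientation).
#'
#' @param poly an `h x 2` matrix of vertices.
#' @return Non-negative area.
#' @export
polygon_area <- function(poly) {
  p <- as.matrix(poly)
  if (nrow(p) < 3L) return(0)
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex
# polygon `clip` (both CCW). Returns the intersection polygon.
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[e, ]
    b <- clip[if (e == nc) 1L else e + 1L, ]
    inside <- function(p)
      (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L]) >= -1e-12
    isect <- function(p, q) {
      dc <- a - b
      dp <- p - q
      n1 <- a[1L] * b[2L] - a[2L] * b[1L]
      n2 <- p[1L] * q[2L] - p[2L] * q[1L]
      den <- dc[1L] * dp[2L] - dc[2L] * dp[1L]
      c(n1 * dp[1L] - n2 * dc[1L], n1 * dp[2L] - n2 * dc[2L]) / den
    }
    inp <- out
    out <- matrix(numeric(0), 0L, 2L)
    np <- nrow(inp)
    for (j in seq_len(np)) {
      p <- inp[j, ]
      q <- inp[if (j == np) 1L else j + 1L, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) out <- rbind(out, p)
      if (pin != qin) out <- rbind(out, isect(p, q))
    }
  }
  out
}

#' Overlap of two convex hulls (Jaccard index)
#'
#' Intersection area over union area of the convex hulls of two point
#' sets, a simple measure of shared morphospace occupation.
#'
#' @param points1,points2 `m x 2` point sets.
#' @return Jaccard index in `[0, 1]`.
#' @export
hull_jaccard <- function(points1, points2) {
  h1 <- convex_hull(points1)
  h2 <- convex_hull(points2)
  a1 <- polygon_area(h1)
  a2 <- polygon_area(h2)
  ai <- polygon_area(clip_convex(h1, h2))
  if (a1 + a2 - ai <= 0) return(0)
  ai / (a1 + a2 - ai)
}
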