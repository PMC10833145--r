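#' Assemble a landmark dataset
#'
#' Bundles a set of 2D landmark configurations with an optional slider
#' table (for semilandmarks) and an optional classifier table into a
#' validated `landmark_dataset` object, the common input of [gpa()],
#' [run_rarefaction()] and the statistical layer.
#'
#' @param coords a `k x 2 x n` numeric array (landmarks in rows, x/y in
#'   columns, specimens along the third dimension), or a list of `n`
#'   `k x 2` matrices sharing the same `k`.
#' @param ids character vector of `n` unique specimen identifiers. If
#'   `coords` carries dimnames on its third dimension they are used as
#'   the default.
#' @param sliders `NULL` or a data frame with integer columns
#'   `before`, `slide`, `after` (1-based landmark indices) defining, for
#'   each sliding semilandmark, its two neighbours along the curve.
#' @param classifiers `NULL` or a data frame with at least an `id`
#'   column; columns `species`, `sex` and `view` are conventionally
#'   present. One row per specimen, matched by `id`.
#' @param curves optional list of integer vectors, each giving the point
#'   indices of one digitized curve (semilandmark run) in order. Kept so
#'   that [write_tps()] can re-emit CURVES blocks.
#' @param scale optional numeric vector of per-specimen scale factors
#'   already applied to the coordinates (recorded for provenance only).
#'
#' @return An object of class `landmark_dataset`: a list with elements
#'   `coords`, `ids`, `sliders`, `classifiers`, `curves`, `scale`,
#'   `k` and `n`.
#'
#' @details Validation enforces: `k >= 3` landmarks, all coordinates
#'   finite, at least `n >= 2` specimens with a common `k`, unique ids,
#'   slider indices in range with every `slide` index appearing at most
#'   once and never equal to its own neighbours, and a total, unique
#'   classifier join when classifiers are supplied. Configurations whose
#'   landmarks coincide exactly after centering and unit scaling trigger
#'   a warning (they are legal but usually indicate digitizing errors).
#'
#' @seealso [read_tps()], [make_sliders_from_curves()]
#' @export
landmark_dataset <- function(coords, ids = NULL, sliders = NULL,
                             classifiers = NULL, curves = NULL,
                             scale = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    ks <- vapply(coords, nrow, integer(1))
    if (length(unique(ks)) != 1L)
      stop("all specimens must share the same number of landmarks; got k = ",
           paste(sort(unique(ks)), collapse = ", "))
    coords <- array(unlist(coords),
                    dim = c(ks[1L], 2L, length(ks)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2L] != 2L)
    stop("'coords' must be a k x 2 x n array")
  k <- dim(coords)[1L]
  n <- dim(coords)[3L]
  if (k < 3L) stop("at least 3 landmarks are required (k = ", k, ")")
  if (n < 2L) stop("at least 2 specimens are required (n = ", n, ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates in dataset")

  if (is.null(ids)) ids <- dimnames(coords)[[3L]]
  if (is.null(ids)) ids <- sprintf("spec_%03d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) must equal the number of specimens")
  if (anyDuplicated(ids)) stop("specimen ids must be unique")
  dimnames(coords) <- list(NULL, c("x", "y"), ids)

  if (!is.null(sliders)) sliders <- validate_sliders(sliders, k)
  if (!is.null(classifiers)) classifiers <- validate_classifiers(classifiers, ids)
  if (!is.null(curves)) {
    for (cv in curves)
      if (any(cv < 1L | cv > k)) stop("curve point index out of range")
  }
  if (!is.null(scale)) {
    scale <- rep_len(as.numeric(scale), n)
    if (any(!is.finite(scale) | scale <= 0)) stop("scale factors must be positive")
  }

  check_coincident_landmarks(coords, ids)

  structure(
    list(coords = coords, ids = ids, sliders = sliders,
         classifiers = classifiers, curves = curves, scale = scale,
         k = k, n = n),
    class = "landmark_dataset")
}

validate_sliders <- function(sliders, k) {
  sliders <- as.data.frame(sliders)
  need <- c("before", "slide", "after")
  if (!all(need %in% names(sliders)))
    stop("slider table must have columns before, slide, after")
  sliders <- sliders[, need]
  for (cc in need) sliders[[cc]] <- as.integer(sliders[[cc]])
  idx <- as.matrix(sliders)
  if (any(idx < 1L | idx > k))
    stop("slider index out of range 1..", k)
  if (any(sliders$slide == sliders$before | sliders$slide == sliders$after |
          sliders$before == sliders$after))
    stop("slider row indices must be distinct within each row")
  if (anyDuplicated(sliders$slide))
    stop("each sliding semilandmark may appear in at most one slider row")
  sliders
}

validate_classifiers <- function(classifiers, ids) {
  classifiers <- as.data.frame(classifiers)
  if (!"id" %in% names(classifiers))
    stop("classifier table must have an 'id' column")
  classifiers$id <- as.character(classifiers$id)
  if (anyDuplicated(classifiers$id))
    stop("classifier ids must be unique")
  missing <- setdiff(ids, classifiers$id)
  if (length(missing))
    stop("classifier table lacks rows for specimens: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  # keep only the dataset's specimens, in specimen order
  classifiers[match(ids, classifiers$id), , drop = FALSE]
}

check_coincident_landmarks <- function(coords, ids, tol = 1e-12) {
  for (i in seq_len(dim(coords)[3L])) {
    x <- center_scale_config(coords[, , i])
    d <- stats::dist(x)
    if (any(d < tol))
      warning("specimen '", ids[i],
              "' has coincident landmarks after centering and unit scaling",
              call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset: ", x$n, " specimens, ", x$k, " landmarks (2D)\n",
      sep = "")
  if (!is.null(x$sliders))
    cat("  sliding semilandmarks: ", nrow(x$sliders), "\n", sep = "")
  if (!is.null(x$curves))
    cat("  curves: ", paste(lengths(x$curves), collapse = "/"),
        " points\n", sep = "")
  if (!is.null(x$classifiers)) {
    cc <- setdiff(names(x$classifiers), "id")
    cat("  classifiers: ", paste(cc, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Subset a landmark dataset by specimen
#'
#' @param x a `landmark_dataset`.
#' @param i specimen indices or ids.
#' @param ... unused.
#' @return A `landmark_dataset` containing the selected specimens (order
#'   preserved as given); sliders, curves and classifier rows carried over.
#' @export
`[.landmark_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  if (anyNA(i)) stop("unknown specimen id in subset")
  landmark_dataset(x$coords[, , i, drop = FALSE], ids = x$ids[i],
                   sliders = x$sliders,
                   classifiers = if (!is.null(x$classifiers))
                     x$classifiers[match(x$ids[i], x$classifiers$id), ,
                                   drop = FALSE] else NULL,
                   curves = x$curves,
                   scale = if (!is.null(x$scale)) x$scale[i] else NULL)
}
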