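#' Read a TPS landmark file
#'
#' Parses landmark files in the tpsDIG dialect: per-specimen records of
#' the form `LM=<k>` followed by `k` coordinate lines, optionally
#' followed by `CURVES=<c>` with `c` blocks of `POINTS=<p>` coordinate
#' lines, and optional `IMAGE=`, `ID=` and `SCALE=` lines. Keys are
#' matched case-insensitively; unknown `KEY=` lines are skipped with a
#' warning. Curve points are appended after the fixed landmarks, in
#' curve order, so a record with `LM=14` and one 15-point curve yields a
#' 29-landmark configuration.
#'
#' When a `SCALE=` factor is present it is applied multiplicatively to
#' the record's coordinates (tpsDIG stores pixel coordinates plus a
#' pixel-to-unit scale). A slider table is generated from the curve
#' structure via [make_sliders_from_curves()]; since TPS files carry no
#' anchor information, each curve's endpoints are treated as fixed and
#' only interior curve points slide.
#'
#' @param path path to a TPS file.
#' @return A [landmark_dataset] (without classifiers).
#' @seealso [write_tps()], [make_sliders_from_curves()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  nonblank <- which(nzchar(lines_trim))
  if (!length(nonblank)) stop("empty TPS file: ", path)

  key_of <- function(s) {
    m <- regmatches(s, regexec("^([A-Za-z]+)=(.*)$", s))[[1L]]
    if (!length(m)) NULL else list(key = toupper(m[2L]), value = trimws(m[3L]))
  }
  parse_coord <- function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines_trim[i], "[,;[:space:]]+")[[1L]]))
    if (length(v) < 2L || anyNA(v[1:2]))
      stop("non-numeric coordinate at line ", i, " of ", path)
    v[1:2]
  }

  specs <- list()
  curves_tpl <- NULL
  i <- 1L
  nline <- length(lines_trim)
  record <- 0L
  while (i <= nline) {
    if (!nzchar(lines_trim[i])) { i <- i + 1L; next }
    kv <- key_of(lines_trim[i])
    if (is.null(kv) || kv$key != "LM")
      stop("expected LM=<k> at line ", i, " of ", path)
    record <- record + 1L
    k_fixed <- suppressWarnings(as.integer(kv$value))
    if (is.na(k_fixed) || k_fixed < 0L)
      stop("invalid LM count in record ", record, " (line ", i, ")")
    i <- i + 1L
    fixed <- matrix(NA_real_, k_fixed, 2L)
    for (j in seq_len(k_fixed)) {
      if (i > nline || !is.null(key_of(lines_trim[i])))
        stop("record ", record, ": expected ", k_fixed,
             " coordinate lines after LM=, found ", j - 1L)
      fixed[j, ] <- parse_coord(i)
      i <- i + 1L
    }
    curves <- list()
    id <- NULL; scale <- NA_real_; image <- NULL
    while (i <= nline) {
      if (!nzchar(lines_trim[i])) { i <- i + 1L; next }
      kv <- key_of(lines_trim[i])
      if (is.null(kv))
        stop("record ", record, ": unexpected coordinate line ", i,
             " outside LM/POINTS blocks")
      if (kv$key == "LM") break
      i <- i + 1L
      if (kv$key == "CURVES") {
        ncur <- as.integer(kv$value)
        for (ci in seq_len(ncur)) {
          while (i <= nline && !nzchar(lines_trim[i])) i <- i + 1L
          pv <- if (i <= nline) key_of(lines_trim[i]) else NULL
          if (is.null(pv) || pv$key != "POINTS")
            stop("record ", record, ": expected POINTS= for curve ", ci)
          np <- as.integer(pv$value)
          i <- i + 1L
          pts <- matrix(NA_real_, np, 2L)
          for (j in seq_len(np)) {
            if (i > nline || !is.null(key_of(lines_trim[i])))
              stop("record ", record, ", curve ", ci, ": expected ", np,
                   " points, found ", j - 1L)
            pts[j, ] <- parse_coord(i)
            i <- i + 1L
          }
          curves[[ci]] <- pts
        }
      } else if (kv$key == "ID") {
        id <- kv$value
      } else if (kv$key == "SCALE") {
        scale <- suppressWarnings(as.numeric(kv$value))
        if (is.na(scale)) stop("record ", record, ": invalid SCALE value")
      } else if (kv$key == "IMAGE") {
        image <- kv$value
      } else if (kv$key == "POINTS") {
        stop("record ", record, ": POINTS= outside a CURVES block")
      } else {
        warning("record ", record, ": ignoring unknown key '", kv$key, "='",
                call. = FALSE)
      }
    }
    coords <- rbind(fixed, do.call(rbind, curves))
    if (!nrow(coords))
      stop("record ", record, ": no coordinates")
    if (!is.na(scale)) coords <- coords * scale
    spans <- if (length(curves)) {
      off <- k_fixed
      lapply(vapply(curves, nrow, integer(1)), function(np) {
        s <- off + seq_len(np); off <<- off + np; s
      })
    } else NULL
    # all records must share curve structure; keep the first as template
    if (record == 1L) curves_tpl <- spans
    specs[[record]] <- list(coords = coords, id = id, scale = scale,
                            image = image, spans = spans)
  }

  ks <- vapply(specs, function(s) nrow(s$coords), integer(1))
  if (length(unique(ks)) != 1L)
    stop("records have differing landmark counts: ",
         paste(unique(ks), collapse = ", "))
  ids <- vapply(seq_along(specs), function(j) {
    if (!is.null(specs[[j]]$id)) specs[[j]]$id else sprintf("spec_%03d", j)
  }, character(1))
  coords <- array(unlist(lapply(specs, `[[`, "coords")),
                  dim = c(ks[1L], 2L, length(specs)))
  sliders <- if (!is.null(curves_tpl))
    make_sliders_from_curves(curves_tpl) else NULL
  landmark_dataset(coords, ids = ids, sliders = sliders,
                   curves = curves_tpl)
}

#' Write a TPS landmark file
#'
#' Emits the tpsDIG dialect understood by [read_tps()]: one record per
#' specimen with `LM=`, coordinate lines at full double precision
#' (15 significant digits), `CURVES=`/`POINTS=` blocks when the dataset
#' records curve structure, and an `ID=` line. Coordinates are written
#' as stored (any original SCALE was applied on read), so reading the
#' file back reproduces the dataset.
#'
#' @param dataset a [landmark_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (dataset$n < 1L) stop("refusing to write an empty dataset")
  curves <- dataset$curves
  fixed_idx <- if (is.null(curves)) seq_len(dataset$k)
               else setdiff(seq_len(dataset$k), unlist(curves))
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- function(m) sprintf("%.15g %.15g", m[, 1L], m[, 2L])
  for (i in seq_len(dataset$n)) {
    x <- dataset$coords[, , i]
    writeLines(sprintf("LM=%d", length(fixed_idx)), con)
    if (length(fixed_idx))
      writeLines(fmt(x[fixed_idx, , drop = FALSE]), con)
    if (!is.null(curves)) {
      writeLines(sprintf("CURVES=%d", length(curves)), con)
      for (cv in curves) {
        writeLines(sprintf("POINTS=%d", length(cv)), con)
        writeLines(fmt(x[cv, , drop = FALSE]), con)
      }
    }
    writeLines(sprintf("ID=%s", dataset$ids[i]), con)
  }
  invisible(path)
}

#' Build a slider table from curve definitions
#'
#' For each digitized curve, emits one `(before, slide, after)` row per
#' sliding semilandmark, with neighbours taken along the curve. When
#' `anchors` supplies a pair of fixed landmark indices for a curve, all
#' of that curve's points slide and the terminal points use their anchor
#' as the outer neighbour (three 6/6/18-point anchored curves give 30
#' slider rows). Without anchors the curve's own endpoints are treated
#' as fixed and only interior points slide.
#'
#' @param curve_point_spans list of integer vectors, each the ordered
#'   point indices of one curve.
#' @param anchors `NULL`, or a list (parallel to `curve_point_spans`) of
#'   `c(start_anchor, end_anchor)` landmark indices; individual entries
#'   may be `NULL` to fall back to fixed endpoints for that curve.
#' @param k optional total landmark count, used to range-check indices.
#' @return A data frame with integer columns `before`, `slide`, `after`
#'   (1-based).
#' @export
make_sliders_from_curves <- function(curve_point_spans, anchors = NULL,
                                     k = NULL) {
  if (!length(curve_point_spans)) return(NULL)
  rows <- list()
  for (ci in seq_along(curve_point_spans)) {
    span <- as.integer(curve_point_spans[[ci]])
    if (!length(span)) stop("curve ", ci, " has no points")
    anc <- if (!is.null(anchors) && length(anchors) >= ci) anchors[[ci]] else NULL
    if (!is.null(anc)) {
      if (length(anc) != 2L) stop("anchors for curve ", ci, " must be length 2")
      if (!is.null(k) && any(anc < 1L | anc > k))
        stop("anchor index out of range for curve ", ci)
      chain <- c(as.integer(anc[1L]), span, as.integer(anc[2L]))
      slide <- span
    } else {
      if (length(span) < 3L) next  # endpoints fixed, nothing slides
      chain <- span
      slide <- span[-c(1L, length(span))]
    }
    pos <- match(slide, chain)
    rows[[ci]] <- data.frame(before = chain[pos - 1L], slide = slide,
                             after = chain[pos + 1L])
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(NULL)
  rownames(out) <- NULL
  out
}

#' Read or write slider tables and classifier tables
#'
#' Side tables travel as plain CSV: sliders with 1-based columns
#' `before,slide,after`; classifiers with at least `id,species,sex,view`
#' (extra columns pass through).
#'
#' @param path a CSV file path.
#' @return `read_sliders()` a slider data frame; `read_classifiers()` a
#'   classifier data frame.
#' @export
read_sliders <- function(path) {
  df <- utils::read.csv(path)
  need <- c("before", "slide", "after")
  if (!all(need %in% names(df)))
    stop("slider CSV must have columns before,slide,after")
  df[need]
}

#' @rdname read_sliders
#' @param sliders a slider data frame.
#' @export
write_sliders <- function(sliders, path) {
  utils::write.csv(sliders, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sliders
#' @export
read_classifiers <- function(path) {
  df <- utils::read.csv(path, colClasses = c(id = "character"))
  if (!"id" %in% names(df)) stop("classifier CSV must have an 'id' column")
  df
}

#' @rdname read_sliders
#' @param classifiers a classifier data frame.
#' @export
write_classifiers <- function(classifiers, path) {
  utils::write.csv(classifiers, path, row.names = FALSE)
  invisible(path)
}
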