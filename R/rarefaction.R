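#' Seeded rarefaction of a landmark dataset
#'
#' The core sample-size experiment: specimens are repeatedly drawn
#' without replacement into fraction bins (by default 100, 75, 50, 25
#' and 10% of the sample), each subsample is superimposed on its own
#' (GPA, with semilandmark sliding if the dataset defines sliders), and
#' its consensus shape, mean log10 centroid size, and partial
#' Procrustes distance to the full-sample consensus (the "true" mean)
#' are recorded. Every draw uses its own reproducible seed,
#' `base_seed * 1e6 + bin_index * 1e4 + iteration`, recorded in the
#' output; re-running with the same arguments reproduces the records
#' exactly. Subsample sizes round half-up, so the 10% bin of n = 72 has
#' 7 specimens and of n = 81 has 8. The 100% bin is identical in every
#' iteration by construction and has distance 0.
#'
#' @param dataset a [landmark_dataset] with at least 10 specimens.
#' @param fractions bin fractions in `(0, 1]`.
#' @param T iterations per bin.
#' @param base_seed small positive integer (at most 2000, so derived
#'   seeds stay below 2^31) controlling the whole experiment.
#' @param slide slide semilandmarks within each subsample's GPA
#'   (default: yes when sliders are present).
#' @param do_shapes if `FALSE`, skip the per-subsample GPA and record
#'   only mean log10 centroid sizes (an exact fast path for
#'   centroid-size questions; `mean_shape`/`dist_to_true` are `NA`).
#' @return An object of class `rarefaction_records`: a data frame with
#'   one row per (fraction, iteration) holding `fraction`, `bin`
#'   (percent label), `iteration`, `seed`, `m`, `mean_log_cs`,
#'   `dist_to_true`; attributes `mean_shapes` (`k x 2 x n_records`
#'   array), `members` (list of id vectors), `full_gpa`, and `dataset`.
#' @seealso [summarize_rarefaction()], [pc1_grids_for_iterations()]
#' @export
run_rarefaction <- function(dataset, fractions = c(1, 0.75, 0.5, 0.25, 0.1),
                            T = 1000, base_seed = 1, slide = NULL,
                            do_shapes = TRUE) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- dataset$n
  if (n < 10L) stop("rarefaction needs at least 10 specimens")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  T <- as.integer(T)
  if (T < 1L) stop("T must be at least 1")
  if (base_seed < 0 || base_seed > 2000)
    stop("base_seed must be a small non-negative integer (<= 2000)")
  if (is.null(slide)) slide <- !is.null(dataset$sliders)

  full_gpa <- gpa(dataset, slide = slide)
  true_consensus <- full_gpa$consensus
  log_cs <- log10(full_gpa$centroid_sizes)
  k <- dataset$k

  ms <- vapply(fractions, function(f) {
    m <- round_half_up(f * n)
    if (m < 3L) stop("fraction ", f, " gives fewer than 3 specimens")
    as.integer(m)
  }, integer(1))

  nrec <- length(fractions) * T
  rec <- data.frame(
    fraction = rep(fractions, each = T),
    bin = factor(rep(sprintf("%g%%", 100 * fractions), each = T),
                 levels = sprintf("%g%%", 100 * sort(fractions,
                                                     decreasing = TRUE))),
    iteration = rep(seq_len(T), times = length(fractions)),
    seed = NA_real_, m = rep(ms, each = T),
    mean_log_cs = NA_real_, dist_to_true = NA_real_)
  mean_shapes <- if (do_shapes) array(NA_real_, dim = c(k, 2L, nrec)) else NULL
  members <- vector("list", nrec)

  r <- 0L
  for (bi in seq_along(fractions)) {
    f <- fractions[bi]
    m <- ms[bi]
    full_bin <- m == n
    # the 100% bin is the same draw every iteration; compute it once
    if (full_bin) {
      msh <- true_consensus
      mlcs <- mean(log_cs)
    }
    for (it in seq_len(T)) {
      r <- r + 1L
      seed_it <- (base_seed * 1e6 + bi * 1e4 + it) %% 2^31
      rec$seed[r] <- seed_it
      if (full_bin) {
        members[[r]] <- dataset$ids
        rec$mean_log_cs[r] <- mlcs
        rec$dist_to_true[r] <- 0
        if (do_shapes) mean_shapes[, , r] <- msh
        next
      }
      set.seed(seed_it)
      sel <- sample.int(n, m)
      members[[r]] <- dataset$ids[sel]
      rec$mean_log_cs[r] <- mean(log_cs[sel])
      if (do_shapes) {
        sub_gpa <- gpa(dataset$coords[, , sel, drop = FALSE],
                       sliders = dataset$sliders, slide = slide)
        mean_shapes[, , r] <- sub_gpa$consensus
        rec$dist_to_true[r] <- procrustes_distance(sub_gpa$consensus,
                                                   true_consensus)
      }
    }
  }

  attr(rec, "mean_shapes") <- mean_shapes
  attr(rec, "members") <- members
  attr(rec, "full_gpa") <- full_gpa
  attr(rec, "dataset") <- dataset
  attr(rec, "slide") <- slide
  attr(rec, "base_seed") <- base_seed
  class(rec) <- c("rarefaction_records", "data.frame")
  rec
}

#' Summarize a rarefaction experiment
#'
#' The comparison battery run on the output of [run_rarefaction()]:
#' (a) one-way ANOVA + Tukey HSD of mean log10 centroid size across
#' bins (100% bin included); (b) the same for the Procrustes distance
#' to the true mean (the degenerate all-zero 100% bin excluded by
#' default); (c) a pairwise dispersion (Procrustes variance)
#' permutation test of the subsample mean shapes across bins; and
#' (d) projection of all subsample mean shapes into the full-sample PC
#' space with per-bin convex hulls. Each permuted subsample is treated
#' as one observation in (a)-(c); iterations within a bin share
#' specimens, so these ANOVAs carry the pseudo-replication of the
#' published procedure and their p-values should be read as descriptive
#' of this experiment, not of independent samples.
#'
#' @param records a `rarefaction_records` object (with shapes).
#' @param full_gpa the full-sample `gpa_result` (default: taken from
#'   `records`).
#' @param n_perm permutations for the dispersion test.
#' @param seed integer seed for the dispersion test.
#' @param include_full_bin include the 100% bin in the distance ANOVA.
#' @return An object of class `rarefaction_summary`: `bin_table`
#'   (per-bin record count, subsample size, mean/sd distance, mean/sd
#'   of mean log CS, hull area), `cs_anova`, `dist_anova`
#'   (`anova_tukey` objects), `dispersion` (`dispersion_test`),
#'   `scores` (per-record PC1/PC2 scores with bin), `hulls` (per-bin
#'   hull vertex matrices), and the full-sample `pca`.
#' @export
summarize_rarefaction <- function(records, full_gpa = attr(records, "full_gpa"),
                                  n_perm = 1000, seed = NULL,
                                  include_full_bin = FALSE) {
  stopifnot(inherits(records, "rarefaction_records"))
  if (nlevels(droplevels(records$bin)) < 2L)
    stop("rarefaction summary needs at least 2 bins")
  shapes <- attr(records, "mean_shapes")
  if (is.null(shapes) || anyNA(records$dist_to_true))
    stop("records lack mean shapes (run_rarefaction with do_shapes = TRUE)")

  cs_anova <- anova_tukey(records$mean_log_cs, records$bin)
  sub <- records$fraction < 1 | include_full_bin
  dist_anova <- if (sum(!duplicated(records$bin[sub])) >= 2L)
    anova_tukey(records$dist_to_true[sub], droplevels(records$bin[sub]))
  else NULL

  # align each subsample mean to the full consensus: subsample GPAs
  # have arbitrary orientation, a common frame is needed for variance
  # and ordination
  cons <- center_scale_config(full_gpa$consensus)
  nrec <- dim(shapes)[3L]
  aligned_means <- shapes
  for (r in seq_len(nrec))
    aligned_means[, , r] <- opa_align(center_scale_config(shapes[, , r]),
                                      cons)$aligned
  dispersion <- dispersion_test(aligned_means, records$bin,
                                n_perm = n_perm, seed = seed)

  pca <- pca_shape(full_gpa)
  sc <- project_shapes(pca, aligned_means)[, 1:2, drop = FALSE]
  scores <- data.frame(bin = records$bin, fraction = records$fraction,
                       PC1 = sc[, 1L], PC2 = sc[, 2L])
  hulls <- lapply(split(seq_len(nrec), records$bin), function(ii)
    convex_hull(sc[ii, , drop = FALSE]))

  bin_table <- do.call(rbind, lapply(split(records, records$bin), function(d) {
    data.frame(bin = d$bin[1L], fraction = d$fraction[1L], m = d$m[1L],
               n_records = nrow(d),
               mean_dist = mean(d$dist_to_true), sd_dist = stats::sd(d$dist_to_true),
               mean_mlcs = mean(d$mean_log_cs), sd_mlcs = stats::sd(d$mean_log_cs))
  }))
  bin_table$hull_area <- vapply(hulls[as.character(bin_table$bin)],
                                polygon_area, numeric(1))
  rownames(bin_table) <- NULL

  structure(list(bin_table = bin_table, cs_anova = cs_anova,
                 dist_anova = dist_anova, dispersion = dispersion,
                 scores = scores, hulls = hulls, pca = pca,
                 n_perm = n_perm, seed = seed),
            class = "rarefaction_summary")
}

#' @export
print.rarefaction_summary <- function(x, ...) {
  cat("Rarefaction summary\n")
  print(format(x$bin_table, digits = 4L))
  cat("\nCentroid-size ANOVA across bins: p =",
      format(x$cs_anova$anova$p[1L], digits = 4L), "\n")
  if (!is.null(x$dist_anova))
    cat("Distance-to-true-mean ANOVA across bins: p =",
        format(x$dist_anova$anova$p[1L], digits = 4L), "\n")
  invisible(x)
}

#' Deformation grids along PC1 for selected rarefaction subsamples
#'
#' For each requested (fraction, iteration) record, reconstitutes the
#' subsample, runs its own GPA and PCA, and builds TPS deformation
#' grids from the subsample consensus to the shapes at the extremes of
#' its PC1 scores; the same grids are produced for the full sample, so
#' the primary axis of shape change can be compared visually or via
#' [grid_field_correlation()].
#'
#' @param records a `rarefaction_records` object.
#' @param which a data frame (or 2-column matrix) of `fraction`,
#'   `iteration` pairs to extract.
#' @param nx,ny grid resolution passed to [deformation_grid()].
#' @return An object of class `pc1_grids`: `full` (list with `neg`,
#'   `pos` deformation grids and the full `pca`) and `subsets` (one
#'   entry per request, with `fraction`, `iteration`, `neg`, `pos`,
#'   `pca`).
#' @export
pc1_grids_for_iterations <- function(records, which, nx = 20, ny = 20) {
  stopifnot(inherits(records, "rarefaction_records"))
  dataset <- attr(records, "dataset")
  full_gpa <- attr(records, "full_gpa")
  slide <- attr(records, "slide")
  which <- as.data.frame(which)
  names(which)[1:2] <- c("fraction", "iteration")

  grids_of <- function(g) {
    pca <- pca_shape(g)
    cons <- mean_shape(g)
    lo <- shape_from_scores(pca, min(pca$scores[, 1L]))
    hi <- shape_from_scores(pca, max(pca$scores[, 1L]))
    list(neg = deformation_grid(tps_warp(cons, lo), nx = nx, ny = ny),
         pos = deformation_grid(tps_warp(cons, hi), nx = nx, ny = ny),
         pca = pca)
  }

  full <- grids_of(full_gpa)
  subsets <- vector("list", nrow(which))
  members <- attr(records, "members")
  for (j in seq_len(nrow(which))) {
    hit <- base::which(records$fraction == which$fraction[j] &
                       records$iteration == which$iteration[j])
    if (!length(hit))
      stop("no record for fraction ", which$fraction[j], ", iteration ",
           which$iteration[j])
    ids <- members[[hit[1L]]]
    if (length(ids) < 3L) stop("subsample too small for PCA")
    sub_gpa <- gpa(dataset$coords[, , match(ids, dataset$ids), drop = FALSE],
                   sliders = dataset$sliders, slide = slide)
    subsets[[j]] <- c(list(fraction = which$fraction[j],
                           iteration = which$iteration[j]),
                      grids_of(sub_gpa))
  }
  structure(list(full = full, subsets = subsets), class = "pc1_grids")
}
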