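#' Sexual shape and size dimorphism test battery
#'
#' Bundles the two dimorphism analyses for one landmark dataset:
#' sexual shape dimorphism (SShD) as a Procrustes ANOVA of shape on
#' log10 centroid size followed by sex (sequential sums of squares, so
#' sex is tested after accounting for size, with RRPP significance),
#' and sexual size dimorphism (SSD) as a one-way ANOVA of log10
#' centroid size on sex. Optionally repeats both with balanced
#' resampling: the more numerous sex is randomly subsampled to the size
#' of the rarer sex `balance_T` times and the count of significant
#' iterations at `alpha` is reported, the standard guard against
#' unequal sex ratios driving significance.
#'
#' @param dataset a [landmark_dataset] whose classifier table has a
#'   `sex` column with both sexes present.
#' @param n_perm RRPP permutations for the shape ANOVA.
#' @param seed integer seed (also drives the balanced resampling).
#' @param balance run the balanced-resampling loop.
#' @param balance_T number of balanced resampling iterations.
#' @param alpha significance level for counting significant iterations.
#' @param slide passed to [gpa()].
#' @return A list of class `dimorphism_suite`: `SShD` (an
#'   [proc_anova_rrpp()] table for `shape ~ size + sex`), `SSD` (an
#'   [anova_tukey()] for `size ~ sex`), and when `balance = TRUE` a
#'   `balance` list with `T`, `alpha`, `n_sig_sshd`, `n_sig_ssd`.
#' @export
sexual_dimorphism_suite <- function(dataset, n_perm = 1000, seed = NULL,
                                    balance = FALSE, balance_T = 100,
                                    alpha = 0.05, slide = NULL) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (is.null(dataset$classifiers) || !"sex" %in% names(dataset$classifiers))
    stop("dataset needs a classifier table with a 'sex' column")
  sex <- factor(dataset$classifiers$sex)
  if (nlevels(droplevels(sex)) < 2L)
    stop("both sexes must be present (single-sex dataset)")

  g <- gpa(dataset, slide = slide)
  size <- log10(g$centroid_sizes)
  covars <- data.frame(size = size, sex = sex)
  sshd <- proc_anova_rrpp(g, covars, terms = c("size", "sex"),
                          n_perm = n_perm, seed = seed)
  ssd <- anova_tukey(size, sex)

  out <- list(SShD = sshd, SSD = ssd, balance = NULL)
  if (balance) {
    tab <- table(sex)
    rare <- names(tab)[which.min(tab)]
    many <- names(tab)[which.max(tab)]
    n_keep <- min(tab)
    idx_rare <- which(sex == rare)
    idx_many <- which(sex == many)
    n_sig_sshd <- 0L
    n_sig_ssd <- 0L
    for (t in seq_len(balance_T)) {
      if (!is.null(seed)) set.seed((seed * 1e4 + t) %% 2^31)
      sel <- sort(c(idx_rare, sample(idx_many, n_keep)))
      gb <- gpa(dataset$coords[, , sel, drop = FALSE],
                sliders = dataset$sliders, slide = slide)
      sizeb <- log10(gb$centroid_sizes)
      sexb <- droplevels(sex[sel])
      tb <- proc_anova_rrpp(gb, data.frame(size = sizeb, sex = sexb),
                            terms = c("size", "sex"), n_perm = n_perm,
                            seed = if (!is.null(seed))
                              (seed * 1e4 + t) %% 2^31 else NULL)
      if (tb["sex", "p"] <= alpha) n_sig_sshd <- n_sig_sshd + 1L
      pb <- anova_tukey(sizeb, sexb)$anova$p[1L]
      if (!is.na(pb) && pb <= alpha) n_sig_ssd <- n_sig_ssd + 1L
    }
    out$balance <- list(T = balance_T, alpha = alpha,
                        n_sig_sshd = n_sig_sshd, n_sig_ssd = n_sig_ssd)
  }
  class(out) <- "dimorphism_suite"
  out
}

#' @export
print.dimorphism_suite <- function(x, ...) {
  cat("Sexual shape dimorphism (shape ~ size + sex):\n")
  print(x$SShD)
  cat("\nSexual size dimorphism (log10 CS ~ sex): F = ",
      format(x$SSD$anova$F[1L], digits = 4L), ", p = ",
      format(x$SSD$anova$p[1L], digits = 4L), "\n", sep = "")
  if (!is.null(x$balance))
    cat(sprintf("balanced resampling: SShD significant in %d / %d, SSD in %d / %d (alpha = %g)\n",
                x$balance$n_sig_sshd, x$balance$T,
                x$balance$n_sig_ssd, x$balance$T, x$balance$alpha))
  invisible(x)
}
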