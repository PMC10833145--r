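#' Principal component analysis of shape
#'
#' Eigen-analysis of the covariance matrix of the flattened,
#' superimposed coordinates (no scaling of variables), the standard
#' shape-space ordination. Components span the non-degenerate
#' directions only, so reconstruction from all components is exact.
#'
#' @param x a `gpa_result` or a `k x 2 x n` array of superimposed
#'   configurations.
#' @return An object of class `shape_pca`: `scores` (`n x q`),
#'   `rotation` (`2k x q`, orthonormal columns), `sdev`, `explained`
#'   (fractions of total variance, non-increasing), `center` (`2k`) and
#'   `k`.
#' @export
pca_shape <- function(x) {
  if (inherits(x, "gpa_result")) x <- x$aligned
  Y <- if (is.matrix(x)) x else flatten_shapes(x)
  n <- nrow(Y)
  if (n < 3L) stop("shape PCA needs at least 3 specimens")
  p <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  keep <- which(p$sdev > max(p$sdev) * 1e-10)
  ev <- p$sdev^2
  structure(
    list(scores = p$x[, keep, drop = FALSE],
         rotation = p$rotation[, keep, drop = FALSE],
         sdev = p$sdev[keep],
         explained = ev[keep] / sum(ev),
         center = p$center,
         k = ncol(Y) / 2L),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA: ", nrow(x$scores), " specimens, ",
      ncol(x$scores), " components\n", sep = "")
  ex <- utils::head(x$explained, 5L)
  cat("  explained: ", paste(sprintf("%.1f%%", 100 * ex), collapse = ", "),
      if (length(x$explained) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Project configurations into an existing shape PCA space
#'
#' @param pca a [pca_shape()] result.
#' @param shapes a `k x 2` matrix, `k x 2 x m` array, or `m x 2k` matrix.
#' @return An `m x q` score matrix.
#' @export
project_shapes <- function(pca, shapes) {
  Y <- if (is.array(shapes) && length(dim(shapes)) == 3L) flatten_shapes(shapes)
       else if (is.matrix(shapes) && ncol(shapes) == 2L)
         matrix(c(shapes[, 1L], shapes[, 2L]), nrow = 1L)
       else as.matrix(shapes)
  sweep(Y, 2L, pca$center) %*% pca$rotation
}

#' Reconstruct a configuration from PC scores
#'
#' @param pca a [pca_shape()] result.
#' @param scores a numeric vector of scores (padded with zeros to the
#'   number of components).
#' @return A `k x 2` coordinate matrix.
#' @export
shape_from_scores <- function(pca, scores) {
  s <- rep(0, ncol(pca$rotation))
  s[seq_along(scores)] <- scores
  v <- pca$center + drop(pca$rotation %*% s)
  cbind(x = v[seq_len(pca$k)], y = v[pca$k + seq_len(pca$k)])
}

#' Procrustes ANOVA with residual-randomization permutation (RRPP)
#'
#' Linear-model decomposition of shape variation using sequential
#' (type I) sums of squares over all flattened coordinates. For each
#' term, significance is assessed by permuting the residuals of the
#' reduced model (the model containing all preceding terms), adding
#' them back to the reduced-model fitted values, and recomputing the
#' term's F statistic; the p-value is the proportion of the permutation
#' distribution (observed arrangement included) at or above the
#' observed F. Effect sizes are reported as `R^2 = SS_term / SS_total`
#' and as the standard deviate Z of the observed F against the
#' permuted F distribution.
#'
#' @param shape the response: a `gpa_result`, a `k x 2 x n` array, an
#'   `n x p` matrix, or a numeric vector (scalar ANOVA, in which case
#'   the decomposition reduces to the classical one).
#' @param data a data frame of covariates (numeric or factor), one row
#'   per specimen.
#' @param terms character vector naming columns of `data` in the order
#'   they enter the model (default: all, in data-frame order).
#' @param n_perm total number of permutations, observed case included.
#' @param seed integer seed for the permutation schedule.
#' @return An object of class `anova_table`: a data frame with one row
#'   per term plus `Residuals` and `Total`, columns `df`, `SS`, `MS`,
#'   `F`, `R2`, `Z`, `p`; the per-term `perm_test_result`s are attached
#'   as attribute `"perm_tests"`.
#' @export
proc_anova_rrpp <- function(shape, data, terms = names(data),
                            n_perm = 1000, seed = NULL) {
  Y <- response_matrix(shape)
  n <- nrow(Y)
  data <- as.data.frame(data)
  if (nrow(data) != n) stop("covariate rows must match specimens")
  if (n_perm < 2) stop("n_perm must be at least 2")
  if (stats::sd(Y) == 0) stop("constant response: no shape variation")

  qrs <- vector("list", length(terms) + 1L)
  Xi <- stats::model.matrix(~1, data)
  qrs[[1L]] <- qr(Xi)
  for (i in seq_along(terms)) {
    f <- stats::as.formula(paste("~", paste(terms[seq_len(i)], collapse = "+")))
    qrs[[i + 1L]] <- qr(stats::model.matrix(f, data))
  }
  ranks <- vapply(qrs, `[[`, integer(1), "rank")
  dfs <- diff(ranks)
  if (any(dfs == 0L))
    stop("collinear covariates: term adds no degrees of freedom")
  qfull <- qrs[[length(qrs)]]
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0L) stop("no residual degrees of freedom")

  fitted_list <- lapply(qrs, function(q) qr.fitted(q, Y))
  SS_tot <- sum(qr.resid(qrs[[1L]], Y)^2)
  SS_terms <- vapply(seq_along(terms), function(i)
    sum((fitted_list[[i + 1L]] - fitted_list[[i]])^2), numeric(1))
  SS_res <- sum(qr.resid(qfull, Y)^2)
  MS_res <- SS_res / df_res
  F_obs <- (SS_terms / dfs) / MS_res

  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(n_perm - 1L, sample.int(n), simplify = FALSE)

  perm_tests <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    fit_r <- fitted_list[[i]]
    res_r <- Y - fit_r
    Fs <- numeric(n_perm)
    Fs[1L] <- F_obs[i]
    for (b in seq_along(perms)) {
      Yp <- fit_r + res_r[perms[[b]], , drop = FALSE]
      ss_t <- sum((qr.fitted(qrs[[i + 1L]], Yp) -
                   qr.fitted(qrs[[i]], Yp))^2)
      ss_r <- sum(qr.resid(qfull, Yp)^2)
      Fs[b + 1L] <- (ss_t / dfs[i]) / (ss_r / df_res)
    }
    perm_tests[[i]] <- new_perm_test_result(
      statistic_name = paste0("F[", terms[i], "]"),
      observed = F_obs[i], permuted = Fs, n_perm = n_perm, seed = seed,
      r_squared = SS_terms[i] / SS_tot)
  }
  names(perm_tests) <- terms

  tab <- data.frame(
    df = c(dfs, df_res, n - 1L),
    SS = c(SS_terms, SS_res, SS_tot),
    MS = c(SS_terms / dfs, MS_res, NA),
    F = c(F_obs, NA, NA),
    R2 = c(SS_terms / SS_tot, SS_res / SS_tot, 1),
    Z = c(vapply(perm_tests, `[[`, numeric(1), "effect_size_z"), NA, NA),
    p = c(vapply(perm_tests, `[[`, numeric(1), "p_value"), NA, NA),
    row.names = c(terms, "Residuals", "Total"))
  attr(tab, "perm_tests") <- perm_tests
  attr(tab, "n_perm") <- n_perm
  attr(tab, "seed") <- seed
  class(tab) <- c("anova_table", "data.frame")
  tab
}

response_matrix <- function(shape) {
  if (inherits(shape, "gpa_result")) shape <- shape$aligned
  if (is.array(shape) && length(dim(shape)) == 3L) return(flatten_shapes(shape))
  if (is.matrix(shape)) return(shape)
  matrix(as.numeric(shape), ncol = 1L)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Procrustes ANOVA (sequential SS",
      if (!is.null(attr(x, "n_perm")))
        paste0(", RRPP, ", attr(x, "n_perm"), " permutations"),
      ")\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 4L))
  invisible(x)
}

#' Permutation test for differences in group dispersion
#'
#' Computes each group's Procrustes variance (the mean squared distance
#' of its members from the group mean in the flattened coordinate
#' space) and tests every pair of groups with the statistic
#' `|var_i - var_j|`, against a null distribution obtained by permuting
#' group labels.
#'
#' @param x a `gpa_result`, `k x 2 x n` array, or `n x d` matrix.
#' @param groups a factor (or coercible) of group labels, each level
#'   with at least 2 members.
#' @param n_perm total permutations, observed labelling included.
#' @param seed integer seed.
#' @return An object of class `dispersion_test`: `variances` (named
#'   per-group Procrustes variances), `pairwise` (observed
#'   `|difference|` matrix), `p` (permutation p-value matrix), `n_perm`,
#'   `seed`.
#' @export
dispersion_test <- function(x, groups, n_perm = 1000, seed = NULL) {
  Y <- response_matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 members")
  n <- nrow(Y)
  group_vars <- function(g) {
    vapply(levels(groups), function(lv) {
      Yi <- Y[g == lv, , drop = FALSE]
      sum(sweep(Yi, 2L, colMeans(Yi))^2) / nrow(Yi)
    }, numeric(1))
  }
  v_obs <- group_vars(groups)
  D_obs <- abs(outer(v_obs, v_obs, `-`))
  if (!is.null(seed)) set.seed(seed)
  count <- matrix(1, nlevels(groups), nlevels(groups))  # observed case
  for (b in seq_len(n_perm - 1L)) {
    vp <- group_vars(groups[sample.int(n)])
    count <- count + (abs(outer(vp, vp, `-`)) >= D_obs - 1e-12)
  }
  p <- count / n_perm
  diag(p) <- NA
  dimnames(D_obs) <- dimnames(p) <- list(levels(groups), levels(groups))
  structure(list(variances = v_obs, pairwise = D_obs, p = p,
                 n_perm = n_perm, seed = seed),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("Dispersion (Procrustes variance) permutation test, n_perm = ",
      x$n_perm, "\n", sep = "")
  cat("group variances:\n")
  print(signif(x$variances, 4L))
  cat("pairwise p-values:\n")
  print(signif(x$p, 4L))
  invisible(x)
}

#' Two-block partial least squares
#'
#' Singular value decomposition of the cross-block covariance matrix of
#' two centered data blocks measured on the same specimens. The
#' association strength is `rPLS`, the absolute correlation of the
#' specimen scores on the first paired singular axes; significance is
#' assessed by permuting the rows of the second block.
#'
#' @param block1,block2 `n x p` matrices or `k x 2 x n` arrays,
#'   row-aligned by specimen.
#' @param n_perm total permutations, observed pairing included.
#' @param seed integer seed.
#' @return An object of class `pls_result` (inheriting
#'   `perm_test_result`) with `observed` (rPLS), `p_value`,
#'   `effect_size_z`, plus `xscores`/`yscores` (first-axis scores),
#'   `left`/`right` (singular vectors) and `d` (singular values).
#' @export
two_block_pls <- function(block1, block2, n_perm = 1000, seed = NULL) {
  X <- response_matrix(block1)
  Y <- response_matrix(block2)
  if (nrow(X) != nrow(Y)) stop("blocks differ in specimen count")
  n <- nrow(X)
  if (n < 4L) stop("two-block PLS needs at least 4 specimens")
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  if (sum(Xc^2) == 0 || sum(Yc^2) == 0) stop("zero-variance block")
  rpls_of <- function(Xc, Yc) {
    sv <- svd(crossprod(Xc, Yc) / (n - 1L), nu = 1L, nv = 1L)
    s1 <- drop(Xc %*% sv$u)
    s2 <- drop(Yc %*% sv$v)
    if (stats::sd(s1) == 0 || stats::sd(s2) == 0) return(list(r = 0, sv = sv))
    list(r = abs(stats::cor(s1, s2)), sv = sv, s1 = s1, s2 = s2)
  }
  obs <- rpls_of(Xc, Yc)
  if (!is.null(seed)) set.seed(seed)
  rs <- numeric(n_perm)
  rs[1L] <- obs$r
  for (b in seq_len(n_perm - 1L))
    rs[b + 1L] <- rpls_of(Xc, Yc[sample.int(n), , drop = FALSE])$r
  out <- new_perm_test_result("rPLS", obs$r, rs, n_perm, seed)
  out$xscores <- obs$s1
  out$yscores <- obs$s2
  out$left <- obs$sv$u
  out$right <- obs$sv$v
  out$d <- obs$sv$d
  class(out) <- c("pls_result", class(out))
  out
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Classical one-way ANOVA (F distribution) followed by Tukey honest
#' significant differences on all group pairs, using the studentized
#' range distribution with the Tukey-Kramer standard error for
#' unbalanced groups (via [stats::aov()] and [stats::TukeyHSD()]).
#' Degenerate inputs are handled explicitly: zero residual variance
#' with equal group means returns `p = 1` with a warning; with unequal
#' means, `p = 0` with a warning.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (at least 2 groups of at least 2).
#' @return A list of class `anova_tukey`: `anova` (data frame with
#'   `df`, `SS`, `MS`, `F`, `p`), `tukey` (data frame with `pair`,
#'   `diff`, `lwr`, `upr`, `p_adj`), and the fitted `aov` object.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 members")
  df <- data.frame(y = as.numeric(values), g = groups)
  fit <- stats::aov(y ~ g, data = df)
  # degenerate (zero-residual) fits are handled explicitly below;
  # silence the stock "essentially perfect fit" warning
  an <- suppressWarnings(stats::anova(fit))
  ss_res <- an[2L, "Sum Sq"]
  ss_grp <- an[1L, "Sum Sq"]
  if (ss_res < .Machine$double.eps * max(1, ss_grp)) {
    if (ss_grp < .Machine$double.eps) {
      warning("all observations identical: F undefined, returning p = 1",
              call. = FALSE)
      p <- 1
    } else {
      warning("zero residual variance with unequal means: returning p = 0",
              call. = FALSE)
      p <- 0
    }
    anova_df <- data.frame(df = an$Df, SS = an$`Sum Sq`, MS = an$`Mean Sq`,
                           F = c(an$`F value`[1L], NA), p = c(p, NA),
                           row.names = c("group", "Residuals"))
    return(structure(list(anova = anova_df, tukey = NULL, fit = fit),
                     class = "anova_tukey"))
  }
  tk <- stats::TukeyHSD(fit)$g
  pairs <- rownames(tk)
  anova_df <- data.frame(df = an$Df, SS = an$`Sum Sq`, MS = an$`Mean Sq`,
                         F = c(an$`F value`[1L], NA),
                         p = c(an$`Pr(>F)`[1L], NA),
                         row.names = c("group", "Residuals"))
  tukey_df <- data.frame(pair = pairs, diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(anova = anova_df, tukey = tukey_df, fit = fit),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("One-way ANOVA\n")
  print(format(x$anova, digits = 4L))
  if (!is.null(x$tukey)) {
    cat("Tukey HSD:\n")
    print(format(x$tukey, digits = 4L))
  }
  invisible(x)
}
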