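#' Built-in landmark templates
#'
#' Deterministic 2D mean-shape templates mimicking the three skull data
#' layouts used throughout the package: a lateral cranium (14 fixed
#' landmarks + one 15-point semilandmark curve along the cranial vault),
#' a ventral cranium (19 + one 6-point curve), and a lateral mandible
#' (10 + three curves of 6, 6 and 18 points). Templates are centered
#' and scaled to unit centroid size; each curve carries anchors on
#' fixed landmarks so every semilandmark slides.
#'
#' @param view one of `"lateral_cranium"`, `"ventral_cranium"`,
#'   `"mandible"`.
#' @return A list with `coords` (`k x 2`, unit centroid size), `fixed`
#'   (count of fixed landmarks), `curves` (list of point index runs),
#'   `anchors` (list of anchor index pairs) and `sliders` (the derived
#'   slider table).
#' @export
shape_template <- function(view = c("lateral_cranium", "ventral_cranium",
                                    "mandible")) {
  view <- match.arg(view)
  arc <- function(npt, from, to, a, b, cx = 0, cy = 0) {
    t <- seq(from, to, length.out = npt)
    cbind(cx + a * cos(t), cy + b * sin(t))
  }
  if (view == "lateral_cranium") {
    # fixed: rostrum, tooth row, jaw joint, occipital region, orbit
    fixed <- rbind(
      c(1.10, -0.05), c(0.95, -0.22), c(0.70, -0.28), c(0.45, -0.30),
      c(0.20, -0.31), c(-0.05, -0.30), c(-0.35, -0.28), c(-0.65, -0.25),
      c(-0.90, -0.15), c(-1.00, 0.05), c(0.60, -0.05), c(0.25, 0.02),
      c(-0.20, 0.05), c(-0.60, 0.02))
    curve <- arc(15L, pi * 0.97, pi * 0.03, 1.02, 0.55)
    coords <- rbind(fixed, curve)
    curves <- list(14L + 1:15)
    anchors <- list(c(10L, 1L))  # occipital and rostral fixed points
  } else if (view == "ventral_cranium") {
    # half cranium in ventral view (one side only): midline + tooth row
    mid <- cbind(seq(1.05, -1.00, length.out = 7), rep(0, 7))
    tooth <- rbind(c(0.95, 0.28), c(0.70, 0.38), c(0.40, 0.42),
                   c(0.10, 0.40), c(-0.20, 0.36))
    zygo <- rbind(c(-0.10, 0.62), c(-0.45, 0.58), c(-0.70, 0.45),
                  c(-0.35, 0.30))
    base <- rbind(c(-0.85, 0.22), c(-0.95, 0.10), c(0.55, 0.18))
    fixed <- rbind(mid, tooth, zygo, base)  # 19 fixed
    curve <- arc(6L, pi * 0.92, pi * 0.45, 1.05, 0.52)
    coords <- rbind(fixed, curve)
    curves <- list(19L + 1:6)
    anchors <- list(c(7L, 12L))
  } else {
    # mandible: condyle/coronoid/angular fixed points, three curves:
    # coronoid notch (6), angular margin (6), corpus outline (18)
    fixed <- rbind(
      c(1.05, 0.02), c(0.85, -0.10), c(0.40, -0.14), c(-0.10, -0.16),
      c(-0.60, -0.14), c(-0.95, -0.05), c(-1.00, 0.22), c(-0.75, 0.45),
      c(-0.45, 0.28), c(0.55, 0.05))
    c1 <- arc(6L, pi * 0.85, pi * 0.30, 0.35, 0.28, cx = -0.45, cy = 0.35)
    c2 <- arc(6L, -pi * 0.75, -pi * 0.15, 0.30, 0.18, cx = -0.75, cy = 0.02)
    c3 <- arc(18L, pi * 0.95, pi * 0.12, 1.04, 0.24, cy = 0.02)
    coords <- rbind(fixed, c1, c2, c3)
    curves <- list(10L + 1:6, 16L + 1:6, 22L + 1:18)
    anchors <- list(c(8L, 9L), c(6L, 5L), c(7L, 1L))
  }
  coords <- center_scale_config(coords)
  colnames(coords) <- c("x", "y")
  sliders <- make_sliders_from_curves(curves, anchors, k = nrow(coords))
  list(coords = coords, fixed = nrow(coords) - length(unlist(curves)),
       curves = curves, anchors = anchors, sliders = sliders)
}

#' Specification for the synthetic landmark-data generator
#'
#' Collects the parameters of the generative model used by
#' [generate_dataset()]. Specimen `i` of sex `g` is built as
#' `CS_i * R(theta_i) * (template + sex_offset_g +
#' slope * (log10 CS_i - mean) * allometry + noise) + translation`,
#' with isotropic Gaussian landmark noise and log-normal centroid
#' sizes. Effect vectors are random combinations of the template's
#' smoothest (lowest bending energy) principal warps — biological shape
#' effects are smooth, large-scale deformations — orthogonalized
#' against the template's similarity directions (translations,
#' rotation, scaling) and against the chord tangents of the sliding
#' semilandmarks, so that the injected "truth" lives in the shape
#' space that a Procrustes analysis with bending-energy sliding
#' estimates (along-tangent semilandmark displacement is nuisance by
#' the sliding criterion's own definition).
#'
#' Defaults emulate an intraspecific sample of a small vespertilionid
#' bat: 48 females and 24 males, centroid size about 32 mm
#' (`10^1.5`) with ~7% coefficient of variation, females about 7%
#' larger (`10^0.03`), a modest sexual shape offset producing a sex
#' effect of a few percent of total shape variance, allometry
#' accounting for roughly 15-20% of shape variance, and digitizing
#' noise of 1% of centroid size per coordinate.
#'
#' @param view template to use, see [shape_template()].
#' @param n named vector of sample sizes per sex, e.g. `c(F = 48, M = 24)`.
#' @param noise_sd isotropic landmark noise standard deviation per
#'   coordinate, in units of template centroid size.
#' @param cs_log10_mean,cs_log10_sd mean and sd of log10 centroid size.
#' @param sex_size_offset added to female log10 centroid size
#'   (positive = females larger).
#' @param sex_shape_norm norm of the female-minus-male shape offset
#'   vector (0 = no sexual shape dimorphism).
#' @param allometry_slope shape displacement (in units of centroid
#'   size) per unit of log10 centroid size.
#' @param species species label written to the classifier table.
#' @param seed integer seed; fixes both the effect-vector directions
#'   and the sampled specimens.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(view = "lateral_cranium",
                           n = c(F = 48, M = 24),
                           noise_sd = 0.01,
                           cs_log10_mean = 1.5,
                           cs_log10_sd = 0.03,
                           sex_size_offset = 0.03,
                           sex_shape_norm = 0.025,
                           allometry_slope = 1.2,
                           species = "sp_A",
                           seed = NULL) {
  if (is.null(names(n))) names(n) <- c("F", "M")[seq_along(n)]
  stopifnot(noise_sd >= 0, cs_log10_sd >= 0, all(n >= 1))
  structure(list(view = view, n = n, noise_sd = noise_sd,
                 cs_log10_mean = cs_log10_mean, cs_log10_sd = cs_log10_sd,
                 sex_size_offset = sex_size_offset,
                 sex_shape_norm = sex_shape_norm,
                 allometry_slope = allometry_slope,
                 species = species, seed = seed),
            class = "generator_spec")
}

# Orthonormal basis of the similarity directions (x/y translation,
# rotation, scaling) of a centered template, as 2k columns.
similarity_basis <- function(template) {
  k <- nrow(template)
  U <- cbind(c(rep(1, k), rep(0, k)),
             c(rep(0, k), rep(1, k)),
             c(-template[, 2L], template[, 1L]),
             c(template[, 1L], template[, 2L]))
  qr.Q(qr(U))
}

# Nuisance basis: similarity directions plus, when sliders are given,
# the chord tangent of every sliding semilandmark. Effects drawn
# orthogonal to this span are exactly the component of shape variation
# that a Procrustes analysis with bending-energy sliding estimates;
# along-tangent components are nuisance by construction.
nuisance_basis <- function(template, sliders = NULL) {
  k <- nrow(template)
  U <- cbind(c(rep(1, k), rep(0, k)),
             c(rep(0, k), rep(1, k)),
             c(-template[, 2L], template[, 1L]),
             c(template[, 1L], template[, 2L]))
  if (!is.null(sliders) && nrow(sliders)) {
    for (r in seq_len(nrow(sliders))) {
      d <- template[sliders$after[r], ] - template[sliders$before[r], ]
      d <- d / sqrt(sum(d^2))
      v <- rep(0, 2L * k)
      v[sliders$slide[r]] <- d[1L]
      v[k + sliders$slide[r]] <- d[2L]
      U <- cbind(U, v)
    }
  }
  qr.Q(qr(U))
}

# Unit vector orthogonal to the similarity directions, from the
# current RNG stream.
tangent_direction <- function(template, basis = similarity_basis(template)) {
  v <- stats::rnorm(2L * nrow(template))
  v <- v - basis %*% crossprod(basis, v)
  drop(v / sqrt(sum(v^2)))
}

# Smooth unit effect direction: a random combination of the template's
# lowest-bending-energy (large-scale) principal warps, applied to the x
# and y heights, orthogonalized against the nuisance basis. Biological
# shape effects are smooth deformations; rough (high-bending) effect
# vectors would be partially absorbed by semilandmark sliding and are
# not realistic.
smooth_direction <- function(template, basis, n_warps = 4L) {
  B <- bending_energy_matrix(template)$matrix
  eg <- eigen(B, symmetric = TRUE)
  nz <- which(eg$values > 1e-8 * max(eg$values))
  warps <- eg$vectors[, rev(nz)[seq_len(min(n_warps, length(nz)))],
                      drop = FALSE]
  v <- c(warps %*% stats::rnorm(ncol(warps)),
         warps %*% stats::rnorm(ncol(warps)))
  v <- v - basis %*% crossprod(basis, v)
  drop(v / sqrt(sum(v^2)))
}

#' Generate a synthetic landmark dataset
#'
#' Samples specimens from the generative model described in
#' [generator_spec()] and returns a ready-to-analyse
#' [landmark_dataset] (with slider and classifier tables) whose true
#' effect vectors are recorded in the `"truth"` attribute for recovery
#' tests: `template`, `allometry_direction`, `allometry_slope`,
#' `sex_offset` (the full 2k vector), `log10_cs`, `sex`, and the raw
#' noise matrix `noise`.
#'
#' @param spec a [generator_spec()].
#' @return A [landmark_dataset]; `attr(, "truth")` holds the generating
#'   parameters and per-specimen latent values.
#' @examples
#' d <- generate_dataset(generator_spec(n = c(F = 6, M = 6), seed = 1))
#' d
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  gen <- generate_core(spec, species_offset = NULL)
  gen$dataset
}

#' Generate an overlapping two-species dataset
#'
#' Adds a second, smaller species sample whose mean shape differs from
#' the first by a small offset (much smaller than the landmark noise by
#' default), emulating a morphologically cryptic congener whose shape
#' space lies largely within the larger species' shape space.
#'
#' @param spec a [generator_spec()] describing the larger species.
#' @param n2 named sample sizes per sex for the second species.
#' @param species_shape_norm norm of the species shape-offset vector.
#' @param species_size_offset added to the second species' log10
#'   centroid size.
#' @param species2 label for the second species.
#' @return A [landmark_dataset] containing both species; the `"truth"`
#'   attribute additionally records `species_offset`.
#' @export
generate_two_species_overlap <- function(spec, n2 = c(F = 12, M = 10),
                                         species_shape_norm = 0.005,
                                         species_size_offset = 0,
                                         species2 = "sp_B") {
  stopifnot(inherits(spec, "generator_spec"))
  gen <- generate_core(spec, species_offset = list(
    n2 = n2, norm = species_shape_norm, size = species_size_offset,
    label = species2))
  gen$dataset
}

generate_core <- function(spec, species_offset = NULL) {
  tpl <- shape_template(spec$view)
  template <- tpl$coords
  k <- nrow(template)
  basis <- nuisance_basis(template, tpl$sliders)
  tvec <- c(template[, 1L], template[, 2L])

  if (!is.null(spec$seed)) set.seed(spec$seed)
  allo_dir <- smooth_direction(template, basis)
  sex_dir <- smooth_direction(template, basis)
  spp_dir <- smooth_direction(template, basis)

  sexes1 <- rep(names(spec$n), spec$n)
  species <- rep(spec$species, length(sexes1))
  sexes <- sexes1
  spp_shift <- rep(0, length(sexes1))
  if (!is.null(species_offset)) {
    s2 <- rep(names(species_offset$n2), species_offset$n2)
    sexes <- c(sexes, s2)
    species <- c(species, rep(species_offset$label, length(s2)))
    spp_shift <- c(spp_shift, rep(1, length(s2)))
  }
  n <- length(sexes)
  is_f <- sexes == names(spec$n)[1L]

  log_cs <- stats::rnorm(n, spec$cs_log10_mean, spec$cs_log10_sd) +
    ifelse(is_f, spec$sex_size_offset, 0) +
    if (!is.null(species_offset)) spp_shift * species_offset$size else 0
  cs <- 10^log_cs
  # sex offset applied symmetrically so the template stays the grand mean
  sex_vec <- spec$sex_shape_norm * sex_dir
  spp_vec <- if (!is.null(species_offset))
    species_offset$norm * spp_dir else rep(0, 2L * k)
  clc <- log_cs - mean(log_cs)

  noise <- matrix(stats::rnorm(n * 2L * k, 0, spec$noise_sd), n, 2L * k)
  coords <- array(NA_real_, dim = c(k, 2L, n))
  for (i in seq_len(n)) {
    v <- tvec + (if (is_f[i]) 0.5 else -0.5) * sex_vec +
      spp_shift[i] * spp_vec +
      spec$allometry_slope * clc[i] * allo_dir + noise[i, ]
    m <- cbind(v[seq_len(k)], v[k + seq_len(k)])
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
    m <- m %*% R * cs[i]
    m <- sweep(m, 2L, stats::runif(2, -2, 2) * cs[i], `+`)
    coords[, , i] <- m
  }
  ids <- sprintf("%s_%s_%03d", species, sexes, seq_len(n))
  classifiers <- data.frame(id = ids, species = species, sex = sexes,
                            view = spec$view)
  ds <- landmark_dataset(coords, ids = ids, sliders = tpl$sliders,
                         classifiers = classifiers, curves = tpl$curves)
  attr(ds, "truth") <- list(
    template = template, allometry_direction = allo_dir,
    allometry_slope = spec$allometry_slope,
    sex_offset = sex_vec, sex_size_offset = spec$sex_size_offset,
    species_offset = spp_vec, noise_sd = spec$noise_sd,
    log10_cs = log_cs, sex = sexes, species = species, noise = noise,
    spec = spec)
  list(dataset = ds)
}
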