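#' Pipeline entry points
#'
#' Config-driven wrappers tying the package together for scripted use;
#' the command-line front end in `inst/cli/morphsample.R` dispatches to
#' these. Every run writes its artifacts plus a `manifest.json`
#' (resolved configuration, seeds, package version) sufficient to
#' reproduce the outputs bit for bit.
#'
#' A run configuration is a named list (or YAML file read with
#' [read_run_config()]) with either input paths (`tps`, `sliders`,
#' `classifiers`) or a generator description (`generator`: arguments
#' for [generator_spec()]), plus the analysis settings used by the
#' respective command: `fractions`, `T`, `n_perm`, `base_seed`,
#' `slide`, and `out_dir`.
#'
#' @param config a named list or a path to a YAML file.
#' @return Each pipeline function returns (invisibly) the paths of the
#'   files it wrote.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  has_paths <- !is.null(config$tps)
  has_gen <- !is.null(config$generator)
  if (has_paths == has_gen)
    stop("config must name exactly one of: input paths (tps), generator spec")
  config
}

config_dataset <- function(config) {
  if (!is.null(config$tps)) {
    ds <- read_tps(config$tps)
    if (!is.null(config$sliders))
      ds <- landmark_dataset(ds$coords, ids = ds$ids,
                             sliders = read_sliders(config$sliders),
                             curves = ds$curves)
    if (!is.null(config$classifiers))
      ds <- landmark_dataset(ds$coords, ids = ds$ids, sliders = ds$sliders,
                             classifiers = read_classifiers(config$classifiers),
                             curves = ds$curves)
    ds
  } else {
    spec <- do.call(generator_spec, config$generator)
    generate_dataset(spec)
  }
}

write_manifest <- function(out_dir, config, extra = list()) {
  manifest <- c(list(
    package = "morphsample",
    version = as.character(utils::packageVersion("morphsample")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

prep_out_dir <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname pipeline
#' @export
pipeline_gpa <- function(config) {
  config <- read_run_config(config)
  out_dir <- prep_out_dir(config)
  ds <- config_dataset(config)
  g <- gpa(ds, slide = config[["slide"]])
  pca <- pca_shape(g)
  aligned <- landmark_dataset(g$aligned, ids = ds$ids, sliders = ds$sliders,
                              curves = ds$curves)
  paths <- c(
    tps = file.path(out_dir, "aligned.tps"),
    cs = file.path(out_dir, "centroid_sizes.csv"),
    pca = file.path(out_dir, "pca_scores.csv"))
  write_tps(aligned, paths["tps"])
  utils::write.csv(data.frame(id = ds$ids, centroid_size = g$centroid_sizes,
                              log10_cs = log10(g$centroid_sizes)),
                   paths["cs"], row.names = FALSE)
  utils::write.csv(data.frame(id = ds$ids, pca$scores, check.names = FALSE),
                   paths["pca"], row.names = FALSE)
  write_manifest(out_dir, config,
                 list(gpa_iterations = g$iterations, slid = g$slid,
                      explained = pca$explained))
  invisible(paths)
}

#' @rdname pipeline
#' @export
pipeline_rarefy <- function(config) {
  config <- read_run_config(config)
  out_dir <- prep_out_dir(config)
  ds <- config_dataset(config)
  rec <- run_rarefaction(ds,
                         fractions = config$fractions %||% c(1, .75, .5, .25, .1),
                         T = config$T %||% 1000,
                         base_seed = config$base_seed %||% 1,
                         slide = config[["slide"]])
  summ <- summarize_rarefaction(rec, n_perm = config$n_perm %||% 1000,
                                seed = config$base_seed %||% 1)
  paths <- c(records = file.path(out_dir, "rarefaction_records.csv"),
             bins = file.path(out_dir, "rarefaction_bins.csv"),
             scores = file.path(out_dir, "rarefaction_pc_scores.csv"))
  utils::write.csv(as.data.frame(rec), paths["records"], row.names = FALSE)
  utils::write.csv(summ$bin_table, paths["bins"], row.names = FALSE)
  utils::write.csv(summ$scores, paths["scores"], row.names = FALSE)
  write_manifest(out_dir, config, list(
    cs_anova_p = summ$cs_anova$anova$p[1L],
    dist_anova_p = if (!is.null(summ$dist_anova))
      summ$dist_anova$anova$p[1L] else NA))
  invisible(paths)
}

#' @rdname pipeline
#' @param views named list of run configurations (one per view) whose
#'   datasets share specimen ids.
#' @export
pipeline_concordance <- function(views, n_perm = 1000, seed = NULL,
                                 out_dir = ".") {
  if (length(views) < 2L) stop("concordance needs at least 2 views")
  dsl <- lapply(views, function(v) config_dataset(read_run_config(v)))
  ids <- Reduce(intersect, lapply(dsl, `[[`, "ids"))
  if (length(ids) < 4L) {
    missing <- lapply(dsl, function(d) setdiff(d$ids, ids))
    stop("fewer than 4 specimens shared across views; unmatched ids: ",
         paste(utils::head(unlist(missing), 10L), collapse = ", "))
  }
  gl <- lapply(dsl, function(d) gpa(d[ids]))
  nm <- names(views) %||% paste0("view", seq_along(views))
  pairs <- utils::combn(seq_along(gl), 2L)
  res <- data.frame(view1 = nm[pairs[1L, ]], view2 = nm[pairs[2L, ]],
                    n = length(ids), rPLS = NA_real_, Z = NA_real_,
                    p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    pl <- two_block_pls(gl[[pairs[1L, j]]]$aligned,
                        gl[[pairs[2L, j]]]$aligned,
                        n_perm = n_perm, seed = seed)
    res$rPLS[j] <- pl$observed
    res$Z[j] <- pl$effect_size_z
    res$p[j] <- pl$p_value
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "concordance_pls.csv")
  utils::write.csv(res, path, row.names = FALSE)
  write_manifest(out_dir, list(views = views, n_perm = n_perm, seed = seed))
  res
}

#' @rdname pipeline
#' @param n_perm,seed,out_dir analysis settings (override config).
#' @export
pipeline_dimorphism <- function(config) {
  config <- read_run_config(config)
  out_dir <- prep_out_dir(config)
  ds <- config_dataset(config)
  suite <- sexual_dimorphism_suite(
    ds, n_perm = config$n_perm %||% 1000, seed = config$base_seed %||% 1,
    balance = isTRUE(config$balance), balance_T = config$balance_T %||% 100,
    slide = config[["slide"]])
  paths <- c(sshd = file.path(out_dir, "sshd_anova.csv"),
             ssd = file.path(out_dir, "ssd_anova.csv"))
  utils::write.csv(cbind(term = rownames(suite$SShD),
                         as.data.frame(suite$SShD)),
                   paths["sshd"], row.names = FALSE)
  utils::write.csv(cbind(term = rownames(suite$SSD$anova), suite$SSD$anova),
                   paths["ssd"], row.names = FALSE)
  if (!is.null(suite$balance)) {
    paths["balance"] <- file.path(out_dir, "balanced_resampling.csv")
    utils::write.csv(as.data.frame(suite$balance), paths["balance"],
                     row.names = FALSE)
  }
  write_manifest(out_dir, config)
  invisible(list(paths = paths, suite = suite))
}

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$generator)) stop("simulate needs a generator spec")
  out_dir <- prep_out_dir(config)
  ds <- generate_dataset(do.call(generator_spec, config$generator))
  paths <- c(tps = file.path(out_dir, "simulated.tps"),
             sliders = file.path(out_dir, "sliders.csv"),
             classifiers = file.path(out_dir, "classifiers.csv"),
             truth = file.path(out_dir, "truth.json"))
  write_tps(ds, paths["tps"])
  write_sliders(ds$sliders, paths["sliders"])
  write_classifiers(ds$classifiers, paths["classifiers"])
  truth <- attr(ds, "truth")
  jsonlite::write_json(
    list(allometry_direction = truth$allometry_direction,
         allometry_slope = truth$allometry_slope,
         sex_offset = truth$sex_offset,
         sex_size_offset = truth$sex_size_offset,
         species_offset = truth$species_offset,
         noise_sd = truth$noise_sd, log10_cs = truth$log10_cs,
         sex = truth$sex, species = truth$species),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, config)
  invisible(paths)
}
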