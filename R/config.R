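#' Pipeline run configuration
#'
#' Collects the thresholds and sweep limits used across the pipeline.
#' Defaults follow the published analysis protocol: probability-of-
#' connection (PICo) maps binarized at 1% of the 5000 streamline samples
#' per seed voxel, cortical maps thresholded at 2% of each subject's
#' maximal cortical value, cluster sweep over K = 2..20, group presence
#' at 25% of subjects, "strong" connectivity above 50%, and region priors
#' dilated with a 5 mm FWHM Gaussian and cut at 0.01.
#'
#' All fractional thresholds are applied inclusively (`>=`) except the
#' strong-connectivity cut, which is strict (`>` 50%), so that the weak
#' band is the closed interval \[25%, 50%\].
#'
#' @param pico_threshold_fraction Fraction of `n_samples_per_voxel` above
#'   which a PICo count counts as a connection. Default 0.01.
#' @param cortical_threshold_fraction Fraction of the per-subject maximal
#'   cortical PICo value used for cortical thresholding. Default 0.02.
#' @param n_samples_per_voxel Streamline samples drawn per seed voxel
#'   upstream (metadata; sets the binarization scale). Default 5000.
#' @param k_min,k_max Cluster-sweep limits. Defaults 2 and 20.
#' @param group_presence_threshold Fraction of subjects in which a voxel /
#'   connection must be present at group level. Default 0.25.
#' @param strong_threshold Fraction above which (strictly) a connection is
#'   classed "strong". Default 0.50.
#' @param weak_band Closed interval (fractions) defining "weak"
#'   connectivity. Default `c(0.25, 0.50)`.
#' @param prior_smoothing_fwhm_mm FWHM (mm) of the Gaussian used to dilate
#'   region priors. Default 5.
#' @param prior_binarise_threshold Cut applied to the smoothed prior.
#'   Default 0.01.
#' @param n_tissue_classes Number of tissue classes in the population
#'   mixture model. Default 6.
#' @param random_seed Integer seed controlling all stochastic steps.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pico_threshold_fraction = 0.01,
                       cortical_threshold_fraction = 0.02,
                       n_samples_per_voxel = 5000,
                       k_min = 2L, k_max = 20L,
                       group_presence_threshold = 0.25,
                       strong_threshold = 0.50,
                       weak_band = c(0.25, 0.50),
                       prior_smoothing_fwhm_mm = 5,
                       prior_binarise_threshold = 0.01,
                       n_tissue_classes = 6L,
                       random_seed = 1L) {
  cfg <- list(pico_threshold_fraction = pico_threshold_fraction,
              cortical_threshold_fraction = cortical_threshold_fraction,
              n_samples_per_voxel = n_samples_per_voxel,
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              group_presence_threshold = group_presence_threshold,
              strong_threshold = strong_threshold,
              weak_band = weak_band,
              prior_smoothing_fwhm_mm = prior_smoothing_fwhm_mm,
              prior_binarise_threshold = prior_binarise_threshold,
              n_tissue_classes = as.integer(n_tissue_classes),
              random_seed = as.integer(random_seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  fr <- c("pico_threshold_fraction", "cortical_threshold_fraction",
          "group_presence_threshold", "strong_threshold",
          "prior_binarise_threshold")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(f, " must lie strictly between 0 and 1 (got ", v, ")")
  }
  if (cfg$k_min < 2L) stop("k_min must be >= 2")
  if (cfg$k_min >= cfg$k_max) stop("k_min must be < k_max")
  if (length(cfg$weak_band) != 2L || cfg$weak_band[1] >= cfg$weak_band[2])
    stop("weak_band must be an increasing pair of fractions")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (f in names(x))
    cat(sprintf("  %-28s %s\n", f, paste(x[[f]], collapse = ", ")))
  invisible(x)
}

#' Read / write a run configuration
#'
#' Configurations serialize to YAML (`.yml`/`.yaml`) or JSON. Unknown
#' fields are rejected; omitted fields take their defaults.
#'
#' @param path File path.
#' @return For `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(unclass(cfg), path)
  else jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}
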