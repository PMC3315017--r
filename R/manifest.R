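#' Write a phantom data set to disk with a manifest
#'
#' Lays a generated phantom out as one directory per subject — the
#' profile count matrix and 0-based seed coordinates as CSV (a plain,
#' inspectable interchange format for seed-by-target matrices) — plus
#' the shared ground-truth label volume, target regions and a
#' `manifest.json` indexing it all. The manifest is the on-disk entry
#' point for the `parcellate` / `connect` / `subregions` command-line
#' stages.
#'
#' @param phantom A `phantom_set` from [generate_profiles()].
#' @param dir Output directory (created if missing).
#' @param target_labels Optional [label_volume()] of target regions to
#'   include.
#' @return Path to `manifest.json`, invisibly.
#' @export
write_phantom <- function(phantom, dir, target_labels = NULL) {
  stopifnot(inherits(phantom, "phantom_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (s in seq_along(phantom$subjects)) {
    sd <- file.path(dir, sprintf("subject_%02d", s))
    dir.create(sd, showWarnings = FALSE)
    p <- phantom$subjects[[s]]$profiles
    utils::write.csv(p$profiles, file.path(sd, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(p$seed_coords),
                     file.path(sd, "seed_coords.csv"), row.names = FALSE)
    entries[[s]] <- list(id = s, dir = basename(sd))
  }
  write_volume(phantom$truth_labels, file.path(dir, "truth.nii.gz"))
  if (!is.null(target_labels))
    write_volume(target_labels, file.path(dir, "target_rois.nii.gz"))
  man <- list(n_subjects = length(phantom$subjects),
              seed_dim = phantom$subjects[[1]]$profiles$seed_dim,
              target_dim = phantom$subjects[[1]]$profiles$target_dim,
              n_samples_per_voxel =
                phantom$subjects[[1]]$profiles$n_samples_per_voxel,
              seed = phantom$seed,
              spec = unclass(phantom$spec),
              truth = "truth.nii.gz",
              target_rois = if (!is.null(target_labels)) "target_rois.nii.gz",
              subjects = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom manifest back into pipeline inputs
#'
#' @param path Path to a `manifest.json` written by [write_phantom()].
#' @return A list with `subjects` (usable as the [run_pipeline()]
#'   manifest) and `target_labels` (or `NULL`).
#' @export
read_phantom_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  subjects <- lapply(seq_len(man$n_subjects), function(s) {
    sd <- file.path(base, man$subjects$dir[s])
    profs <- as.matrix(utils::read.csv(file.path(sd, "profiles.csv")))
    coords <- as.matrix(utils::read.csv(file.path(sd, "seed_coords.csv")))
    list(profiles = voxel_profiles(
      unname(profs), unname(coords), man$seed_dim,
      target_dim = man$target_dim,
      n_samples_per_voxel = man$n_samples_per_voxel))
  })
  target_labels <- NULL
  if (!is.null(man$target_rois) && !is.na(man$target_rois))
    target_labels <- read_volume(file.path(base, man$target_rois))
  list(subjects = subjects, target_labels = target_labels,
       truth = read_volume(file.path(base, man$truth)))
}
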