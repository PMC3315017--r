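#' Binarize connectivity profiles at a fraction of the sample count
#'
#' An entry becomes 1 when its probability-of-connection (PICo) count
#' reaches `threshold_fraction * n_samples_per_voxel`; the comparison is
#' inclusive, so with 5000 samples and the default 1% threshold the cut
#' falls at a count of 50. All-zero rows (seed voxels that never connect)
#' are permitted and flagged via the `zero_rows` attribute.
#'
#' @param p A [voxel_profiles()] object.
#' @param threshold_fraction Fraction in (0, 1); default 0.01.
#' @return A `binary_profiles` object: same shape as `p`, entries in
#'   \{0, 1\}, with the threshold recorded.
#' @export
binarize_profiles <- function(p, threshold_fraction = 0.01) {
  stopifnot(inherits(p, "voxel_profiles"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie strictly between 0 and 1")
  cut <- threshold_fraction * p$n_samples_per_voxel
  bin <- (p$profiles >= cut) * 1L
  out <- p
  out$profiles <- bin
  out$threshold_fraction <- threshold_fraction
  class(out) <- c("binary_profiles", class(p))
  attr(out, "zero_rows") <- which(rowSums(bin) == 0L)
  out
}

#' Product of forward and backward connection maps
#'
#' Mutual-connectivity refinement: the voxel-wise product of a seed-to-
#' target map and the corresponding target-to-seed map, keeping only
#' locations supported in both directions.
#'
#' @param forward,backward [scalar_volume()]s on the same grid.
#' @return A [scalar_volume()] holding the voxel-wise product.
#' @export
mutual_connectivity_product <- function(forward, backward) {
  stopifnot_same_grid(forward, backward, "forward/backward maps")
  scalar_volume(forward$data * backward$data, forward$affine,
                meta = c(forward$meta, list(op = "mutual_product")))
}

#' Threshold profiles at a fraction of the maximal cortical value
#'
#' Distance-corrected cortical thresholding: per subject, the maximal
#' count over the cortical mask (across all seed voxels) defines the
#' scale, and entries reaching `fraction` of it (inclusive), restricted
#' to the mask, survive. With the published 2% fraction and a maximal
#' cortical count of 950 the cut falls at a PICo value of 19.
#'
#' @param p A [voxel_profiles()] object.
#' @param cortical_mask A [label_volume()] on the target grid; nonzero
#'   voxels form the mask.
#' @param fraction Fraction in (0, 1\]; default 0.02.
#' @return A `binary_profiles` object restricted to the mask. The cut
#'   value used is stored in the `cut_value` attribute.
#' @export
cortical_threshold <- function(p, cortical_mask, fraction = 0.02) {
  stopifnot(inherits(p, "voxel_profiles"))
  if (!identical(as.integer(dim(cortical_mask$data)),
                 as.integer(p$target_dim)))
    stop("cortical mask is not on the profile target grid")
  mask <- as.vector(cortical_mask$data) != 0
  if (!any(mask)) stop("cortical mask is empty")
  m <- max(p$profiles[, mask, drop = FALSE])
  if (m == 0) stop("no cortical signal: maximal cortical count is zero")
  cut <- fraction * m
  bin <- matrix(0L, nrow(p$profiles), ncol(p$profiles))
  bin[, mask] <- (p$profiles[, mask, drop = FALSE] >= cut) * 1L
  out <- p
  out$profiles <- bin
  out$threshold_fraction <- fraction
  class(out) <- c("binary_profiles", class(p))
  attr(out, "cut_value") <- cut
  out
}

#' Group frequency map
#'
#' Voxel-wise fraction of subjects whose binarized map is set, i.e. the
#' group average of the binary maps. Values are exact multiples of
#' 1/n_subjects.
#'
#' @param binary_maps Non-empty list of [scalar_volume()]s (binary data)
#'   on a common grid.
#' @return A `group_frequency_map`: a [scalar_volume()] in \[0, 1\] with
#'   the subject count in `meta$n_subjects`.
#' @export
group_frequency <- function(binary_maps) {
  if (length(binary_maps) < 1L) stop("need at least one map")
  ref <- binary_maps[[1L]]
  acc <- array(0, dim = dim(ref$data))
  for (m in binary_maps) {
    stopifnot_same_grid(ref, m, "group maps")
    acc <- acc + (m$data != 0)
  }
  out <- scalar_volume(acc / length(binary_maps), ref$affine,
                       meta = list(n_subjects = length(binary_maps)))
  class(out) <- c("group_frequency_map", class(out))
  out
}

#' Strength class for a group-presence percentage
#'
#' Partition of \[0, 100\]: `none` below 25, `weak` in the closed band
#' \[25, 50\], `strong` strictly above 50.
#'
#' @param percent Numeric vector of percentages in \[0, 100\].
#' @param cfg A [run_config()] supplying the band limits.
#' @return Character vector in `c("none", "weak", "strong")`.
#' @export
strength_class <- function(percent, cfg = run_config()) {
  lo <- 100 * cfg$weak_band[1]
  hi <- 100 * cfg$weak_band[2]
  ifelse(percent > 100 * cfg$strong_threshold, "strong",
         ifelse(percent >= lo & percent <= hi, "weak", "none"))
}

#' Region-level connection table across subjects
#'
#' For every labelled target region, a subject counts as connected when
#' any supra-threshold profile entry (the maximal connectivity value of
#' the seed with the region) falls inside it. The table reports the
#' per-subject presence, the percentage of subjects present and the
#' weak/strong class; regions reaching the group-presence threshold
#' (default 25%, inclusive) are marked `reported`.
#'
#' @param profiles_by_subject List of [voxel_profiles()], one per subject.
#' @param target_labels A [label_volume()] on the target grid.
#' @param cfg A [run_config()].
#' @return A `data.frame` with columns `region`, `hemisphere` (parsed
#'   from a `lh_`/`rh_` name prefix, else `NA`), `n_present`, `percent`,
#'   `class`, `reported`, `empty_region`, plus a `presence` attribute
#'   (region x subject logical matrix).
#' @export
region_connection_table <- function(profiles_by_subject, target_labels,
                                    cfg = run_config()) {
  if (length(profiles_by_subject) < 1L) stop("no subjects")
  lab <- as.vector(target_labels$data)
  ids <- as.integer(names(target_labels$label_names))
  n_sub <- length(profiles_by_subject)
  presence <- matrix(FALSE, length(ids), n_sub,
                     dimnames = list(target_labels$label_names, NULL))
  for (s in seq_len(n_sub)) {
    p <- profiles_by_subject[[s]]
    if (prod(p$target_dim) != length(lab))
      stop("target labels are not on the profile grid")
    bin <- binarize_profiles(p, cfg$pico_threshold_fraction)
    hit <- colSums(bin$profiles) > 0          # any seed voxel reaches it
    for (i in seq_along(ids)) {
      vox <- lab == ids[i]
      presence[i, s] <- any(hit[vox])
    }
  }
  n_present <- rowSums(presence)
  percent <- 100 * n_present / n_sub
  region <- unname(target_labels$label_names)
  hemi <- ifelse(grepl("^lh_", region), "L",
                 ifelse(grepl("^rh_", region), "R", NA_character_))
  empty <- vapply(ids, function(i) !any(lab == i), logical(1))
  out <- data.frame(region = region, hemisphere = hemi,
                    n_present = n_present, percent = percent,
                    class = strength_class(percent, cfg),
                    reported = percent >= 100 * cfg$group_presence_threshold,
                    empty_region = empty,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "presence") <- presence
  attr(out, "n_subjects") <- n_sub
  out
}

#' Write a region connection table as CSV
#'
#' Writes the reported rows (group presence at or above threshold) by
#' default, or all rows with `all = TRUE`.
#'
#' @param tab Output of [region_connection_table()].
#' @param path Output CSV path.
#' @param all Write every region, not only the reported ones.
#' @export
write_connection_table <- function(tab, path, all = FALSE) {
  rows <- if (all) tab else tab[tab$reported, , drop = FALSE]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# Reconstruct a scalar volume on the target grid from one profile row or
# any length-V vector
profile_row_volume <- function(p, values) {
  scalar_volume(array(values, dim = p$target_dim), p$target_affine)
}
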