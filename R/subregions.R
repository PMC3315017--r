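#' Re-estimate connectivity per STN sub-region
#'
#' For every named cluster of the parcellation, each subject's member
#' seed-voxel profiles are binarized (1% PICo threshold by default) and
#' aggregated voxel-wise over the members into one presence map per
#' subject per cluster; presence maps are averaged across subjects into
#' a group distribution per cluster.
#'
#' The default aggregation marks a target voxel as connected when at
#' least `member_fraction` of the cluster's seed voxels connect to it.
#' A plain any-member rule (`aggregate = "max"`) is available but
#' saturates for large clusters: with m member voxels and per-entry
#' noise rate q, a spurious target fires with probability
#' 1 - (1-q)^m, close to 1 already at m ~ 50, q = 0.05. Requiring a
#' quarter of members keeps the re-estimated distributions specific to
#' genuine sub-region connectivity. `aggregate = "sum"` binarizes the
#' summed member counts against the member count scale.
#'
#' @param profiles_by_subject List of [voxel_profiles()], one per subject.
#' @param parcellations A single `subject_parcellation` (applied to every
#'   subject) or a list of them, one per subject, with matching names.
#' @param cfg A [run_config()].
#' @param aggregate `"fraction"` (default), `"max"` or `"sum"`.
#' @param member_fraction Fraction of member seed voxels that must
#'   connect under `aggregate = "fraction"` (inclusive). Default 0.25.
#' @return A `subregion_distributions` object: `distributions` (named
#'   list of group [scalar_volume()]s on the target grid), `presence`
#'   (named list of per-subject binary volumes), `n_subjects`, `names`.
#' @export
subregion_connectivity <- function(profiles_by_subject, parcellations,
                                   cfg = run_config(),
                                   aggregate = c("fraction", "max", "sum"),
                                   member_fraction = 0.25) {
  aggregate <- match.arg(aggregate)
  n_sub <- length(profiles_by_subject)
  if (n_sub < 1L) stop("no subjects")
  if (inherits(parcellations, "subject_parcellation"))
    parcellations <- rep(list(parcellations), n_sub)
  if (length(parcellations) != n_sub)
    stop("need one parcellation per subject (or a single shared one)")
  nm <- parcellations[[1L]]$names
  K <- length(nm)
  presence <- stats::setNames(vector("list", K), nm)
  for (k in seq_len(K)) presence[[k]] <- vector("list", n_sub)

  for (s in seq_len(n_sub)) {
    p <- profiles_by_subject[[s]]
    bin <- binarize_profiles(p, cfg$pico_threshold_fraction)
    memb <- parcellations[[s]]$membership
    if (length(memb) != nrow(p$profiles))
      stop("parcellation does not cover the profile seed voxels")
    for (k in seq_len(K)) {
      rows <- which(memb == k)
      if (length(rows) == 0L)
        stop("cluster '", nm[k], "' has no member voxels in subject ", s)
      sub_bin <- bin$profiles[rows, , drop = FALSE]
      agg <- switch(aggregate,
        fraction = (colMeans(sub_bin) >= member_fraction) * 1L,
        max = apply(sub_bin, 2L, max),
        sum = (colSums(p$profiles[rows, , drop = FALSE]) >=
                 cfg$pico_threshold_fraction * length(rows) *
                 p$n_samples_per_voxel) * 1L)
      presence[[k]][[s]] <- profile_row_volume(p, agg)
    }
  }
  dists <- lapply(presence, group_frequency)
  structure(list(distributions = dists, presence = presence,
                 n_subjects = n_sub, names = nm),
            class = "subregion_distributions")
}

#' Hard-segment target voxels by dominant sub-region connectivity
#'
#' Target voxels reached by at least `presence_threshold` of subjects
#' for at least one sub-region distribution receive the label of the
#' distribution with the maximal group value there (ties towards the
#' more anterior cluster: anterior < middle < posterior).
#'
#' @param dists A `subregion_distributions` object.
#' @param target_labels Optional [label_volume()] restricting the
#'   segmentation to labelled voxels; `NULL` segments the whole grid.
#' @param presence_threshold Group-presence fraction; default 0.25.
#' @return A [label_volume()] with cluster labels (1 = anterior, ...).
#' @export
hard_segment_targets <- function(dists, target_labels = NULL,
                                 presence_threshold = 0.25) {
  stopifnot(inherits(dists, "subregion_distributions"))
  d <- dist_matrix(dists)
  best <- max.col(d, ties.method = "first")
  best_val <- d[cbind(seq_len(nrow(d)), best)]
  lab <- ifelse(best_val >= presence_threshold, best, 0L)
  if (!is.null(target_labels)) lab[as.vector(target_labels$data) == 0L] <- 0L
  ref <- dists$distributions[[1L]]
  label_volume(array(as.integer(lab), dim(ref$data)), ref$affine,
               stats::setNames(dists$names, seq_along(dists$names)))
}

# group-value matrix (voxels x clusters) of a distribution set
dist_matrix <- function(dists) {
  n <- length(dists$distributions[[1L]]$data)
  m <- vapply(dists$distributions, function(v) as.vector(v$data),
              numeric(n))
  matrix(m, nrow = n,
         dimnames = list(NULL, names(dists$distributions)))
}

# canonical seven overlap classes of {limbic, associative, motor};
# bit code: L = 1, A = 2, M = 4
overlap_class_names <- function() {
  c("1" = "L", "2" = "A", "3" = "LA", "4" = "M",
    "5" = "LM", "6" = "AM", "7" = "LAM")
}

#' Seven-class overlap labelling of target voxels
#'
#' Classifies every voxel of a region of interest by the non-empty
#' subset of the three sub-region distributions (limbic/anterior L,
#' associative/middle A, motor/posterior M) that reach it, a
#' distribution reaching a voxel when its group value meets
#' `presence_threshold`. The 2^3 - 1 = 7 classes are
#' L, A, LA, M, LM, AM, LAM; voxels reached by none are background.
#'
#' @param dists A `subregion_distributions` object with exactly three
#'   named distributions.
#' @param roi_mask Optional [label_volume()]; nonzero voxels delimit the
#'   region of interest. `NULL` classifies the whole grid.
#' @param presence_threshold Group-presence fraction; default 0.25.
#' @return An `overlap_labels` [label_volume()] with the 7 classes.
#' @export
overlap_classes <- function(dists, roi_mask = NULL,
                            presence_threshold = 0.25) {
  stopifnot(inherits(dists, "subregion_distributions"))
  if (length(dists$distributions) != 3L)
    stop("overlap classification needs exactly three distributions")
  d <- dist_matrix(dists)
  reached <- d >= presence_threshold
  code <- reached[, 1] * 1L + reached[, 2] * 2L + reached[, 3] * 4L
  if (!is.null(roi_mask)) code[as.vector(roi_mask$data) == 0L] <- 0L
  ref <- dists$distributions[[1L]]
  out <- label_volume(array(as.integer(code), dim(ref$data)), ref$affine,
                      overlap_class_names())
  class(out) <- c("overlap_labels", class(out))
  out
}

#' Per-region composition over the seven overlap classes
#'
#' For each labelled target region, the proportion of its connected
#' (non-background) voxels falling in each overlap class. Proportions
#' sum to 1 over the connected voxels of a region; regions with no
#' connected voxel get an all-zero row and are flagged.
#'
#' @param overlap An `overlap_labels` volume from [overlap_classes()].
#' @param target_labels A [label_volume()] on the same grid.
#' @return A `data.frame`: one row per region, columns `region`,
#'   `n_connected`, the seven class proportions, and `flagged` (no
#'   connected voxels).
#' @export
region_composition <- function(overlap, target_labels) {
  stopifnot_same_grid(overlap, target_labels, "overlap/target volumes")
  cls_names <- unname(overlap_class_names())
  lab <- as.vector(target_labels$data)
  ov <- as.vector(overlap$data)
  ids <- as.integer(names(target_labels$label_names))
  rows <- lapply(seq_along(ids), function(i) {
    sel <- lab == ids[i] & ov != 0L
    n <- sum(sel)
    props <- if (n == 0L) rep(0, 7L)
             else as.numeric(table(factor(ov[sel], levels = 1:7)) / n)
    c(n_connected = n, stats::setNames(props, cls_names))
  })
  out <- data.frame(region = unname(target_labels$label_names),
                    do.call(rbind, rows), check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$flagged <- out$n_connected == 0L
  out
}

#' Assign each target region to its dominant sub-region cluster
#'
#' Region-level hard segmentation: every labelled region is assigned to
#' the cluster whose group distribution has the highest mean value over
#' the region's voxels (ties towards the more anterior cluster). Used to
#' compare recovered functional zones against phantom ground truth.
#'
#' @param dists A `subregion_distributions` object.
#' @param target_labels A [label_volume()] on the target grid.
#' @return A `data.frame` with columns `region`, `cluster` (name) and
#'   the per-cluster mean group values.
#' @export
region_cluster_assignment <- function(dists, target_labels) {
  stopifnot(inherits(dists, "subregion_distributions"))
  d <- dist_matrix(dists)
  lab <- as.vector(target_labels$data)
  ids <- as.integer(names(target_labels$label_names))
  means <- t(sapply(ids, function(i)
    colMeans(d[lab == i, , drop = FALSE])))
  colnames(means) <- dists$names
  best <- max.col(means, ties.method = "first")
  data.frame(region = unname(target_labels$label_names),
             cluster = dists$names[best], means,
             check.names = FALSE, stringsAsFactors = FALSE)
}
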