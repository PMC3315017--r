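#' Cross-correlation matrix of binarized connectivity profiles
#'
#' Pearson correlation between all pairs of seed-voxel binary profiles
#' (no down-sampling or binning). Zero-variance rows — seed voxels whose
#' binary profile is constant — cannot be correlated: their off-diagonal
#' entries are set to 0, the diagonal kept at 1, and the row indices are
#' recorded in the `zero_variance` attribute so the voxels stay in the
#' matrix (N is preserved) but are visible in reports.
#'
#' @param b A `binary_profiles` object (see [binarize_profiles()]).
#' @return A `correlation_matrix` object: list with `C` (N x N symmetric,
#'   unit diagonal), `seed_coords`, `seed_dim`, `seed_affine`.
#' @export
correlation_matrix <- function(b) {
  stopifnot(inherits(b, "binary_profiles"))
  N <- nrow(b$profiles)
  if (N < 2L) stop("need at least 2 seed voxels")
  sds <- apply(b$profiles, 1L, stats::sd)
  zv <- which(sds == 0)
  C <- matrix(0, N, N)
  ok <- setdiff(seq_len(N), zv)
  if (length(ok) >= 2L)
    C[ok, ok] <- stats::cor(t(b$profiles[ok, , drop = FALSE]))
  diag(C) <- 1
  structure(list(C = C, seed_coords = b$seed_coords,
                 seed_dim = b$seed_dim, seed_affine = b$seed_affine),
            class = "correlation_matrix",
            zero_variance = zv)
}

as_corr_mat <- function(C) {
  if (inherits(C, "correlation_matrix")) C$C else as.matrix(C)
}

#' Total sum of squared errors of a correlation matrix
#'
#' Deviation of each row of C from the mean row:
#' `T_SSE = sum_i sum_j (C_ij - mean_m C_mj)^2`.
#'
#' @param C A `correlation_matrix` or plain numeric matrix.
#' @return Non-negative scalar.
#' @export
total_sse <- function(C) {
  M <- as_corr_mat(C)
  sum(sweep(M, 2L, colMeans(M))^2)
}

#' Within-cluster sum of squared errors
#'
#' For a partition of the N rows into K clusters,
#' `W_SSE = sum_k sum_{i in k} sum_j (C_ij - mean_{m in k} C_mj)^2`:
#' each row's squared deviation from its own cluster's mean row.
#'
#' @param C A `correlation_matrix` or plain numeric matrix.
#' @param membership Integer vector of length N assigning each row to a
#'   cluster; every cluster must be non-empty.
#' @return Non-negative scalar.
#' @export
within_sse <- function(C, membership) {
  M <- as_corr_mat(C)
  if (length(membership) != nrow(M))
    stop("membership length must equal the number of rows")
  w <- 0
  for (k in unique(membership)) {
    idx <- which(membership == k)
    if (length(idx) == 0L) stop("empty cluster: ", k)
    sub <- M[idx, , drop = FALSE]
    w <- w + sum(sweep(sub, 2L, colMeans(sub))^2)
  }
  w
}

#' Ward-linkage cluster sweep with fractional variance explained
#'
#' Agglomerative Ward clustering of the rows of the correlation matrix
#' (Euclidean distance between rows; Lance-Williams Ward update via
#' [stats::hclust()] `"ward.D2"`, which minimises the within-cluster
#' sum-of-squares increase at each merge). The tree is cut at every K in
#' `k_min..k_max`; for each cut the within-cluster SSE and the
#' fractional variance explained `1 - W_SSE / T_SSE` are computed, and
#' the elbow of the variance-explained curve is detected with
#' [detect_elbow()].
#'
#' @param C A `correlation_matrix`.
#' @param k_min,k_max Sweep limits (inclusive); `k_max` must be < N.
#' @return A `cluster_sweep` object: `K` (vector of cluster counts),
#'   `membership` (N x length(K) integer matrix), `w_sse`, `t_sse`,
#'   `variance_explained`, `elbow_K`, and the `hclust` tree.
#' @export
ward_sweep <- function(C, k_min = 2L, k_max = 20L) {
  M <- as_corr_mat(C)
  N <- nrow(M)
  if (k_max >= N) stop("k_max must be smaller than the number of voxels")
  if (k_min < 2L) stop("k_min must be >= 2")
  if (k_max < k_min) stop("k_max must be >= k_min")
  hc <- stats::hclust(stats::dist(M), method = "ward.D2")
  Ks <- k_min:k_max
  membership <- sapply(Ks, function(k) stats::cutree(hc, k))
  t_sse <- total_sse(M)
  w_sse <- apply(membership, 2L, function(m) within_sse(M, m))
  ve <- 1 - w_sse / t_sse
  elbow <- detect_elbow(stats::setNames(ve, Ks))
  structure(list(K = Ks, membership = membership, w_sse = w_sse,
                 t_sse = t_sse, variance_explained = ve,
                 elbow_K = elbow, tree = hc),
            class = "cluster_sweep")
}

#' @export
print.cluster_sweep <- function(x, ...) {
  cat(sprintf("<cluster_sweep> K = %d..%d, elbow at K = %d\n",
              min(x$K), max(x$K), x$elbow_K))
  invisible(x)
}

#' Detect the elbow of a variance-explained curve
#'
#' Objective elbow criterion: the curve's most concave interior point,
#' i.e. the K maximising the negated discrete second difference
#' `-(v(K+1) - 2 v(K) + v(K-1))`. Ties break towards the smallest K.
#' A curve with no strictly concave point (flat or linear) has no elbow;
#' the smallest K is returned with a warning.
#'
#' @param curve Named numeric vector of variance explained, names being
#'   the K values, length >= 3.
#' @return The elbow K (integer).
#' @export
detect_elbow <- function(curve) {
  if (length(curve) < 3L) stop("curve must have length >= 3")
  Ks <- if (is.null(names(curve))) seq_along(curve) + 1L
        else as.integer(names(curve))
  v <- as.numeric(curve)
  n <- length(v)
  concavity <- -(v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)])
  if (max(concavity) <= 1e-12) {
    warning("no concave elbow in variance-explained curve; returning k_min")
    return(Ks[1L])
  }
  # ties (to numerical precision) break towards the smallest K
  cand <- which(concavity >= max(concavity) - 1e-9)
  Ks[1L + cand[1L]]
}

#' Name three clusters by their anterior-posterior position
#'
#' Orders the K = 3 clusters by the world-y coordinate of their centroid
#' (descending): the most anterior cluster is the limbic "anterior"
#' zone, then "middle" (associative), then "posterior" (motor). For
#' K != 3 the numeric ids are kept and no names are assigned.
#'
#' @param membership Integer vector of cluster ids per seed voxel.
#' @param seed_coords N x 3 matrix of 0-based voxel indices.
#' @param affine Seed-grid voxel-to-world affine.
#' @param seed_dim Seed grid dimensions.
#' @return A `subject_parcellation`: list with `labels` (a
#'   [label_volume()] relabelled 1 = anterior, 2 = middle, 3 = posterior
#'   when K = 3), `names`, `centroids_world` and `membership` (the
#'   relabelled vector).
#' @export
name_clusters_by_axis <- function(membership, seed_coords, affine = diag(4),
                                  seed_dim = NULL) {
  ids <- sort(unique(membership))
  K <- length(ids)
  world <- voxel_to_world(affine, seed_coords)
  cent <- t(sapply(ids, function(k)
    colMeans(world[membership == k, , drop = FALSE])))
  rownames(cent) <- ids
  if (K == 3L) {
    y <- cent[, 2]
    if (anyDuplicated(y))
      warning("tied centroid y coordinates; breaking ties by cluster id")
    ord <- ids[order(-y, ids)]            # anterior (max y) first
    new_id <- match(membership, ord)      # 1 = anterior, 2 = middle, 3 = posterior
    nm <- c("anterior", "middle", "posterior")
  } else {
    ord <- ids
    new_id <- match(membership, ord)
    nm <- paste0("cluster_", seq_len(K))
  }
  if (is.null(seed_dim)) seed_dim <- apply(seed_coords, 2, max) + 1L
  data <- array(0L, dim = seed_dim)
  data[as.matrix(seed_coords) + 1L] <- new_id
  labels <- label_volume(data, affine,
                         stats::setNames(nm, seq_len(K)))
  structure(list(labels = labels, names = nm,
                 centroids_world = cent[as.character(ord), , drop = FALSE],
                 membership = new_id, seed_coords = seed_coords),
            class = "subject_parcellation")
}

#' Consolidate subject parcellations into a group parcellation
#'
#' For every seed voxel, the frequency of each named cluster across
#' subjects is computed; voxels whose maximal frequency reaches
#' `presence_threshold` (inclusive) receive the argmax label (ties to
#' the lower label id, i.e. the more anterior name); all others become
#' background.
#'
#' @param parcellations List of `subject_parcellation`s on a common seed
#'   grid, all with the same K and matching cluster names.
#' @param presence_threshold Group-presence fraction; default 0.25.
#' @return A [label_volume()] with the consolidated labels.
#' @export
group_consolidate <- function(parcellations, presence_threshold = 0.25) {
  if (length(parcellations) < 1L) stop("no subjects")
  ref <- parcellations[[1L]]
  nm <- ref$names
  for (p in parcellations) {
    if (!identical(p$names, nm))
      stop("cluster names differ across subjects; cannot consolidate")
    stopifnot_same_grid(ref$labels, p$labels, "subject parcellations")
  }
  K <- length(nm)
  dims <- dim(ref$labels$data)
  counts <- array(0L, dim = c(prod(dims), K))
  for (p in parcellations)
    for (k in seq_len(K))
      counts[, k] <- counts[, k] + (as.vector(p$labels$data) == k)
  freq <- counts / length(parcellations)
  best <- max.col(freq, ties.method = "first")
  best_freq <- freq[cbind(seq_len(nrow(freq)), best)]
  lab <- ifelse(best_freq >= presence_threshold, best, 0L)
  label_volume(array(as.integer(lab), dims), ref$labels$affine,
               stats::setNames(nm, seq_len(K)))
}
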