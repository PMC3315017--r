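#' Specification of a synthetic STN connectivity phantom
#'
#' Defines a multi-subject phantom emulating the inputs to connectivity-
#' based STN sub-segmentation: per-subject matrices of seed-voxel x
#' target-voxel probabilistic-streamline counts with `k_true` latent
#' connectivity prototypes arranged in bands along the anterior-posterior
#' (world y) axis of an ellipsoidal seed mask.
#'
#' Profiles are generated directly as binarizable count matrices: a seed
#' voxel's profile equals its band's binary prototype scaled to
#' `n_samples_per_voxel`, perturbed by per-subject prototype jitter and
#' per-entry Bernoulli flips. No streamline propagation is simulated; the
#' phantom exercises the post-tractography analysis only.
#'
#' Each prototype's target support is a contiguous block of target voxels
#' extended by a fraction `prototype_overlap` into each neighbouring
#' block, so the middle band is a partial mixture of its flanking
#' prototypes (a connectivity gradient rather than sharply distinct
#' zones).
#'
#' @param n_subjects Number of subjects. Default 12.
#' @param n_seed_voxels Approximate seed-mask size (voxels at 1 mm);
#'   default 150, matching reported STN volumes of ~150 mm^3.
#' @param n_target_voxels Number of target (whole-brain stand-in) voxels.
#' @param k_true Number of latent connectivity prototypes. Default 3
#'   (anterior/limbic, middle/associative, posterior/motor).
#' @param prototype_overlap Fraction of each neighbouring prototype's
#'   block shared with a prototype, in \[0, 1). Default 0.25.
#' @param flip_noise Per-entry Bernoulli probability of flipping a
#'   profile entry (connection added or removed). Default 0.05.
#' @param subject_jitter Per-subject, per-entry probability of perturbing
#'   the prototype itself before voxel-level noise. Default 0.02.
#' @param axis_layout Integer permutation assigning prototype ids to
#'   anterior-to-posterior bands; default `1:k_true`.
#' @param n_samples_per_voxel Streamline samples per seed voxel
#'   (count scale). Default 5000.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_subjects = 12L,
                         n_seed_voxels = 150L,
                         n_target_voxels = 600L,
                         k_true = 3L,
                         prototype_overlap = 0.25,
                         flip_noise = 0.05,
                         subject_jitter = 0.02,
                         axis_layout = NULL,
                         n_samples_per_voxel = 5000L) {
  if (k_true < 1L) stop("k_true must be >= 1")
  if (n_seed_voxels < k_true) stop("n_seed_voxels must be >= k_true")
  for (p in c(prototype_overlap, flip_noise, subject_jitter))
    if (p < 0 || p >= 1) stop("probabilities must lie in [0, 1)")
  if (is.null(axis_layout)) axis_layout <- seq_len(k_true)
  if (!setequal(axis_layout, seq_len(k_true)))
    stop("axis_layout must be a permutation of 1..k_true")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_seed_voxels = as.integer(n_seed_voxels),
                 n_target_voxels = as.integer(n_target_voxels),
                 k_true = as.integer(k_true),
                 prototype_overlap = prototype_overlap,
                 flip_noise = flip_noise,
                 subject_jitter = subject_jitter,
                 axis_layout = as.integer(axis_layout),
                 n_samples_per_voxel = as.integer(n_samples_per_voxel)),
            class = "phantom_spec")
}

#' Voxel-wise connectivity profile matrix
#'
#' Container pairing an N x V matrix of per-seed-voxel connection sample
#' counts with the 0-based seed voxel coordinates, the seed grid, and the
#' target grid the V columns index (column j corresponds to linear index
#' j of the target grid, column-major).
#'
#' @param profiles N x V non-negative count matrix.
#' @param seed_coords N x 3 matrix of 0-based voxel indices.
#' @param seed_dim,seed_affine Seed grid dimensions and affine.
#' @param target_dim,target_affine Target grid dimensions and affine.
#' @param n_samples_per_voxel Maximum possible count per entry.
#' @return An object of class `voxel_profiles`.
#' @export
voxel_profiles <- function(profiles, seed_coords, seed_dim,
                           seed_affine = diag(4),
                           target_dim = c(ncol(profiles), 1L, 1L),
                           target_affine = diag(4),
                           n_samples_per_voxel = 5000L) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0) || any(profiles > n_samples_per_voxel))
    stop("profile counts must lie in [0, n_samples_per_voxel]")
  seed_coords <- as.matrix(seed_coords)
  if (nrow(seed_coords) != nrow(profiles))
    stop("seed_coords rows must match profile rows")
  if (prod(target_dim) != ncol(profiles))
    stop("target grid size must equal the number of profile columns")
  structure(list(profiles = profiles, seed_coords = seed_coords,
                 seed_dim = as.integer(seed_dim), seed_affine = seed_affine,
                 target_dim = as.integer(target_dim),
                 target_affine = target_affine,
                 n_samples_per_voxel = as.integer(n_samples_per_voxel)),
            class = "voxel_profiles")
}

#' @export
print.voxel_profiles <- function(x, ...) {
  cat(sprintf("<voxel_profiles> %d seed voxels x %d targets (max %d samples)\n",
              nrow(x$profiles), ncol(x$profiles), x$n_samples_per_voxel))
  invisible(x)
}

# Ellipsoidal seed mask elongated along y (axis ratio 1:1.8:1), sized to
# approximately n voxels on a 1 mm grid. Returns 0-based coords and dims.
seed_mask_coords <- function(n_seed_voxels) {
  count_for <- function(r) {
    a <- r; b <- 1.8 * r; cc <- r
    xs <- seq(-ceiling(a), ceiling(a))
    ys <- seq(-ceiling(b), ceiling(b))
    zs <- seq(-ceiling(cc), ceiling(cc))
    g <- expand.grid(x = xs, y = ys, z = zs)
    inside <- (g$x / a)^2 + (g$y / b)^2 + (g$z / cc)^2 <= 1
    g[inside, , drop = FALSE]
  }
  radii <- seq(1, 12, by = 0.05)
  best <- NULL; best_diff <- Inf
  for (r in radii) {
    m <- count_for(r)
    d <- abs(nrow(m) - n_seed_voxels)
    if (d < best_diff) { best <- m; best_diff <- d }
    if (nrow(m) > 2 * n_seed_voxels) break
  }
  coords <- as.matrix(best)
  offset <- apply(coords, 2, min)
  coords <- sweep(coords, 2, offset)           # 0-based, non-negative
  dims <- apply(coords, 2, max) + 1L
  list(coords = coords, dim = as.integer(dims))
}

# Contiguous target blocks, one core block per prototype
target_blocks <- function(n_target_voxels, k_true) {
  sizes <- rep(n_target_voxels %/% k_true, k_true)
  sizes[seq_len(n_target_voxels %% k_true)] <-
    sizes[seq_len(n_target_voxels %% k_true)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

# Binary prototypes over targets: core block plus overlap fraction of
# each adjacent block (nearest edge first). Within any block a prototype
# connects to 4 of every 5 targets, so profiles are never constant
# (a real whole-brain profile leaves most voxels unreached) and the
# binarized rows retain variance even for a single prototype.
make_prototypes <- function(spec) {
  blocks <- target_blocks(spec$n_target_voxels, spec$k_true)
  support <- function(idx) idx[idx %% 5L != 0L]
  protos <- matrix(0L, spec$k_true, spec$n_target_voxels)
  for (k in seq_len(spec$k_true)) {
    on <- support(blocks[[k]])
    if (k > 1L) {
      prev <- blocks[[k - 1L]]
      take <- floor(spec$prototype_overlap * length(prev))
      if (take > 0) on <- c(on, support(utils::tail(prev, take)))
    }
    if (k < spec$k_true) {
      nxt <- blocks[[k + 1L]]
      take <- floor(spec$prototype_overlap * length(nxt))
      if (take > 0) on <- c(on, support(utils::head(nxt, take)))
    }
    protos[k, on] <- 1L
  }
  attr(protos, "blocks") <- blocks
  protos
}

# Anterior-to-posterior band index (1 = most anterior) for seed coords,
# by equal-width cuts of world y
band_index <- function(coords, affine, k_true) {
  y <- voxel_to_world(affine, coords)[, 2]
  if (k_true == 1L) return(rep(1L, nrow(coords)))
  breaks <- seq(min(y) - 0.5, max(y) + 0.5, length.out = k_true + 1L)
  # bands numbered from anterior (largest y) to posterior
  band <- (k_true + 1L) - as.integer(cut(y, breaks, include.lowest = TRUE))
  if (length(unique(band)) < k_true)
    stop("empty anterior-posterior band for this seed geometry; ",
         "reduce k_true or enlarge the seed mask")
  band
}

#' Generate multi-subject phantom connectivity profiles
#'
#' Draws per-subject [voxel_profiles()] plus the ground-truth cluster
#' [label_volume()] on the seed grid. Deterministic given `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer random seed.
#' @return A list of class `phantom_set` with elements `subjects` (each a
#'   list with `profiles` and `truth`), `prototypes` (k x V binary
#'   matrix), `truth_labels` (shared ground-truth label volume), and
#'   `spec`.
#' @export
generate_profiles <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr_seed(seed)
  sm <- seed_mask_coords(spec$n_seed_voxels)
  band <- band_index(sm$coords, diag(4), spec$k_true)
  cluster <- spec$axis_layout[band]
  protos <- make_prototypes(spec)
  N <- nrow(sm$coords); V <- spec$n_target_voxels

  truth_data <- array(0L, dim = sm$dim)
  truth_data[sm$coords + 1L] <- cluster
  lnames <- cluster_names(spec$k_true)
  truth <- label_volume(truth_data, diag(4),
                        stats::setNames(lnames, seq_len(spec$k_true)))

  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sp <- protos
    if (spec$subject_jitter > 0) {
      jit <- matrix(stats::runif(length(sp)) < spec$subject_jitter,
                    nrow(sp), ncol(sp))
      sp <- abs(sp - jit * 1L)
    }
    bin <- sp[cluster, , drop = FALSE]
    if (spec$flip_noise > 0) {
      flips <- matrix(stats::runif(N * V) < spec$flip_noise, N, V)
      bin <- abs(bin - flips * 1L)
    }
    counts <- bin * spec$n_samples_per_voxel
    subjects[[s]] <- list(
      profiles = voxel_profiles(counts, sm$coords, sm$dim,
                                n_samples_per_voxel = spec$n_samples_per_voxel),
      truth = truth)
  }
  structure(list(subjects = subjects, prototypes = protos,
                 truth_labels = truth, spec = spec, seed = seed),
            class = "phantom_set")
}

cluster_names <- function(k) {
  if (k == 3L) c("anterior", "middle", "posterior")
  else paste0("cluster_", seq_len(k))
}

# set.seed wrapper keeping RNG kind explicit for reproducibility
withr_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
}

#' Generate named target regions aligned with prototype structure
#'
#' Partitions the target voxels into `n_regions` named regions such that
#' each region's voxels are drawn from one prototype's core block (so
#' each region is dominated by a single prototype's support and the
#' sub-region connectivity analysis has recoverable structure). Regions
#' are allocated to prototypes as evenly as possible.
#'
#' @param spec A [phantom_spec()].
#' @param n_regions Number of regions (>= 1, <= `n_target_voxels`).
#' @return A [label_volume()] on the target grid; the attribute
#'   `generating_cluster` maps each region id to the prototype that
#'   dominates it.
#' @export
generate_target_rois <- function(spec, n_regions = 6L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("n_regions must be >= 1")
  if (n_regions > spec$n_target_voxels)
    stop("more regions than target voxels")
  blocks <- target_blocks(spec$n_target_voxels, spec$k_true)
  # round-robin allocation of regions to prototypes
  proto_of_region <- rep(seq_len(spec$k_true), length.out = n_regions)
  lab <- integer(spec$n_target_voxels)
  rid <- 0L
  for (k in seq_len(spec$k_true)) {
    rids <- which(proto_of_region == k)
    if (length(rids) == 0L) next
    parts <- if (length(rids) == 1L) list(blocks[[k]])
             else split(blocks[[k]],
                        cut(seq_along(blocks[[k]]), length(rids),
                            labels = FALSE))
    for (i in seq_along(rids)) lab[parts[[i]]] <- rids[i]
  }
  # any leftover targets (k_true > n_regions) fold into the last region
  lab[lab == 0L] <- n_regions
  data <- array(lab, dim = c(spec$n_target_voxels, 1L, 1L))
  names_vec <- stats::setNames(sprintf("region_%02d", seq_len(n_regions)),
                               seq_len(n_regions))
  out <- label_volume(data, diag(4), names_vec)
  attr(out, "generating_cluster") <-
    stats::setNames(proto_of_region, names_vec)
  out
}

#' Specification of a two-channel tissue phantom
#'
#' Defines multi-subject quantitative-image phantoms for the groupwise
#' tissue-mixture model: each voxel draws a class from a shared spatial
#' prior pattern and intensities from that class's bivariate Gaussian
#' (MT-like channel in percent units, R2*-like channel in 1/s), with a
#' multiplicative Jacobian-determinant field drawn uniformly from
#' `jacobian_range`.
#'
#' Default class parameters mimic three well-separated tissue types at a
#' realistic quantitative-MRI scale: a CSF-like class (low MT, low R2*),
#' a grey-matter-like class and a white-matter-like class.
#'
#' @param n_subjects Number of subjects. Default 4.
#' @param dim Grid dimensions. Default `c(12, 12, 12)`.
#' @param class_means G x 2 matrix of class means.
#' @param class_covariances List of G positive-definite 2x2 matrices.
#' @param prior_pattern Either the keyword `"slabs"` (default; the grid is
#'   split into G slabs along x, the local class having prior 0.85 and
#'   the rest sharing the remainder) or a 4-D array (dim, G) of priors
#'   summing to 1 at every voxel.
#' @param jacobian_range Length-2 `c(lo, hi)` of the uniform Jacobian
#'   field. Default `c(0.9, 1.1)`.
#' @return An object of class `tissue_phantom_spec`.
#' @export
tissue_phantom_spec <- function(n_subjects = 4L,
                                dim = c(12L, 12L, 12L),
                                class_means = rbind(c(0.3, 8),
                                                    c(0.9, 22),
                                                    c(1.7, 42)),
                                class_covariances = NULL,
                                prior_pattern = "slabs",
                                jacobian_range = c(0.9, 1.1)) {
  G <- nrow(class_means)
  if (is.null(class_covariances))
    class_covariances <- replicate(G, diag(c(0.01, 2.5)), simplify = FALSE)
  if (length(class_covariances) != G)
    stop("need one covariance per class")
  for (S in class_covariances) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("class covariance not positive-definite")
  }
  if (jacobian_range[1] <= 0 || jacobian_range[1] > jacobian_range[2])
    stop("jacobian_range must be positive and increasing")
  spec <- structure(list(n_subjects = as.integer(n_subjects),
                         dim = as.integer(dim), n_classes = G,
                         class_means = class_means,
                         class_covariances = class_covariances,
                         prior_pattern = prior_pattern,
                         jacobian_range = jacobian_range),
                    class = "tissue_phantom_spec")
  pr <- tissue_priors_array(spec)
  sums <- apply(pr, 1:3, sum)
  if (max(abs(sums - 1)) > 1e-8)
    stop("prior_pattern probabilities must sum to 1 at every voxel")
  spec
}

# (dim, G) array of per-voxel class priors
tissue_priors_array <- function(spec) {
  G <- spec$n_classes
  if (is.array(spec$prior_pattern)) return(spec$prior_pattern)
  if (!identical(spec$prior_pattern, "slabs"))
    stop("unknown prior_pattern: ", spec$prior_pattern)
  pr <- array(0, dim = c(spec$dim, G))
  slab <- if (G == 1L) rep(1L, spec$dim[1])
          else as.integer(cut(seq_len(spec$dim[1]), G, labels = FALSE))
  p_local <- 0.85
  for (x in seq_len(spec$dim[1])) {
    p <- rep((1 - p_local) / (G - 1), G)
    if (G == 1L) p <- 1 else p[slab[x]] <- p_local
    pr[x, , , ] <- rep(p, each = spec$dim[2] * spec$dim[3])
  }
  pr
}

#' Generate a multi-subject two-channel tissue phantom
#'
#' @param spec A [tissue_phantom_spec()].
#' @param seed Integer random seed.
#' @return A list of class `tissue_phantom_set`: per subject, a list with
#'   `channels` (list of two [scalar_volume()]s), `jacobian`
#'   ([scalar_volume()]) and `truth` ([label_volume()]); plus `priors`
#'   (the (dim, G) prior array) and `spec`.
#' @export
generate_tissue_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "tissue_phantom_spec"))
  withr_seed(seed)
  pr <- tissue_priors_array(spec)
  G <- spec$n_classes
  nvox <- prod(spec$dim)
  prm <- matrix(pr, nvox, G)
  chol_list <- lapply(spec$class_covariances, chol)

  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    u <- stats::runif(nvox)
    cum <- prm %*% upper.tri(diag(G), diag = TRUE)
    cls <- rowSums(u > cum) + 1L
    y <- matrix(0, nvox, 2)
    for (g in seq_len(G)) {
      idx <- which(cls == g)
      if (length(idx) == 0L) next
      z <- matrix(stats::rnorm(2L * length(idx)), ncol = 2L)
      y[idx, ] <- sweep(z %*% chol_list[[g]], 2,
                        spec$class_means[g, ], "+")
    }
    jac <- stats::runif(nvox, spec$jacobian_range[1], spec$jacobian_range[2])
    subjects[[s]] <- list(
      channels = list(
        scalar_volume(array(y[, 1], spec$dim)),
        scalar_volume(array(y[, 2], spec$dim))),
      jacobian = scalar_volume(array(jac, spec$dim)),
      truth = label_volume(array(cls, spec$dim), diag(4),
                           stats::setNames(paste0("class_", seq_len(G)),
                                           seq_len(G))))
  }
  structure(list(subjects = subjects, priors = pr, spec = spec, seed = seed),
            class = "tissue_phantom_set")
}
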