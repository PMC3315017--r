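#' EM settings for the population tissue model
#'
#' @param max_iters Maximum EM iterations. Default 200.
#' @param tol Absolute tolerance on the weighted log-likelihood increase
#'   for convergence. Default 1e-6.
#' @param init Initialisation strategy; only `"kmeans"` (k-means on the
#'   pooled intensities with a fixed seed) is provided.
#' @param seed Integer seed for the initialisation.
#' @return An object of class `em_settings`.
#' @export
em_settings <- function(max_iters = 200L, tol = 1e-6,
                        init = "kmeans", seed = 1L) {
  if (tol <= 0) stop("tol must be > 0")
  structure(list(max_iters = as.integer(max_iters), tol = tol,
                 init = match.arg(init, "kmeans"),
                 seed = as.integer(seed)),
            class = "em_settings")
}

# log density of a bivariate normal, closed form
log_dmvnorm2 <- function(y, mu, sigma) {
  d <- sweep(y, 2L, mu)
  s11 <- sigma[1, 1]; s22 <- sigma[2, 2]; s12 <- sigma[1, 2]
  det_s <- s11 * s22 - s12^2
  q <- (d[, 1]^2 * s22 - 2 * d[, 1] * d[, 2] * s12 + d[, 2]^2 * s11) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

#' Fit a groupwise Jacobian-weighted Gaussian mixture tissue model
#'
#' Fits a mixture of bivariate Gaussians to a collection of spatially
#' normalised two-channel quantitative images. Because the images are
#' quantitative, each tissue class's intensity distribution (mean,
#' covariance) is shared by all subjects; the class priors `pi_g(x)` are
#' shared voxel-wise across subjects and estimated from the data,
#' serving as population tissue probability maps. Regional expansion or
#' contraction under spatial normalisation is accounted for by weighting
#' every voxel's log-likelihood contribution with its Jacobian
#' determinant (a voxel that expanded represents more native-space
#' tissue); `use_jacobians = FALSE` disables the weighting for
#' comparison.
#'
#' EM maximises `sum_s sum_x J_s(x) log sum_g pi_g(x) N(y_s(x); mu_g,
#' Sigma_g)`; the weighted log-likelihood is non-decreasing across
#' iterations and the fit stops when its increase drops below `tol`.
#' Covariances carry a ridge of `1e-6` times the pooled channel variance
#' against degeneracy.
#'
#' @param images List (one element per subject) of two-element lists of
#'   [scalar_volume()]s: the two quantitative channels, all on a common
#'   grid.
#' @param jacobians List of [scalar_volume()]s of positive Jacobian
#'   determinants, one per subject, or `NULL` for unit weights.
#' @param n_classes Number of tissue classes G. Default 6.
#' @param settings An [em_settings()].
#' @param use_jacobians Apply Jacobian weighting. Default `TRUE`.
#' @return A `tissue_model`: `means` (G x 2), `covariances` (list of G
#'   2x2), `priors` ((dim, G) array summing to 1 voxel-wise),
#'   `log_likelihood` (per-iteration trace of the weighted
#'   log-likelihood), `n_iter`, `converged`, `dim`, `affine`.
#' @export
fit_population_mog <- function(images, jacobians = NULL, n_classes = 6L,
                               settings = em_settings(),
                               use_jacobians = TRUE) {
  n_sub <- length(images)
  if (n_sub < 1L) stop("need at least one subject")
  ref <- images[[1L]][[1L]]
  dims <- dim(ref$data)
  nvox <- prod(dims)
  G <- as.integer(n_classes)

  Y <- matrix(0, n_sub * nvox, 2L)
  w <- rep(1, n_sub * nvox)
  for (s in seq_len(n_sub)) {
    ch <- images[[s]]
    if (length(ch) != 2L) stop("each subject needs two channels")
    stopifnot_same_grid(ref, ch[[1L]], "channel images")
    stopifnot_same_grid(ref, ch[[2L]], "channel images")
    rows <- (s - 1L) * nvox + seq_len(nvox)
    Y[rows, 1L] <- as.vector(ch[[1L]]$data)
    Y[rows, 2L] <- as.vector(ch[[2L]]$data)
    if (!is.null(jacobians) && use_jacobians) {
      stopifnot_same_grid(ref, jacobians[[s]], "jacobian images")
      j <- as.vector(jacobians[[s]]$data)
      if (any(j <= 0)) stop("non-positive Jacobian determinant")
      w[rows] <- j
    }
  }
  vox <- rep(seq_len(nvox), times = n_sub)
  ridge <- diag(1e-6 * apply(Y, 2L, stats::var), 2L)

  withr_seed(settings$seed)
  km <- stats::kmeans(Y, centers = G, nstart = 5L, iter.max = 50L)
  ord <- order(km$centers[, 1L])          # stable class order by channel 1
  mu <- km$centers[ord, , drop = FALSE]
  sigma <- vector("list", G)
  for (g in seq_len(G)) {
    idx <- km$cluster == ord[g]
    sigma[[g]] <- if (sum(idx) > 2L)
      stats::cov(Y[idx, , drop = FALSE]) + ridge
    else diag(apply(Y, 2L, stats::var)) + ridge
  }
  pi_vox <- matrix(1 / G, nvox, G)

  ll_trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  for (it in seq_len(settings$max_iters)) {
    logd <- sapply(seq_len(G), function(g)
      log_dmvnorm2(Y, mu[g, ], sigma[[g]]))
    logp <- logd + log(pmax(pi_vox[vox, , drop = FALSE], 1e-300))
    m <- apply(logp, 1L, max)
    pe <- exp(logp - m)
    tot <- rowSums(pe)
    ll <- sum(w * (m + log(tot)))
    ll_trace <- c(ll_trace, ll)
    r <- pe / tot                          # responsibilities
    wr <- r * w
    for (g in seq_len(G)) {
      sw <- sum(wr[, g])
      mu[g, ] <- colSums(wr[, g] * Y) / sw
      d <- sweep(Y, 2L, mu[g, ])
      S <- crossprod(d * sqrt(wr[, g])) / sw
      sigma[[g]] <- S + ridge
    }
    num <- rowsum(wr, vox)                 # nvox x G sums over subjects
    pi_vox <- num / rowSums(num)
    if (is.finite(prev_ll) && ll - prev_ll < settings$tol) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
  }
  structure(list(means = mu, covariances = sigma,
                 priors = array(pi_vox, dim = c(dims, G)),
                 log_likelihood = ll_trace, n_iter = length(ll_trace),
                 converged = converged, dim = dims, affine = ref$affine,
                 jacobian_weighted = use_jacobians && !is.null(jacobians)),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> %d classes, %d EM iterations%s\n",
              nrow(x$means), x$n_iter,
              if (x$converged) " (converged)" else ""))
  print(round(x$means, 3))
  invisible(x)
}

#' Serialize / read a tissue model (means and covariances) as JSON
#'
#' Prior maps are volumetric and are written separately with
#' [write_volume()]; the JSON carries the shared class parameters.
#'
#' @param model A `tissue_model`.
#' @param path Output `.json` path.
#' @export
write_tissue_model <- function(model, path) {
  obj <- list(n_classes = nrow(model$means),
              means = apply(model$means, 1L, identity, simplify = FALSE),
              covariances = lapply(model$covariances, function(S)
                list(S[1, 1], S[1, 2], S[2, 2])),
              jacobian_weighted = model$jacobian_weighted,
              n_iter = model$n_iter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# separable Gaussian convolution with edge renormalisation (constants
# are preserved exactly); sigma in voxels, per axis
gaussian_smooth_3d <- function(data, sigma_vox) {
  out <- data
  norm <- array(1, dim = dim(data))
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
    norm <- convolve_axis(norm, k, ax)
  }
  out / norm
}

# zero-padded convolution of a 3-D array along one axis
convolve_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  dims <- dim(a)
  acc <- array(0, dim = dims)
  n <- dims[axis]
  for (i in seq_along(kernel)) {
    s <- i - r - 1L                        # shift
    src <- seq_len(n) + s
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    idx_to <- which(keep)
    idx_from <- src[keep]
    if (axis == 1L)
      acc[idx_to, , ] <- acc[idx_to, , ] + kernel[i] * a[idx_from, , ]
    else if (axis == 2L)
      acc[, idx_to, ] <- acc[, idx_to, ] + kernel[i] * a[, idx_from, ]
    else
      acc[, , idx_to] <- acc[, , idx_to] + kernel[i] * a[, , idx_from]
  }
  acc
}

#' Extract a region prior mask by Gaussian dilation and binarisation
#'
#' Smooths a probability map with a Gaussian of the given FWHM (in mm,
#' converted to voxels through the affine; sigma = FWHM / sqrt(8 ln 2))
#' and binarises the result at `threshold` (inclusive). Defaults follow
#' the region-prior protocol: 5 mm FWHM, cut at 0.01.
#'
#' @param prior_map A [scalar_volume()] with values in \[0, 1\].
#' @param fwhm_mm Full width at half maximum of the smoothing kernel.
#' @param threshold Binarisation cut.
#' @return A [label_volume()] mask (label 1 = "roi").
#' @export
extract_roi_prior <- function(prior_map, fwhm_mm = 5, threshold = 0.01) {
  stopifnot(inherits(prior_map, "scalar_volume"))
  if (min(prior_map$data) < 0 || max(prior_map$data) > 1)
    stop("prior map must lie in [0, 1]")
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  sigma_vox <- sigma_mm / voxel_spacing(prior_map$affine)
  sm <- gaussian_smooth_3d(prior_map$data, sigma_vox)
  mask <- (sm >= threshold) * 1L
  label_volume(array(as.integer(mask), dim(prior_map$data)),
               prior_map$affine, c("1" = "roi"))
}

#' Assign tissue labels by maximum joint probability
#'
#' Per voxel, the label is the candidate class maximising the joint
#' probability of the population spatial prior and the subject's voxel
#' intensity density: `argmax_g pi_g(x) N(y(x); mu_g, Sigma_g)`. The
#' candidate set is explicit (typically white matter plus the region of
#' interest) rather than all classes.
#'
#' @param model A `tissue_model`.
#' @param subject_image Two-element list of [scalar_volume()] channels.
#' @param candidate_classes Integer vector of class indices to choose
#'   among; default all classes.
#' @return A [label_volume()] of winning class indices.
#' @export
assign_labels <- function(model, subject_image,
                          candidate_classes = seq_len(nrow(model$means))) {
  stopifnot(inherits(model, "tissue_model"))
  if (length(candidate_classes) < 1L) stop("empty candidate class set")
  if (!all(candidate_classes %in% seq_len(nrow(model$means))))
    stop("candidate classes outside the model")
  dims <- model$dim
  nvox <- prod(dims)
  Y <- cbind(as.vector(subject_image[[1L]]$data),
             as.vector(subject_image[[2L]]$data))
  pi_m <- matrix(model$priors, nvox, nrow(model$means))
  logp <- sapply(candidate_classes, function(g)
    log(pmax(pi_m[, g], 1e-300)) +
      log_dmvnorm2(Y, model$means[g, ], model$covariances[[g]]))
  win <- candidate_classes[max.col(logp, ties.method = "first")]
  label_volume(array(as.integer(win), dims), model$affine,
               stats::setNames(paste0("class_", seq_len(nrow(model$means))),
                               seq_len(nrow(model$means))))
}
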