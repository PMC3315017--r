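test_that("noiseless phantoms have identical within-cluster profiles", {
  spec <- phantom_spec(n_subjects = 2, n_seed_voxels = 60,
                       n_target_voxels = 120, flip_noise = 0,
                       subject_jitter = 0)
  ph <- generate_profiles(spec, seed = 1)
  p <- ph$subjects[[1]]$profiles
  truth <- ph$truth_labels$data[as.matrix(p$seed_coords) + 1L]
  for (k in 1:3) {
    rows <- p$profiles[truth == k, , drop = FALSE]
    expect_true(all(rows == rep(rows[1, ], each = nrow(rows))))
  }
  # prototypes of different clusters differ
  protos <- ph$prototypes
  expect_false(any(duplicated(protos)))
  # counts bounded by the sample budget
  expect_lte(max(p$profiles), spec$n_samples_per_voxel)
})

test_that("a single latent prototype yields a near-all-ones correlation", {
  spec <- phantom_spec(n_subjects = 1, n_seed_voxels = 40,
                       n_target_voxels = 400, k_true = 1,
                       flip_noise = 0.01, subject_jitter = 0)
  ph <- generate_profiles(spec, seed = 3)
  bin <- binarize_profiles(ph$subjects[[1]]$profiles, 0.01)
  C <- correlation_matrix(bin)$C
  expect_gt(mean(C[upper.tri(C)]), 0.85)
  # and exactly one shared prototype
  expect_equal(nrow(ph$prototypes), 1L)
})

test_that("empirical flip rate matches the requested noise level", {
  spec <- phantom_spec(n_subjects = 1, n_seed_voxels = 150,
                       n_target_voxels = 600, flip_noise = 0.05,
                       subject_jitter = 0)
  ph <- generate_profiles(spec, seed = 11)
  p <- ph$subjects[[1]]$profiles
  truth <- ph$truth_labels$data[as.matrix(p$seed_coords) + 1L]
  expected <- (ph$prototypes[truth, , drop = FALSE] > 0) * 1L
  observed <- (p$profiles > 0) * 1L
  n_entries <- length(expected)
  rate <- mean(observed != expected)
  se <- sqrt(0.05 * 0.95 / n_entries)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("phantom generation is bit-reproducible given the seed", {
  spec <- phantom_spec(n_subjects = 3, n_seed_voxels = 50,
                       n_target_voxels = 100)
  a <- generate_profiles(spec, seed = 21)
  b <- generate_profiles(spec, seed = 21)
  expect_identical(a$subjects[[2]]$profiles$profiles,
                   b$subjects[[2]]$profiles$profiles)
  c <- generate_profiles(spec, seed = 22)
  expect_false(identical(a$subjects[[2]]$profiles$profiles,
                         c$subjects[[2]]$profiles$profiles))
})

test_that("within-cluster correlation decays as flip noise grows", {
  mean_within <- function(noise) {
    spec <- phantom_spec(n_subjects = 1, n_seed_voxels = 80,
                         n_target_voxels = 300, flip_noise = noise,
                         subject_jitter = 0)
    ph <- generate_profiles(spec, seed = 5)
    p <- ph$subjects[[1]]$profiles
    truth <- ph$truth_labels$data[as.matrix(p$seed_coords) + 1L]
    C <- correlation_matrix(binarize_profiles(p, 0.01))$C
    vals <- c()
    for (k in 1:3) {
      idx <- which(truth == k)
      sub <- C[idx, idx]
      vals <- c(vals, sub[upper.tri(sub)])
    }
    mean(vals)
  }
  ms <- vapply(c(0.01, 0.05, 0.15, 0.3), mean_within, numeric(1))
  expect_true(all(diff(ms) < 0))
})

test_that("target regions align with their generating prototypes", {
  spec <- phantom_spec(n_seed_voxels = 60, n_target_voxels = 120)
  rois <- generate_target_rois(spec, n_regions = 6)
  gen <- attr(rois, "generating_cluster")
  expect_length(gen, 6)
  # with 6 regions and 3 prototypes, each prototype's core support
  # dominates exactly 2 regions
  expect_equal(as.vector(table(gen)), c(2L, 2L, 2L))
  lab <- as.vector(rois$data)
  protos <- make_prototypes_for_test(spec)
  for (r in seq_len(6)) {
    vox <- which(lab == r)
    k <- gen[[r]]
    cover <- rowMeans(protos[, vox, drop = FALSE])
    # the generating prototype dominates the region's support
    expect_equal(unname(which.max(cover)), k)
    expect_gte(cover[k], 0.75)
  }

  one <- generate_target_rois(spec, n_regions = 1)
  expect_equal(sort(unique(as.vector(one$data))), 1L)
  expect_error(generate_target_rois(spec, n_regions = 0), ">= 1")
  expect_error(generate_target_rois(spec, n_regions = 1000), "more regions")
})

test_that("tissue phantoms honour their specification", {
  spec <- tissue_phantom_spec(n_subjects = 2, dim = c(10, 10, 10))
  tp <- generate_tissue_phantom(spec, seed = 2)
  s1 <- tp$subjects[[1]]
  # empirical class means within 3 standard errors of spec means
  for (g in seq_len(spec$n_classes)) {
    idx <- s1$truth$data == g
    n <- sum(idx)
    for (ch in 1:2) {
      emp <- mean(s1$channels[[ch]]$data[idx])
      se <- sqrt(spec$class_covariances[[g]][ch, ch] / n)
      expect_lt(abs(emp - spec$class_means[g, ch]), 3 * se)
    }
  }
  # unit jacobian range collapses to exactly 1
  spec1 <- tissue_phantom_spec(n_subjects = 1, dim = c(6, 6, 6),
                               jacobian_range = c(1, 1))
  tp1 <- generate_tissue_phantom(spec1, seed = 4)
  expect_true(all(tp1$subjects[[1]]$jacobian$data == 1))

  # degenerate prior: class 1 everywhere
  pr <- array(0, c(6, 6, 6, 3)); pr[, , , 1] <- 1
  spec2 <- tissue_phantom_spec(n_subjects = 1, dim = c(6, 6, 6),
                               prior_pattern = pr)
  tp2 <- generate_tissue_phantom(spec2, seed = 4)
  expect_true(all(tp2$subjects[[1]]$truth$data == 1))

  expect_error(tissue_phantom_spec(
    class_means = rbind(c(0, 0), c(1, 1)),
    class_covariances = list(diag(2), matrix(c(1, 2, 2, 1), 2))),
    "positive-definite")
})
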