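# shared tiny parcellation: 6 seed voxels, 3 clusters of 2
tiny_parc <- function(memb = c(1L, 1L, 2L, 2L, 3L, 3L)) {
  coords <- cbind(0:5, c(5L, 5L, 3L, 3L, 1L, 1L), 0L)
  name_clusters_by_axis(memb, coords, diag(4), c(6, 6, 1))
}

test_that("sub-region distributions recover prototype supports", {
  # noiseless single subject: cluster distribution = its prototype support
  spec <- phantom_spec(n_subjects = 1, n_seed_voxels = 60,
                       n_target_voxels = 120, flip_noise = 0,
                       subject_jitter = 0)
  ph <- generate_profiles(spec, seed = 1)
  p <- ph$subjects[[1]]$profiles
  truth <- ph$truth_labels$data[as.matrix(p$seed_coords) + 1L]
  parc <- name_clusters_by_axis(truth, p$seed_coords, p$seed_affine,
                                p$seed_dim)
  sub <- subregion_connectivity(list(p), parc)
  # parcellation renames anterior band to 1; map back to generator ids
  for (k in 1:3) {
    gen_id <- truth[match(k, parc$membership)]
    expect_equal(as.vector(sub$distributions[[k]]$data),
                 as.numeric(ph$prototypes[gen_id, ]))
  }
})

test_that("single-voxel clusters and group averaging behave as counts", {
  counts <- rbind(c(5000, 0, 0, 0), c(0, 5000, 0, 0), c(0, 0, 5000, 0),
                  c(5000, 5000, 0, 0), c(0, 0, 0, 5000), c(0, 0, 5000, 5000))
  p <- tiny_profiles(counts)
  parc <- tiny_parc()
  sub1 <- subregion_connectivity(list(p), parc)
  # a cluster of one voxel equals that voxel's thresholded profile
  single <- tiny_parc(c(1L, 1L, 2L, 2L, 2L, 3L))
  subs <- subregion_connectivity(list(p), single)
  expect_equal(as.vector(subs$distributions[[3]]$data),
               as.numeric(counts[6, ] >= 50))

  # 6 subjects: group averages are multiples of 1/6
  spec <- phantom_spec(n_subjects = 6, n_seed_voxels = 40,
                       n_target_voxels = 80)
  ph <- generate_profiles(spec, seed = 9)
  truth <- ph$truth_labels$data[
    as.matrix(ph$subjects[[1]]$profiles$seed_coords) + 1L]
  parc6 <- name_clusters_by_axis(
    truth, ph$subjects[[1]]$profiles$seed_coords, diag(4),
    ph$subjects[[1]]$profiles$seed_dim)
  sub6 <- subregion_connectivity(lapply(ph$subjects, `[[`, "profiles"),
                                 parc6)
  for (d in sub6$distributions) {
    v <- as.vector(d$data)
    expect_true(all(abs(v * 6 - round(v * 6)) < 1e-12))
  }

  empty3 <- tiny_parc()
  empty3$membership <- c(1L, 1L, 2L, 2L, 2L, 2L)   # posterior left empty
  expect_error(subregion_connectivity(list(p), empty3),
               "no member voxels")
})

test_that("hard segmentation assigns the argmax distribution", {
  d <- tiny_distributions(list(c(0.2, 0.1, 0.9, 0.3),
                               c(0.5, 0.1, 0.2, 0.3),
                               c(0.3, 0.1, 0.1, 0.3)))
  seg <- hard_segment_targets(d, presence_threshold = 0.25)
  expect_equal(as.vector(seg$data), c(2L, 0L, 1L, 1L))  # tie -> anterior
  expect_equal(unname(seg$label_names[2]), "middle")
})

test_that("overlap classes realize all seven subsets exactly", {
  # 8 voxels covering every subset combination of three distributions
  on <- function(bits) as.numeric(bits) * 0.5
  d <- tiny_distributions(list(on(c(0, 1, 0, 1, 0, 1, 0, 1)),
                               on(c(0, 0, 1, 1, 0, 0, 1, 1)),
                               on(c(0, 0, 0, 0, 1, 1, 1, 1))))
  ov <- overlap_classes(d, presence_threshold = 0.25)
  expect_equal(as.vector(ov$data), 0:7)
  expect_equal(length(setdiff(unique(as.vector(ov$data)), 0L)), 7L)
  expect_equal(unname(ov$label_names),
               c("L", "A", "LA", "M", "LM", "AM", "LAM"))

  # subset logic: limbic and motor only -> LM
  d2 <- tiny_distributions(list(c(0.6), c(0.1), c(0.9)))
  expect_equal(as.vector(overlap_classes(d2)$data), 5L)
  d3 <- tiny_distributions(list(c(0.6), c(0.3), c(0.9)))
  expect_equal(as.vector(overlap_classes(d3)$data), 7L)

  # ROI mask restricts the classification
  mask <- label_volume(array(c(0L, rep(1L, 7)), c(8, 1, 1)),
                       label_names = c("1" = "roi"))
  ov_m <- overlap_classes(d, mask, 0.25)
  expect_equal(as.vector(ov_m$data)[1], 0L)

  expect_error(overlap_classes(tiny_distributions(
    list(c(1), c(1)), names = c("a", "b"))), "three")
})

test_that("region composition is a normalized class histogram", {
  ov_data <- array(c(1L, 1L, 1L, 7L, 4L, 4L, 0L, 0L), c(8, 1, 1))
  ov <- label_volume(ov_data, label_names = stnparc:::overlap_class_names())
  class(ov) <- c("overlap_labels", class(ov))
  labels <- label_volume(array(c(rep(1L, 4), rep(2L, 2), rep(3L, 2)),
                               c(8, 1, 1)),
                         label_names = c("1" = "rA", "2" = "rB", "3" = "rC"))
  comp <- region_composition(ov, labels)
  # region rA: 3 L-voxels and 1 LAM-voxel
  expect_equal(comp$L[1], 0.75)
  expect_equal(comp$LAM[1], 0.25)
  # region rB entirely motor
  expect_equal(comp$M[2], 1)
  # region rC has no connected voxels: all-zero row, flagged
  expect_true(comp$flagged[3])
  expect_equal(sum(comp[3, c("L", "A", "LA", "M", "LM", "AM", "LAM")]), 0)
  # proportions sum to 1 for connected regions
  cls <- c("L", "A", "LA", "M", "LM", "AM", "LAM")
  expect_equal(unname(rowSums(comp[1:2, cls])), c(1, 1))
})

test_that("noisy phantoms still map regions to generating prototypes", {
  spec <- phantom_spec(n_subjects = 6, n_seed_voxels = 150,
                       n_target_voxels = 600, flip_noise = 0.05)
  ph <- generate_profiles(spec, seed = 23)
  rois <- generate_target_rois(spec, 6)
  rep <- run_pipeline(run_config(random_seed = 23L), ph,
                      target_labels = rois)
  ass <- region_cluster_assignment(rep$subregions, rois)
  gen <- attr(rois, "generating_cluster")
  expected <- c("anterior", "middle", "posterior")[gen]
  expect_gte(mean(ass$cluster == unname(expected)), 0.9)
})

test_that("regions are assigned to their dominant cluster", {
  d <- tiny_distributions(list(c(1, 1, 0.2, 0), c(0.2, 0.2, 1, 0.2),
                               c(0, 0, 0.2, 1)))
  labels <- label_volume(array(c(1L, 1L, 2L, 3L), c(4, 1, 1)),
                         label_names = c("1" = "rA", "2" = "rB", "3" = "rC"))
  ass <- region_cluster_assignment(d, labels)
  expect_equal(ass$cluster, c("anterior", "middle", "posterior"))
})
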