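test_that("correlation matrix is the Pearson correlation of binary rows", {
  b <- tiny_binary(rbind(c(1, 0, 1, 0), c(1, 0, 1, 0)))
  expect_equal(correlation_matrix(b)$C[1, 2], 1)

  b2 <- tiny_binary(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
  expect_equal(correlation_matrix(b2)$C[1, 2], -1)

  b3 <- tiny_binary(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(correlation_matrix(b3)$C[1, 2], 0)

  # zero-variance rows keep the voxel but are flagged and decorrelated
  b4 <- tiny_binary(rbind(c(1, 1, 1, 1), c(1, 0, 1, 0), c(0, 1, 0, 1)))
  C4 <- correlation_matrix(b4)
  expect_equal(attr(C4, "zero_variance"), 1L)
  expect_equal(C4$C[1, 2], 0)
  expect_equal(C4$C[1, 1], 1)
  expect_true(isSymmetric(C4$C))

  expect_error(correlation_matrix(tiny_binary(rbind(c(1, 0)))), "at least 2")
})

test_that("total and within SSE match naive loop oracles", {
  C <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(total_sse(C), 1.0)                 # four terms of (+-0.5)^2
  expect_equal(total_sse(matrix(0.4, 3, 3)), 0)   # identical rows

  set.seed(10)
  for (rep in 1:10) {
    N <- sample(4:12, 1)
    M <- matrix(runif(N * N, -1, 1), N, N)
    expect_equal(total_sse(M), naive_total_sse(M), tolerance = 1e-9)
    memb <- sample(1:3, N, replace = TRUE)
    while (length(unique(memb)) < 3) memb <- sample(1:3, N, replace = TRUE)
    expect_equal(within_sse(M, memb), naive_within_sse(M, memb),
                 tolerance = 1e-9)
  }

  # definitional limits
  M <- matrix(runif(64, -1, 1), 8, 8)
  expect_equal(within_sse(M, 1:8), 0)             # singletons
  expect_equal(within_sse(M, rep(1, 8)), total_sse(M))  # one cluster
  expect_error(within_sse(M, c(1:7)), "length")
})

test_that("ward sweep recovers separated groups and matches a greedy oracle", {
  # two well-separated row groups
  set.seed(3)
  M <- rbind(matrix(rnorm(4 * 6, 5), 4, 6), matrix(rnorm(4 * 6, -5), 4, 6))
  sw <- ward_sweep(M, k_min = 2, k_max = 4)
  expect_equal(ari(sw$membership[, 1], rep(1:2, each = 4)), 1)

  # memberships match a greedy minimum-SSE-increase agglomeration
  for (rep in 1:5) {
    N <- sample(5:8, 1)
    M <- matrix(rnorm(N * N), N, N)
    oracle <- greedy_ward_partitions(M)
    sw <- ward_sweep(M, k_min = 2, k_max = N - 1)
    for (K in sw$K) {
      expect_equal(ari(sw$membership[, match(K, sw$K)],
                       oracle[[as.character(K)]]), 1,
                   info = sprintf("N=%d K=%d", N, K))
    }
  }
  expect_error(ward_sweep(matrix(rnorm(25), 5, 5), 2, 5), "k_max")
})

test_that("variance explained is monotone and reaches its limits", {
  set.seed(8)
  for (rep in 1:5) {
    N <- 12
    M <- matrix(runif(N * N, -1, 1), N, N)
    sw <- ward_sweep(M, k_min = 2, k_max = N - 1)
    expect_true(all(diff(sw$variance_explained) >= -1e-12))
    expect_true(all(diff(sw$w_sse) <= 1e-12))     # W_SSE non-increasing in K
    expect_true(all(sw$variance_explained >= -1e-12 &
                    sw$variance_explained <= 1 + 1e-12))
    # K = N explains everything; the single cluster explains nothing
    expect_equal(within_sse(M, 1:N), 0)
    expect_equal(1 - within_sse(M, 1:N) / total_sse(M), 1)
    expect_equal(1 - within_sse(M, rep(1, N)) / total_sse(M), 0)
  }
})

test_that("elbow detection finds the most concave point", {
  curve <- setNames(c(0.50, 0.90, 0.92, 0.93, 0.94), 2:6)
  expect_equal(detect_elbow(curve), 3L)

  expect_warning(e <- detect_elbow(setNames(seq(0.1, 0.5, 0.1), 2:6)),
                 "no concave elbow")
  expect_equal(e, 2L)
  expect_warning(e2 <- detect_elbow(setNames(rep(0.5, 5), 2:6)))
  expect_equal(e2, 2L)
  expect_error(detect_elbow(c(1, 2)), "length >= 3")

  # ties break towards the smaller K: concavity 0.2 at both K=3 and K=4
  tied <- setNames(c(0, 0.5, 0.8, 0.9, 0.9, 0.9), 2:7)
  expect_equal(detect_elbow(tied), 3L)
})

test_that("clusters are named along the anterior-posterior axis", {
  coords <- rbind(c(0, 10, 0), c(0, 9, 0), c(0, 5, 0), c(0, 4, 0),
                  c(0, 0, 0), c(0, 1, 0))
  memb <- c(2L, 2L, 3L, 3L, 1L, 1L)   # arbitrary ids; y decides the names
  parc <- name_clusters_by_axis(memb, coords, diag(4), c(1, 11, 1))
  expect_equal(parc$names, c("anterior", "middle", "posterior"))
  expect_equal(parc$membership, c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(unname(parc$labels$label_names),
               c("anterior", "middle", "posterior"))

  # K != 3: ids kept, generic names
  parc2 <- name_clusters_by_axis(c(1L, 1L, 2L, 2L, 2L, 1L), coords)
  expect_equal(parc2$names, c("cluster_1", "cluster_2"))

  # tied centroids warn and break by id
  coords_t <- rbind(c(0, 2, 0), c(0, 1, 0), c(0, 2, 0), c(0, 1, 0),
                    c(0, 0, 0), c(0, 0, 0))
  expect_warning(name_clusters_by_axis(c(1L, 1L, 2L, 2L, 3L, 3L), coords_t),
                 "tie")
})

test_that("group consolidation keeps voxels present above threshold", {
  mk_parc <- function(labels) {
    coords <- cbind(seq_along(labels) - 1L, 0L, 0L)
    data <- array(0L, c(length(labels), 1, 1))
    data[cbind(seq_along(labels), 1L, 1L)] <- labels
    structure(list(
      labels = label_volume(data, diag(4),
                            c("1" = "anterior", "2" = "middle",
                              "3" = "posterior")),
      names = c("anterior", "middle", "posterior"),
      membership = labels, seed_coords = coords),
      class = "subject_parcellation")
  }
  # voxel 1: anterior in 6/10, middle 2, posterior 1, absent 1 -> anterior
  # voxel 2: all frequencies below 0.25 -> background
  # voxel 3: identical across subjects -> that label
  subs <- lapply(1:10, function(s) {
    v1 <- if (s <= 6) 1L else if (s <= 8) 2L else if (s == 9) 3L else 0L
    v2 <- if (s <= 2) 1L else if (s == 3) 2L else if (s == 4) 3L else 0L
    mk_parc(c(v1, v2, 2L))
  })
  cons <- group_consolidate(subs, 0.25)
  expect_equal(as.vector(cons$data), c(1L, 0L, 2L))

  # identical parcellations consolidate to any single subject
  same <- lapply(1:5, function(s) mk_parc(c(1L, 2L, 3L)))
  expect_equal(group_consolidate(same, 0.25)$data, same[[1]]$labels$data)

  bad <- mk_parc(c(1L, 2L, 3L)); bad$names <- c("a", "b", "c")
  expect_error(group_consolidate(list(same[[1]], bad), 0.25),
               "names differ")
})
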