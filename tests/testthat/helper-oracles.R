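# Independent brute-force oracles and tiny fixture builders used across
# the suite. These deliberately avoid the package's vectorised code
# paths: plain loops, recomputed from the definitions.

# total SSE: deviation of each row from the mean row, written as loops
naive_total_sse <- function(C) {
  N <- nrow(C)
  tot <- 0
  for (i in 1:N) for (j in 1:N) {
    mbar <- 0
    for (m in 1:N) mbar <- mbar + C[m, j]
    mbar <- mbar / N
    tot <- tot + (C[i, j] - mbar)^2
  }
  tot
}

# within-cluster SSE with explicit membership indicators
naive_within_sse <- function(C, membership) {
  N <- nrow(C)
  tot <- 0
  for (k in unique(membership)) {
    members <- which(membership == k)
    for (i in members) for (j in 1:N) {
      ck <- 0
      for (m in members) ck <- ck + C[m, j]
      ck <- ck / length(members)
      tot <- tot + (C[i, j] - ck)^2
    }
  }
  tot
}

# greedy agglomeration over rows of C: at each step merge the pair of
# clusters whose union minimally increases total within-cluster SSE.
# Returns a list mapping K to the membership vector at that K.
greedy_ward_partitions <- function(C) {
  N <- nrow(C)
  clusters <- as.list(1:N)
  sse <- function(idx) {
    sub <- C[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  partitions <- list()
  snapshot <- function() {
    memb <- integer(N)
    for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
    memb
  }
  partitions[[as.character(N)]] <- snapshot()
  while (length(clusters) > 1L) {
    best <- NULL; best_inc <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      inc <- sse(c(clusters[[a]], clusters[[b]])) -
        sse(clusters[[a]]) - sse(clusters[[b]])
      if (inc < best_inc) { best_inc <- inc; best <- c(a, b) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    partitions[[as.character(length(clusters))]] <- snapshot()
  }
  partitions
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

make_prototypes_for_test <- function(spec) stnparc:::make_prototypes(spec)

# a minimal voxel_profiles object from a plain count matrix
tiny_profiles <- function(counts, n_samples = 5000L) {
  counts <- as.matrix(counts)
  coords <- cbind(0:(nrow(counts) - 1L), 0L, 0L)
  voxel_profiles(counts, coords, seed_dim = c(nrow(counts), 1L, 1L),
                 n_samples_per_voxel = n_samples)
}

# binary profiles wrapper without going through a threshold
tiny_binary <- function(mat) {
  p <- tiny_profiles(as.matrix(mat) * 5000L)
  binarize_profiles(p, 0.01)
}

# subregion_distributions built directly from three group-value vectors
tiny_distributions <- function(vals, n_subjects = 4L,
                               names = c("anterior", "middle", "posterior")) {
  dists <- lapply(vals, function(v)
    scalar_volume(array(v, c(length(v), 1L, 1L))))
  names(dists) <- names
  structure(list(distributions = dists, presence = NULL,
                 n_subjects = n_subjects, names = names),
            class = "subregion_distributions")
}
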