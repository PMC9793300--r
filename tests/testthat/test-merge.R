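test_that("cluster pair distance is the representative-path distance", {
  a <- make_cluster(1)
  expect_equal(cluster_pair_distance(a, a), 0)
  # parallel representatives 2 A apart
  t1 <- make_tunnel(cbind(seq(0, 8, length.out = 10), 0, 0))
  t2 <- make_tunnel(cbind(seq(0, 8, length.out = 10), 2, 0))
  c1 <- new_tunnel_cluster(list(t1))
  c2 <- new_tunnel_cluster(list(t2))
  expect_equal(cluster_pair_distance(c1, c2), 2)
  # random pair: brute-force recomputation
  b <- make_cluster(2)
  pa <- a$representative_path$nodes; pb <- b$representative_path$nodes
  brute <- mean(sqrt(rowSums((pa - pb)^2)))
  expect_equal(cluster_pair_distance(a, b), brute)
  expect_equal(cluster_pair_distance(b, a), brute)
})

test_that("mutually distant clusters from one slice map to themselves", {
  # three clusters far apart: merging is the identity
  far <- lapply(1:3, function(i) {
    t <- make_tunnel(cbind(seq(0, 10, length.out = 12), 0, 0) +
                       rep(c(0, 40 * i, 0), each = 12), frame = i)
    new_tunnel_cluster(list(t), slice_index = 1L, cluster_id = i)
  })
  scs <- merge_superclusters(far, cutoff = 1.0, total_frames = 3)
  expect_length(scs, 3)
  expect_true(all(vapply(scs, function(s) length(s$members), integer(1)) == 1))
  expect_length(merge_superclusters(list(), 1.0, 1), 0)
})

test_that("the same channel seen in all slices merges into one supercluster", {
  # 4 slices x 3 frames of one persistent channel (tiny coordinate jitter)
  clusters <- list()
  for (s in 1:4) {
    tunnels <- lapply(1:3, function(i) {
      set.seed(s * 10 + i)
      make_tunnel(cbind(seq(0, 12, length.out = 15), 0, 0) +
                    matrix(rnorm(45, sd = 0.05), ncol = 3),
                  frame = (s - 1L) * 3L + i)
    })
    clusters[[s]] <- new_tunnel_cluster(tunnels, slice_index = s,
                                        cluster_id = 1L)
  }
  scs <- merge_superclusters(clusters, cutoff = 1.0, total_frames = 12)
  expect_length(scs, 1)
  st <- compute_stats(scs[[1]])
  expect_equal(st$n_frames, 12)
  expect_equal(sort(scs[[1]]$frames_present), 1:12)
})

test_that("merging matches the brute-force Ward oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:14, 1)
    # a few well-separated families plus noise keeps instances non-trivial
    cls <- lapply(seq_len(n), function(i)
      make_cluster(seed * 200 + i, slice = i, id = 1L, frame = i))
    cutoff <- runif(1, 2, 12)
    scs <- merge_superclusters(cls, cutoff = cutoff, total_frames = n)
    memb <- integer(n)
    for (si in seq_along(scs)) for (m in scs[[si]]$members)
      memb[m$slice_index] <- si
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      D[i, j] <- cluster_pair_distance(cls[[i]], cls[[j]])
    oracle <- oracle_ward_cut(D, cutoff)
    expect_equal(canon_partition(memb), canon_partition(oracle),
                 label = paste("seed", seed))
  }
})

test_that("shrinking the Ward cutoff never decreases the supercluster count", {
  cls <- lapply(1:10, function(i) make_cluster(i * 31, slice = i, frame = i))
  counts <- vapply(c(20, 10, 5, 2, 1, 0.5), function(h)
    length(merge_superclusters(cls, h, total_frames = 10)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("supercluster statistics follow the per-frame representatives", {
  t1 <- make_tunnel(cbind(seq(0, 15, length.out = 10), 0, 0),
                    radii = c(rep(1.2, 5), 0.9, rep(1.2, 4)), frame = 1L)
  c1 <- new_tunnel_cluster(list(t1), slice_index = 1L, cluster_id = 1L)
  sc <- new_super_cluster(list(c1))
  st <- compute_stats(sc)
  expect_equal(st, data.frame(n_frames = 1L, avg_bottleneck = 0.9,
                              avg_length = 15, max_bottleneck = 0.9),
               tolerance = 1e-12)
  # two members covering frames 1-3 and 4-6, all bottlenecks 1.0
  mk <- function(frames, slice) {
    new_tunnel_cluster(lapply(frames, function(f)
      make_tunnel(cbind(seq(0, 10, length.out = 8), 0, 0),
                  radii = rep(1, 8), frame = f)),
      slice_index = slice, cluster_id = 1L)
  }
  sc2 <- new_super_cluster(list(mk(1:3, 1L), mk(4:6, 2L)))
  st2 <- compute_stats(sc2)
  expect_equal(st2$n_frames, 6L)
  expect_equal(st2$avg_bottleneck, 1.0)
  expect_equal(st2$max_bottleneck, 1.0)
  # designed per-frame bottleneck sequence: stats equal direct recomputation
  radii_seq <- c(1.1, 0.8, 1.4, 0.95, 1.25)
  tunnels <- lapply(seq_along(radii_seq), function(f)
    make_tunnel(cbind(seq(0, 12, length.out = 6), 0, 0),
                radii = rep(radii_seq[f], 6), frame = f))
  sc3 <- new_super_cluster(list(new_tunnel_cluster(tunnels)))
  st3 <- compute_stats(sc3)
  expect_equal(st3$avg_bottleneck, mean(radii_seq))
  expect_equal(st3$max_bottleneck, max(radii_seq))
})

test_that("match_clusterings reports identity and split correspondences", {
  cls <- lapply(1:3, function(i) {
    t <- make_tunnel(cbind(seq(0, 10, length.out = 12), 0, 0) +
                       rep(c(0, 30 * i, 0), each = 12), frame = i)
    new_tunnel_cluster(list(t), slice_index = 1L, cluster_id = i)
  })
  scs <- merge_superclusters(cls, 1.0, total_frames = 3)
  m <- match_clusterings(scs, scs, tol = 1.0)
  expect_equal(nrow(m), 3)
  expect_equal(m$ref_id, m$other_id)
  expect_true(all(m$jaccard == 1))
  # one reference cluster split into two, covering disjoint frames
  both <- new_tunnel_cluster(lapply(1:4, function(f)
    make_tunnel(cbind(seq(0, 10, length.out = 12), 0, 0), frame = f)))
  ref <- merge_superclusters(list(both), 1.0, total_frames = 4)
  half <- function(frames, slice) new_tunnel_cluster(
    lapply(frames, function(f)
      make_tunnel(cbind(seq(0, 10, length.out = 12), 0, 0), frame = f)),
    slice_index = slice, cluster_id = 1L)
  split2 <- list(new_super_cluster(list(half(1:2, 1L)), super_id = 1L),
                 new_super_cluster(list(half(3:4, 2L)), super_id = 2L))
  ms <- match_clusterings(ref, split2, tol = 1.0)
  expect_equal(nrow(ms), 2)
  expect_equal(ms$ref_id, c(1L, 1L))
  expect_equal(sort(ms$other_id), 1:2)
  expect_equal(ms$jaccard, c(0.5, 0.5))
})
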