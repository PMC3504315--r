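test_that("Gromos clustering handles the degenerate limits", {
  dup <- random_ensemble(A = 6, F = 1, seed = 1)
  frames <- array(dup$frames[, , 1], dim = c(6, 3, 8))
  same <- conformational_ensemble(dup$topology, frames)
  cs <- gromos_cluster(same, 0.4, "ca")
  expect_equal(length(cs$clusters), 1)
  expect_equal(cs$clusters[[1]]$weight, 1.0)

  # cutoff below the minimum pairwise distance: all singletons, own medoids
  spread <- random_ensemble(A = 6, F = 7, sd = 3, seed = 2)
  M <- pairwise_rmsd_matrix(spread, "ca")
  tiny <- min(M[upper.tri(M)]) / 2
  cs2 <- gromos_cluster(spread, tiny, "ca")
  expect_equal(length(cs2$clusters), 7)
  expect_true(all(vapply(cs2$clusters, function(cl)
    cl$medoid == cl$members[1] && length(cl$members) == 1, TRUE)))

  expect_error(gromos_cluster(spread, 0), "positive")
})

test_that("Gromos clustering equals the brute-force greedy oracle", {
  set.seed(10)
  for (rep in 1:60) {
    Fn <- sample(5:20, 1)
    pts <- matrix(rnorm(Fn * 2), Fn, 2)
    M <- as.matrix(dist(pts))
    cutoff <- runif(1, 0.2, 2.5)
    ours <- lapply(gromos_cluster_matrix(M, cutoff)$clusters, `[[`, "members")
    expect_identical(ours, gromos_oracle(M, cutoff))
  }
  # the first extracted cluster maximizes the neighbourhood size
  set.seed(11)
  M <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  cs <- gromos_cluster_matrix(M, 0.8)
  adj <- M <= 0.8
  expect_equal(length(cs$clusters[[1]]$members), max(rowSums(adj)))
})

test_that("cluster sets partition the frames with unit total weight", {
  ens <- random_ensemble(A = 8, F = 25, sd = 0.8, seed = 3)
  cs <- gromos_cluster(ens, 0.5, "ca")
  members <- sort(unlist(lapply(cs$clusters, `[[`, "members")))
  expect_identical(members, 1:25)
  expect_equal(sum(vapply(cs$clusters, `[[`, 0, "weight")), 1,
               tolerance = 1e-12)
  m <- cluster_membership(cs)
  expect_true(all(m >= 1))
  for (k in seq_along(cs$clusters))
    expect_true(cs$clusters[[k]]$medoid %in% cs$clusters[[k]]$members)
})

test_that("smaller cutoffs never produce fewer clusters", {
  ens <- random_ensemble(A = 8, F = 20, sd = 0.8, seed = 6)
  M <- pairwise_rmsd_matrix(ens, "ca")
  n_by_cutoff <- vapply(c(1.2, 0.8, 0.5, 0.3, 0.15), function(co)
    length(gromos_cluster_matrix(M, co)$clusters), 1L)
  expect_true(all(diff(n_by_cutoff) >= 0))
})

test_that("order parameter hits its closed-form anchors", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(order_parameter(list(X), 1)$O, 1, tolerance = 1e-12)

  # two identical conformations, split weights: still 1
  expect_equal(order_parameter(list(X, X), c(0.5, 0.5))$O, 1,
               tolerance = 1e-12)

  # n mutually distant conformations: O = log2(1 + 1/n). Structures of very
  # different spatial extent stay distant after superposition (a rigid fit
  # would remove a mere translation), so D^2 >> <D^2> for every pair.
  for (n in 2:5) {
    reps <- lapply(1:n, function(k) matrix(rnorm(30, sd = 5 * k), 10, 3))
    o <- order_parameter(reps, rep(1 / n, n))
    expect_equal(o$O, log2(1 + 1 / n), tolerance = 1e-9)
  }
  expect_equal(order_parameter_uniform(2, 1e9), log2(1.5), tolerance = 1e-12)

  expect_error(order_parameter(list(X, X), c(0.7, 0.2)), "sum to 1")
  expect_error(order_parameter(list(X, X[1:5, ]), c(0.5, 0.5)), "count")
})

test_that("order parameter is invariant to duplicating a representative", {
  set.seed(2)
  reps <- lapply(1:3, function(k) matrix(rnorm(30, sd = 0.3), 10, 3))
  w <- c(0.5, 0.3, 0.2)
  o1 <- order_parameter(reps, w)$O
  o2 <- order_parameter(c(reps, reps[3]), c(0.5, 0.3, 0.1, 0.1))$O
  expect_equal(o2, o1, tolerance = 1e-12)
})

test_that("order parameter decreases when distances are scaled up", {
  set.seed(3)
  D2 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))^2
  w <- rep(1 / 6, 6)
  scales <- c(0.5, 1, 2, 4, 8)
  os <- vapply(scales, function(s) order_parameter_d2(D2 * s, w), 0)
  expect_true(all(diff(os) < 0))
  expect_true(all(os > 0 & os <= 1))
})

test_that("the disorder profile reproduces planted-state geometry", {
  # identical frames: every cutoff gives one cluster and O = 1
  one <- random_ensemble(A = 6, F = 1, seed = 4)
  frames <- array(one$frames[, , 1], dim = c(6, 3, 10))
  same <- conformational_ensemble(one$topology, frames)
  prof <- disorder_profile(same, c(0.3, 0.4, 0.5))
  expect_true(all(prof$n_clusters == 1))
  expect_true(all(abs(prof$O - 1) < 1e-12))

  # 5 planted distant states, equal weights, tiny intra-state noise:
  # n_clusters = 5 and O ~ log2(1 + 1/5)
  set.seed(5)
  A <- 10
  # states of very different spatial extent: distant even after superposition
  centers <- lapply(1:5, function(k) matrix(rnorm(A * 3, sd = 2 * k), A, 3))
  frames <- array(NA_real_, dim = c(A, 3, 20))
  state <- rep(1:5, each = 4)
  for (f in 1:20)
    frames[, , f] <- centers[[state[f]]] + rnorm(A * 3, sd = 0.001)
  ens5 <- conformational_ensemble(list(atom_names = rep("CA", A),
                                       residue_names = rep("ALA", A),
                                       residue_ids = 1:A,
                                       elements = rep("C", A)), frames)
  prof5 <- disorder_profile(ens5, 0.4, selection = "ca")
  expect_equal(prof5$n_clusters, 5)
  expect_equal(prof5$O, log2(1 + 1 / 5), tolerance = 0.02)
})
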