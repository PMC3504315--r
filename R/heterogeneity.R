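#' Gromos clustering of an ensemble
#'
#' Greedy neighbour-count clustering on the pairwise RMSD matrix: the frame
#' with the most neighbours within `rmsd_cutoff` becomes the first cluster
#' centre, it and its neighbours are removed, and the procedure repeats until
#' every frame is assigned. Ties in neighbour count are broken by lowest frame
#' index for determinism. The medoid of each cluster is the member with the
#' lowest mean RMSD to the other members.
#'
#' @param ensemble a [conformational_ensemble()].
#' @param rmsd_cutoff neighbour cutoff, nm (> 0).
#' @param selection atom selection used for the RMSD (default main chain).
#' @param rmsd_matrix optional precomputed `F x F` RMSD matrix (reused across
#'   cutoffs).
#' @return an object of class `cluster_set`: per-cluster member frame indices,
#'   medoid frame index and weight `w = members / F`.
#' @export
gromos_cluster <- function(ensemble, rmsd_cutoff = 0.4, selection = "mainchain",
                           rmsd_matrix = NULL) {
  if (rmsd_cutoff <= 0) stop("rmsd_cutoff must be positive")
  F_ <- n_frames(ensemble)
  M <- if (is.null(rmsd_matrix)) {
    if (F_ == 1) matrix(0, 1, 1) else pairwise_rmsd_matrix(ensemble, selection)
  } else rmsd_matrix
  cs <- gromos_cluster_matrix(M, rmsd_cutoff)
  cs$selection <- if (is.character(selection)) selection else "custom"
  cs
}

#' Gromos clustering on a precomputed distance matrix
#'
#' @param M symmetric `F x F` distance matrix with zero diagonal.
#' @param cutoff neighbour cutoff (> 0), same units as `M`.
#' @return a `cluster_set` (see [gromos_cluster()]).
#' @export
gromos_cluster_matrix <- function(M, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive")
  M <- as.matrix(M)
  F_ <- nrow(M)
  adj <- M <= cutoff
  diag(adj) <- TRUE
  remaining <- rep(TRUE, F_)
  clusters <- list()
  while (any(remaining)) {
    counts <- colSums(adj[remaining, , drop = FALSE]) # neighbours still in pool
    counts[!remaining] <- -1L
    centre <- which.max(counts)  # which.max takes the first (lowest index) tie
    members <- which(remaining & adj[centre, ])
    if (length(members) == 1) {
      medoid <- members
    } else {
      sub <- M[members, members, drop = FALSE]
      medoid <- members[which.min(rowSums(sub) / (length(members) - 1))]
    }
    clusters[[length(clusters) + 1L]] <-
      list(members = members, centre = centre, medoid = medoid,
           weight = length(members) / F_)
    remaining[members] <- FALSE
  }
  structure(list(clusters = clusters, rmsd_cutoff = cutoff, n_frames = F_),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  w <- vapply(x$clusters, `[[`, 0, "weight")
  cat(sprintf("Gromos clustering: %d clusters of %d frames (cutoff %.3g)\n",
              length(x$clusters), x$n_frames, x$rmsd_cutoff))
  cat(sprintf("  largest cluster weight %.3f\n", max(w)))
  invisible(x)
}

#' Membership vector of a cluster set
#' @param cs a `cluster_set`.
#' @return integer vector: cluster number of every frame.
#' @export
cluster_membership <- function(cs) {
  out <- integer(cs$n_frames)
  for (k in seq_along(cs$clusters)) out[cs$clusters[[k]]$members] <- k
  out
}

#' Fisher-Stultz ensemble order parameter
#'
#' `O = sum_i w_i log2[ 1 + sum_j w_j exp( -D^2(s_i, s_j) / (2 <D^2>) ) ]`,
#' where `D^2` is the pairwise Calpha mean-square distance between
#' representative conformations, the weights are the relative cluster sizes,
#' and `<D^2>` is the mean-square fluctuation scale of a typical folded
#' protein (0.27 nm^2 by default). `O = 1` for a single conformation and
#' tends to 0 for an infinite number of equally populated, mutually different
#' conformations.
#'
#' @param representatives a [conformational_ensemble()] of representative
#'   structures (e.g. cluster medoids), or a list of `A x 3` Calpha coordinate
#'   matrices.
#' @param weights non-negative weights summing to 1 (tolerance 1e-6).
#' @param msd_scale reference mean-square distance `<D^2>`, nm^2.
#' @param fit superpose each pair optimally before the distance (default) or
#'   use coordinates as-is.
#' @return an object of class `order_parameter_result` with elements `O`,
#'   `n_clusters`, `weights`, `msd_scale` and the `D2` matrix.
#' @export
order_parameter <- function(representatives, weights, msd_scale = 0.27,
                            fit = TRUE) {
  if (inherits(representatives, "conformational_ensemble")) {
    idx <- select_atoms(representatives, "ca")
    reps <- lapply(seq_len(n_frames(representatives)),
                   function(f) representatives$frames[idx, , f])
  } else {
    reps <- representatives
  }
  n <- length(reps)
  if (length(weights) != n) stop("one weight per representative is required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be non-negative and sum to 1 (within 1e-6)")
  ncas <- vapply(reps, nrow, 1L)
  if (length(unique(ncas)) != 1)
    stop("representatives must share the same Calpha count")
  D2 <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      D2[i, j] <- D2[j, i] <- rmsd_pair(reps[[i]], reps[[j]], fit = fit)^2
    }
  }
  O <- order_parameter_d2(D2, weights, msd_scale)
  structure(list(O = O, n_clusters = n, weights = weights,
                 msd_scale = msd_scale, D2 = D2),
            class = "order_parameter_result")
}

#' Order parameter from a precomputed squared-distance matrix
#'
#' @param D2 symmetric `n x n` matrix of pairwise Calpha mean-square
#'   distances, nm^2.
#' @param weights non-negative weights summing to 1.
#' @param msd_scale reference mean-square distance `<D^2>`, nm^2.
#' @return the scalar order parameter `O` in `(0, 1]`.
#' @export
order_parameter_d2 <- function(D2, weights, msd_scale = 0.27) {
  S <- exp(-D2 / (2 * msd_scale))
  inner <- as.vector(S %*% weights)
  sum(weights * log2(1 + inner))
}

#' Order parameter of n exchangeable, equally weighted conformations
#'
#' Closed form for the exchangeable geometry in which all pairwise
#' mean-square distances share one value `d2`: with uniform weights `1/n`,
#' `O = log2(1 + 1/n + (1 - 1/n) exp(-d2 / (2 <D^2>)))`. For `d2` much larger
#' than `<D^2>` this reduces to `log2(1 + 1/n)`, whose limit for unboundedly
#' many equally populated conformations is 0; for `d2 = 0` it is 1. Evaluable
#' for arbitrarily large `n` without constructing coordinates.
#'
#' @param n number of conformations.
#' @param d2 common pairwise mean-square distance, nm^2.
#' @param msd_scale reference mean-square distance `<D^2>`, nm^2.
#' @return the scalar order parameter.
#' @export
order_parameter_uniform <- function(n, d2, msd_scale = 0.27) {
  w <- 1 / n
  log2(1 + w + (1 - w) * exp(-d2 / (2 * msd_scale)))
}

#' @export
print.order_parameter_result <- function(x, ...) {
  cat(sprintf("Order parameter O = %.4f (%d representatives, <D^2> = %.3g nm^2)\n",
              x$O, x$n_clusters, x$msd_scale))
  invisible(x)
}

#' Disorder profile: clusters and order parameter across RMSD cutoffs
#'
#' For each cutoff the ensemble is Gromos-clustered on the main-chain RMSD
#' matrix, the cluster medoids and relative-size weights are extracted, and
#' the order parameter is computed on the medoids' Calpha coordinates --
#' the full ensemble-heterogeneity workflow in one call.
#'
#' @param ensemble a [conformational_ensemble()].
#' @param cutoffs RMSD cutoffs, nm (all > 0).
#' @param selection atom selection for clustering RMSDs.
#' @param msd_scale reference `<D^2>`, nm^2.
#' @return data frame with columns `cutoff`, `n_clusters`, `O`.
#' @export
disorder_profile <- function(ensemble, cutoffs = c(0.3, 0.4, 0.5),
                             selection = "mainchain", msd_scale = 0.27) {
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  F_ <- n_frames(ensemble)
  M <- if (F_ == 1) matrix(0, 1, 1) else pairwise_rmsd_matrix(ensemble, selection)
  ca <- select_atoms(ensemble, "ca")
  rows <- lapply(cutoffs, function(co) {
    cs <- gromos_cluster_matrix(M, co)
    med <- vapply(cs$clusters, `[[`, 1L, "medoid")
    w <- vapply(cs$clusters, `[[`, 0, "weight")
    reps <- lapply(med, function(f) ensemble$frames[ca, , f])
    o <- order_parameter(reps, w, msd_scale = msd_scale)
    data.frame(cutoff = co, n_clusters = length(cs$clusters), O = o$O)
  })
  do.call(rbind, rows)
}
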