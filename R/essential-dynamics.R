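#' Principal component analysis of positional fluctuations
#'
#' Eigen-decomposition of the (optionally mass-weighted) covariance matrix of
#' Cartesian coordinates about their ensemble mean -- the essential-dynamics
#' description of the dominant collective motions. The ensemble should be
#' superposed first ([superpose_ensemble()]) so that rigid-body motion does not
#' contaminate the fluctuations.
#'
#' When the coordinate dimension `3A` exceeds `dual_threshold` the
#' decomposition is computed through the frame-space (`F x F`) dual problem,
#' which yields the identical non-zero spectrum at much lower cost for
#' all-atom selections.
#'
#' @param ensemble a superposed [conformational_ensemble()] with `F > 1`.
#' @param selection atom selection (see [select_atoms()]); `"ca"` or `"all"`
#'   are the standard choices.
#' @param mass_weighted logical; weight each coordinate by sqrt(mass) (amu).
#' @param dual_threshold coordinate dimension above which the dual solver is
#'   used.
#' @return an object of class `ensemble_pca` with orthonormal `eigenvectors`
#'   (columns, descending eigenvalue order), non-negative `eigenvalues`
#'   (nm^2, or nm^2 amu if mass-weighted), the `mean` structure of the
#'   selection, and bookkeeping fields.
#' @export
fit_pca <- function(ensemble, selection = "ca", mass_weighted = FALSE,
                    dual_threshold = 3000) {
  idx <- select_atoms(ensemble, selection)
  F_ <- n_frames(ensemble)
  if (F_ < 2) stop("PCA needs more than one frame (no fluctuations in F = 1)")
  A <- length(idx)
  # F x 3A coordinate matrix, atom-major (x1 y1 z1 x2 ...)
  X <- t(matrix(aperm(ensemble$frames[idx, , , drop = FALSE], c(2, 1, 3)),
                nrow = 3 * A, ncol = F_))
  w <- if (mass_weighted)
    sqrt(rep(atom_masses(ensemble$topology$elements[idx]), each = 3))
  else rep(1, 3 * A)
  Xw <- sweep(X, 2, w, `*`)
  mu <- colMeans(Xw)
  Xc <- sweep(Xw, 2, mu)
  if (3 * A <= dual_threshold) {
    C <- crossprod(Xc) / (F_ - 1)
    e <- eigen(C, symmetric = TRUE)
    vals <- e$values
    vecs <- e$vectors
  } else {
    K <- tcrossprod(Xc) / (F_ - 1)
    e <- eigen(K, symmetric = TRUE)
    keep <- which(e$values > max(e$values) * 1e-12)
    vals <- c(e$values[keep], rep(0, min(3 * A, F_) - length(keep)))
    vecs <- crossprod(Xc, e$vectors[, keep, drop = FALSE])
    vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), `/`)
    vals <- vals[seq_len(ncol(vecs))]
  }
  vals[vals < 0] <- 0
  structure(list(eigenvectors = vecs, eigenvalues = vals,
                 mean = matrix(mu / w, ncol = 3, byrow = TRUE),
                 mean_weighted = mu,
                 selection = idx, selection_label =
                   if (is.character(selection)) selection else "custom",
                 mass_weighted = mass_weighted, weights = w,
                 n_frames = F_),
            class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  k <- min(3, length(x$eigenvalues))
  cat("Essential-dynamics PCA:", nrow(x$eigenvectors), "coordinates,",
      x$n_frames, "frames",
      if (x$mass_weighted) "(mass-weighted)" else "", "\n")
  cat(sprintf("  first %d PCs carry %.1f%% of the variance\n", k,
              100 * sum(x$eigenvalues[seq_len(k)]) / tot))
  invisible(x)
}

#' Project ensemble frames onto principal components
#'
#' Centers the (mass-)weighted coordinates of each frame on the decomposition
#' mean and takes inner products with the first `k` eigenvectors, giving the
#' reaction coordinates used for free-energy-landscape estimation.
#'
#' @param ensemble a [conformational_ensemble()] over the same atoms as `eig`.
#' @param eig an [fit_pca()] decomposition.
#' @param k number of leading components.
#' @return an object of class `projection_set`: matrix `values` (`F x k`) plus
#'   the decomposition reference.
#' @export
project_frames <- function(ensemble, eig, k = 2) {
  stopifnot(inherits(eig, "ensemble_pca"))
  if (k > ncol(eig$eigenvectors)) stop("k exceeds available eigenvectors")
  idx <- eig$selection
  if (max(idx) > n_atoms(ensemble))
    stop("ensemble does not cover the decomposition's atom selection")
  F_ <- n_frames(ensemble)
  A <- length(idx)
  X <- t(matrix(aperm(ensemble$frames[idx, , , drop = FALSE], c(2, 1, 3)),
                nrow = 3 * A, ncol = F_))
  Xc <- sweep(sweep(X, 2, eig$weights, `*`), 2, eig$mean_weighted)
  structure(list(values = Xc %*% eig$eigenvectors[, seq_len(k), drop = FALSE],
                 eig = eig),
            class = "projection_set")
}

#' Cumulative explained variance of the leading components
#'
#' @param eig an [fit_pca()] decomposition.
#' @param k number of leading components.
#' @return fraction in `[0, 1]`: `sum(lambda[1:k]) / sum(lambda)`.
#' @export
cumulative_variance <- function(eig, k) {
  stopifnot(k >= 1, k <= length(eig$eigenvalues))
  sum(eig$eigenvalues[seq_len(k)]) / sum(eig$eigenvalues)
}

#' Root mean square inner product between two essential subspaces
#'
#' `RMSIP = sqrt( (1/d) * sum_{i<=d} sum_{j<=d} (eta_i^A . eta_j^B)^2 )`,
#' the standard measure of overlap between the subspaces spanned by the first
#' `d` eigenvectors of two decompositions: 1 for identical subspaces, 0 for
#' mutually orthogonal ones. A value above 0.5 for the first 10 eigenvectors
#' is the usual convergence benchmark for independent trajectory replicates.
#'
#' @param eigA,eigB [fit_pca()] decompositions over the same coordinate
#'   dimension (or plain matrices whose columns are orthonormal eigenvectors).
#' @param d subspace dimension to compare (default 10).
#' @return RMSIP value in `[0, 1]`.
#' @export
rmsip <- function(eigA, eigB, d = 10) {
  VA <- if (inherits(eigA, "ensemble_pca")) eigA$eigenvectors else as.matrix(eigA)
  VB <- if (inherits(eigB, "ensemble_pca")) eigB$eigenvectors else as.matrix(eigB)
  if (nrow(VA) != nrow(VB)) stop("eigenvector dimensions differ")
  if (d > ncol(VA) || d > ncol(VB)) stop("d exceeds available eigenvectors")
  M <- crossprod(VA[, seq_len(d), drop = FALSE], VB[, seq_len(d), drop = FALSE])
  sqrt(sum(M^2) / d)
}
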