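#' Read a multi-model PDB file as a conformational ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file with a single bare
#' coordinate block yields a one-frame ensemble. Coordinates are converted from
#' Angstrom (the PDB unit) to nm at the boundary; the topology is taken from
#' the first model and every subsequent model is checked against it atom by
#' atom.
#'
#' @param path path to a PDB file.
#' @return a [conformational_ensemble()] with `source_units = "angstrom"`.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no atoms found in ", path)

  if (length(model_starts) == 0) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines))
    blocks <- lapply(seq_along(model_starts), function(k) {
      rng <- seq(model_starts[k], model_ends[k])
      rng[is_atom[rng]]
    })
  }

  parse_block <- function(idx) {
    rec <- lines[idx]
    list(atom_names = trimws(substr(rec, 13, 16)),
         residue_names = trimws(substr(rec, 18, 20)),
         residue_ids = as.integer(substr(rec, 23, 26)),
         elements = {
           el <- trimws(substr(rec, 77, 78))
           guess <- substr(gsub("[^A-Za-z]", "", trimws(substr(rec, 13, 16))), 1, 1)
           ifelse(el == "", guess, el)
         },
         xyz = cbind(as.numeric(substr(rec, 31, 38)),
                     as.numeric(substr(rec, 39, 46)),
                     as.numeric(substr(rec, 47, 54))) / 10)  # Angstrom -> nm
  }

  first <- parse_block(blocks[[1]])
  A <- length(first$atom_names)
  if (A == 0) stop("MODEL 1 contains zero atoms")
  frames <- array(NA_real_, dim = c(A, 3, length(blocks)))
  frames[, , 1] <- first$xyz
  for (k in seq_along(blocks)[-1]) {
    b <- parse_block(blocks[[k]])
    if (length(b$atom_names) != A)
      stop(sprintf("MODEL %d has %d atoms, expected %d (MODEL 1)",
                   k, length(b$atom_names), A))
    if (!identical(b$atom_names, first$atom_names) ||
        !identical(b$residue_ids, first$residue_ids) ||
        !identical(b$residue_names, first$residue_names))
      stop(sprintf("MODEL %d atom identity differs from MODEL 1", k))
    frames[, , k] <- b$xyz
  }
  conformational_ensemble(first, frames, source_units = "angstrom")
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` pair per frame; coordinates are written in Angstrom at
#' PDB fixed-width precision (0.001 A), so a read/write round trip preserves
#' coordinates to 1e-4 nm.
#'
#' @param ensemble a [conformational_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformational_ensemble"))
  top <- ensemble$topology
  A <- n_atoms(ensemble)
  name_field <- ifelse(nchar(top$atom_names) >= 4,
                       substr(top$atom_names, 1, 4),
                       sprintf(" %-3s", top$atom_names))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble$frames[, , f] * 10  # nm -> Angstrom
    writeLines(sprintf("ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(A), name_field, top$residue_names,
                       top$residue_ids, xyz[, 1], xyz[, 2], xyz[, 3],
                       top$elements), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Concatenate replicate ensembles into a macro-trajectory
#'
#' Members must share an identical topology. The first `discard_head` frames of
#' each member (equilibration) are dropped; `frame_labels` record the source
#' replicate of every retained frame.
#'
#' @param ensembles list of [conformational_ensemble()] objects, in order.
#' @param discard_head integer, frames to discard at the head of each member;
#'   scalar or one value per member.
#' @param labels optional replicate labels (default `r1`, `r2`, ...).
#' @return a single concatenated [conformational_ensemble()].
#' @export
concatenate_ensembles <- function(ensembles, discard_head = 0, labels = NULL) {
  stopifnot(length(ensembles) >= 1)
  discard <- rep_len(as.integer(discard_head), length(ensembles))
  if (is.null(labels)) labels <- paste0("r", seq_along(ensembles))
  ref <- ensembles[[1]]$topology
  kept <- vector("list", length(ensembles))
  lab <- vector("list", length(ensembles))
  for (k in seq_along(ensembles)) {
    e <- ensembles[[k]]
    if (!identical(e$topology, ref))
      stop("topology of member ", k, " differs from member 1")
    Fk <- n_frames(e)
    if (discard[k] >= Fk)
      stop("discard_head (", discard[k], ") >= frame count (", Fk,
           ") for member ", k)
    idx <- seq.int(discard[k] + 1L, Fk)
    kept[[k]] <- e$frames[, , idx, drop = FALSE]
    lab[[k]] <- rep(labels[k], length(idx))
  }
  frames <- array(unlist(kept), dim = c(dim(kept[[1]])[1], 3,
                                        sum(vapply(kept, function(x) dim(x)[3], 1L))))
  conformational_ensemble(ref, frames, frame_labels = unlist(lab),
                          source_units = ensembles[[1]]$source_units)
}

#' Remove rigid-body motion by least-squares superposition
#'
#' Each frame is fitted onto a reference by the optimal (Kabsch) rigid-body
#' transform over the selected atoms. With `reference = "mean"` the fit is
#' iterative: fit every frame to the reference, recompute the mean structure,
#' refit to the mean, until the mean shifts by less than `tol` (at most
#' `max_iter` iterations) -- the standard preparation for covariance analysis
#' of positional fluctuations.
#'
#' The iteration starts from the current ensemble mean (falling back to frame
#' 1 if that mean is degenerate), which makes the operation idempotent: a
#' superposed ensemble is its own fixed point.
#'
#' @param ensemble a [conformational_ensemble()].
#' @param selection atom selection for the fit (see [select_atoms()]).
#' @param reference `"mean"` for the iterative mean structure, or a frame index.
#' @param tol convergence tolerance on the mean shift, nm.
#' @param max_iter iteration cap for the iterative-mean fit.
#' @return the superposed [conformational_ensemble()].
#' @export
superpose_ensemble <- function(ensemble, selection = "ca", reference = "mean",
                               tol = 1e-12, max_iter = 200) {
  idx <- select_atoms(ensemble, selection)
  if (length(idx) < 3) stop("superposition needs at least 3 selected atoms")
  F_ <- n_frames(ensemble)
  frames <- ensemble$frames
  fit_all <- function(frames, ref_xyz) {
    for (f in seq_len(F_))
      frames[, , f] <- superpose_onto(frames[, , f], ref_xyz, idx)
    frames
  }
  if (identical(reference, "mean")) {
    ref_xyz <- apply(frames, c(1, 2), mean)
    if (sqrt(sum(scale(ref_xyz[idx, ], scale = FALSE)^2)) < 1e-6)
      ref_xyz <- frames[, , 1]  # degenerate mean (e.g. random rotations)
    for (it in seq_len(max_iter)) {
      frames <- fit_all(frames, ref_xyz)
      new_ref <- apply(frames, c(1, 2), mean)
      shift <- sqrt(sum((new_ref[idx, ] - ref_xyz[idx, ])^2) / length(idx))
      ref_xyz <- new_ref
      if (shift < tol) break
    }
  } else {
    ref_i <- as.integer(reference)
    stopifnot(ref_i >= 1, ref_i <= F_)
    frames <- fit_all(frames, frames[, , ref_i])
  }
  conformational_ensemble(ensemble$topology, frames,
                          frame_labels = ensemble$frame_labels,
                          source_units = ensemble$source_units)
}

#' Pairwise RMSD matrix over an ensemble
#'
#' Symmetric `F x F` matrix of least-squares RMSDs over the selected atoms. By
#' default every pair is optimally superposed before the RMSD is taken
#' (`fit = "pairwise"`); `fit = "none"` uses the coordinates as they are (one
#' prior global superposition).
#'
#' @param ensemble a [conformational_ensemble()] with `F >= 2`.
#' @param selection atom selection (see [select_atoms()]).
#' @param fit `"pairwise"` or `"none"`.
#' @return numeric `F x F` symmetric matrix, nm.
#' @export
pairwise_rmsd_matrix <- function(ensemble, selection = "mainchain",
                                 fit = c("pairwise", "none")) {
  fit <- match.arg(fit)
  idx <- select_atoms(ensemble, selection)
  F_ <- n_frames(ensemble)
  if (F_ < 2) stop("pairwise RMSD needs at least 2 frames")
  n <- length(idx)
  # pre-centered selected coordinates per frame
  coords <- lapply(seq_len(F_), function(f) {
    X <- ensemble$frames[idx, , f]
    if (fit == "pairwise") sweep(X, 2, colMeans(X)) else X
  })
  ssq <- vapply(coords, function(X) sum(X^2), 0)
  M <- matrix(0, F_, F_)
  for (i in seq_len(F_ - 1L)) {
    Xi <- coords[[i]]
    for (j in seq.int(i + 1L, F_)) {
      if (fit == "pairwise") {
        Xj <- coords[[j]]
        s <- svd(crossprod(Xi, Xj))
        d <- sign(det(tcrossprod(s$v, s$u)))
        R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
        val <- sqrt(sum((Xi %*% R - Xj)^2) / n)
      } else {
        val <- sqrt(sum((Xi - coords[[j]])^2) / n)
      }
      M[i, j] <- M[j, i] <- val
    }
  }
  M
}
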