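#' Structural model: an atom table with one set of coordinates
#'
#' A minimal topology-plus-coordinates container: atom names, residue names
#' (3-letter codes), 1-based residue identifiers, element symbols, and an
#' `A x 3` coordinate matrix in nanometres.
#'
#' @param atom_names character vector of atom names (e.g. `"CA"`).
#' @param residue_names character vector of 3-letter residue codes.
#' @param residue_ids integer vector, monotone non-decreasing.
#' @param elements character vector of element symbols.
#' @param coordinates numeric `A x 3` matrix, nm.
#' @return An object of class `structural_model`.
#' @export
structural_model <- function(atom_names, residue_names, residue_ids, elements,
                             coordinates) {
  coordinates <- as.matrix(coordinates)
  A <- length(atom_names)
  if (A < 1) stop("structural model must contain at least one atom")
  if (length(residue_names) != A || length(residue_ids) != A ||
      length(elements) != A || nrow(coordinates) != A || ncol(coordinates) != 3)
    stop("atom table fields and coordinates must agree in length (A x 3)")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (is.unsorted(residue_ids)) stop("residue_ids must be non-decreasing")
  structure(list(atom_names = as.character(atom_names),
                 residue_names = as.character(residue_names),
                 residue_ids = as.integer(residue_ids),
                 elements = as.character(elements),
                 coordinates = coordinates),
            class = "structural_model")
}

#' Conformational ensemble: topology plus frames of coordinates
#'
#' The universal input of the package: an atom/residue topology shared by all
#' frames plus an `A x 3 x F` array of Cartesian coordinates, stored in nm.
#'
#' @param topology a `structural_model` (its coordinates are ignored) or a list
#'   with fields `atom_names`, `residue_names`, `residue_ids`, `elements`.
#' @param frames numeric array `A x 3 x F` (or a list of `A x 3` matrices), nm.
#' @param frame_labels optional character vector of length `F` (replicate id,
#'   time, ...).
#' @param source_units units the coordinates were read in (`"nm"` or
#'   `"angstrom"`); storage is always nm.
#' @return An object of class `conformational_ensemble`.
#' @export
conformational_ensemble <- function(topology, frames, frame_labels = NULL,
                                    source_units = "nm") {
  if (is.list(frames) && !is.array(frames)) {
    frames <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  }
  if (length(dim(frames)) == 2) frames <- array(frames, dim = c(dim(frames), 1))
  A <- length(topology$atom_names)
  if (dim(frames)[1] != A || dim(frames)[2] != 3)
    stop("frames must be an A x 3 x F array matching the topology")
  F_ <- dim(frames)[3]
  if (F_ < 1) stop("ensemble must contain at least one frame")
  if (!all(is.finite(frames))) stop("frame coordinates must be finite")
  if (!is.null(frame_labels) && length(frame_labels) != F_)
    stop("frame_labels must have one entry per frame")
  source_units <- match.arg(source_units, c("nm", "angstrom"))
  structure(list(topology = list(atom_names = as.character(topology$atom_names),
                                 residue_names = as.character(topology$residue_names),
                                 residue_ids = as.integer(topology$residue_ids),
                                 elements = as.character(topology$elements)),
                 frames = frames,
                 frame_labels = if (is.null(frame_labels)) NULL else as.character(frame_labels),
                 source_units = source_units),
            class = "conformational_ensemble")
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat("Conformational ensemble:",
      n_frames(x), "frames,",
      n_atoms(x), "atoms,",
      length(unique(x$topology$residue_ids)), "residues\n")
  invisible(x)
}

#' @export
print.structural_model <- function(x, ...) {
  cat("Structural model:", length(x$atom_names), "atoms,",
      length(unique(x$residue_ids)), "residues\n")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble a `conformational_ensemble`.
#' @return integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$frames)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$frames)[1]

#' Extract one frame as a structural model
#' @param ensemble a `conformational_ensemble`.
#' @param i frame index.
#' @return a `structural_model`.
#' @export
get_frame <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  with(ensemble$topology,
       structural_model(atom_names, residue_names, residue_ids, elements,
                        ensemble$frames[, , i]))
}

#' Resolve an atom selection to indices
#'
#' Named selections follow the field's conventions: `"ca"` selects the Calpha
#' trace, `"mainchain"` the backbone atoms N, CA, C, O, `"all"` every atom.
#' Logical or integer vectors are passed through (validated).
#'
#' @param ensemble a `conformational_ensemble` (or anything with a `$topology`).
#' @param selection `"ca"`, `"mainchain"`, `"all"`, or a logical/integer vector.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(ensemble, selection = "all") {
  top <- ensemble$topology
  A <- length(top$atom_names)
  if (is.character(selection) && length(selection) == 1) {
    idx <- switch(match.arg(selection, c("ca", "mainchain", "all")),
                  ca = which(top$atom_names == "CA"),
                  mainchain = which(top$atom_names %in% c("N", "CA", "C", "O")),
                  all = seq_len(A))
  } else if (is.logical(selection)) {
    if (length(selection) != A) stop("logical selection must have length A")
    idx <- which(selection)
  } else {
    idx <- as.integer(selection)
    if (any(idx < 1 | idx > A)) stop("selection indices out of range")
  }
  if (length(idx) == 0) stop("selection matches no atoms")
  idx
}

# Subset an ensemble to a fixed set of frames (labels follow).
subset_frames <- function(ensemble, frames_idx) {
  conformational_ensemble(ensemble$topology,
                          ensemble$frames[, , frames_idx, drop = FALSE],
                          frame_labels = ensemble$frame_labels[frames_idx],
                          source_units = ensemble$source_units)
}

# Standard atomic masses by element; pseudo/unknown atoms default to carbon.
atom_masses <- function(elements) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974)
  m <- tab[elements]
  m[is.na(m)] <- 12.011
  unname(m)
}
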