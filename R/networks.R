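# Per-frame intramolecular interaction detection, persistence matrices, and
# the persistence-weighted residue graph (hubs, components, simple paths).

.basic_res <- c("LYS", "ARG")
.acidic_res <- c("ASP", "GLU")
.aromatic_res <- c("PHE", "TYR", "TRP", "HIS")
.hydrophobic_res <- c("ALA", "VAL", "LEU", "ILE", "MET", "PRO", "PHE")

# Atom names carrying each interaction role in a full-atom topology; when a
# residue of the right type has none of them, its side-chain reference
# pseudo-atom (CB) stands in (minimal synthetic topologies).
.role_atoms <- list(
  basic_n = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")),
  acidic_o = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
  ring = list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
              TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
              TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
              HIS = c("CG", "ND1", "CD2", "CE1", "NE2")))

# Resolve, per residue, the atom indices playing `role` for `class`.
# Returns a list(res_id -> integer atom indices), empty entries dropped.
resolve_role_atoms <- function(topology, residues, role_names) {
  out <- list()
  for (r in residues) {
    rmask <- topology$residue_ids == r
    rname <- topology$residue_names[rmask][1]
    wanted <- role_names[[rname]]
    idx <- if (!is.null(wanted))
      which(rmask & topology$atom_names %in% wanted) else integer(0)
    if (length(idx) == 0)
      idx <- which(rmask & topology$atom_names == "CB")  # pseudo-atom fallback
    if (length(idx) > 0) out[[as.character(r)]] <- idx
  }
  out
}

#' Interaction persistence matrix over an ensemble
#'
#' A residue pair is in contact in a frame when the class-specific distance
#' criterion is met; its persistence is the exact fraction of frames with the
#' contact. Classes and defaults:
#' \describe{
#'   \item{salt_bridge}{minimum distance between side-chain charged N of
#'     Lys/Arg and carboxylate O of Asp/Glu, cutoff 0.5 nm. His excluded by
#'     default (`include_his`).}
#'   \item{aromatic}{ring-centroid distance between Phe/Tyr/Trp/His rings,
#'     cutoff 0.6 nm.}
#'   \item{amino_aromatic}{ring centroid to charged N distance, cutoff 0.6 nm.}
#'   \item{hydrophobic}{minimum side-chain distance between
#'     Ala/Val/Leu/Ile/Met/Pro/Phe residues with sequence separation >= 2,
#'     cutoff 0.5 nm.}
#' }
#' Minimal topologies that carry a single side-chain reference atom per
#' residue (the synthetic generator's) are supported: the reference atom
#' stands in for the class group of its residue type.
#'
#' @param ensemble a [conformational_ensemble()].
#' @param interaction_class one of `"salt_bridge"`, `"aromatic"`,
#'   `"amino_aromatic"`, `"hydrophobic"`.
#' @param distance_cutoff nm; default depends on the class (0.5, or 0.6 for
#'   the aromatic classes).
#' @param include_his include His among the basic residues (default FALSE).
#' @param frames frame indices to scan (default all; persistence is relative
#'   to the scanned frames).
#' @return an object of class `persistence_matrix`: symmetric `R x R` matrix
#'   of exact frame fractions (dimnames = residue ids), plus class, cutoff
#'   and frame count.
#' @export
contact_persistence <- function(ensemble,
                                interaction_class = c("salt_bridge", "aromatic",
                                                      "amino_aromatic",
                                                      "hydrophobic"),
                                distance_cutoff = NULL,
                                include_his = FALSE,
                                frames = NULL) {
  interaction_class <- match.arg(interaction_class)
  if (is.null(distance_cutoff))
    distance_cutoff <- switch(interaction_class,
                              salt_bridge = 0.5, aromatic = 0.6,
                              amino_aromatic = 0.6, hydrophobic = 0.5)
  top <- ensemble$topology
  rids <- unique(top$residue_ids)
  rnames <- top$residue_names[match(rids, top$residue_ids)]
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  Fn <- length(frames)
  basic <- if (include_his) c(.basic_res, "HIS") else .basic_res

  # groups: list of two sets of residues + their atoms + pairing rule
  if (interaction_class == "salt_bridge") {
    gA <- resolve_role_atoms(top, rids[rnames %in% basic],
                             .role_atoms$basic_n)
    gB <- resolve_role_atoms(top, rids[rnames %in% .acidic_res],
                             .role_atoms$acidic_o)
    centroidA <- centroidB <- FALSE; min_sep <- 1
  } else if (interaction_class == "aromatic") {
    gA <- resolve_role_atoms(top, rids[rnames %in% .aromatic_res],
                             .role_atoms$ring)
    gB <- gA
    centroidA <- centroidB <- TRUE; min_sep <- 1
  } else if (interaction_class == "amino_aromatic") {
    gA <- resolve_role_atoms(top, rids[rnames %in% basic],
                             .role_atoms$basic_n)
    gB <- resolve_role_atoms(top, rids[rnames %in% .aromatic_res],
                             .role_atoms$ring)
    centroidA <- FALSE; centroidB <- TRUE; min_sep <- 1
  } else {
    hyd <- rids[rnames %in% .hydrophobic_res]
    side <- function(topology, residues) {
      out <- list()
      for (r in residues) {
        rmask <- topology$residue_ids == r
        idx <- which(rmask & topology$elements == "C" &
                     !(topology$atom_names %in% c("C", "CA")))
        if (length(idx) > 0) out[[as.character(r)]] <- idx
      }
      out
    }
    gA <- side(top, hyd)
    gB <- gA
    centroidA <- centroidB <- FALSE; min_sep <- 2
  }
  if (length(gA) == 0 || length(gB) == 0)
    stop("no residues carry atoms for interaction class ", interaction_class)

  R <- length(rids)
  counts <- matrix(0L, R, R, dimnames = list(rids, rids))
  resA <- as.integer(names(gA))
  resB <- as.integer(names(gB))
  for (f in frames) {
    X <- ensemble$frames[, , f]
    posA <- lapply(gA, function(idx)
      if (centroidA) matrix(colMeans(X[idx, , drop = FALSE]), 1)
      else X[idx, , drop = FALSE])
    posB <- lapply(gB, function(idx)
      if (centroidB) matrix(colMeans(X[idx, , drop = FALSE]), 1)
      else X[idx, , drop = FALSE])
    hit <- matrix(FALSE, R, R)
    for (a in seq_along(resA)) {
      for (b in seq_along(resB)) {
        ra <- resA[a]; rb <- resB[b]
        if (ra == rb || abs(ra - rb) < min_sep) next
        ia <- match(ra, rids); ib <- match(rb, rids)
        if (hit[ia, ib]) next
        PA <- posA[[a]]; PB <- posB[[b]]
        d2min <- min(outer(rowSums(PA^2), rep(1, nrow(PB))) +
                     outer(rep(1, nrow(PA)), rowSums(PB^2)) -
                     2 * tcrossprod(PA, PB))
        if (d2min <= distance_cutoff^2 + 1e-12)
          hit[ia, ib] <- hit[ib, ia] <- TRUE
      }
    }
    counts <- counts + hit
  }
  storage.mode(counts) <- "integer"
  diag(counts) <- 0L
  structure(list(matrix = counts / Fn,
                 interaction_class = interaction_class,
                 distance_cutoff = distance_cutoff,
                 n_frames = Fn, residue_ids = rids),
            class = "persistence_matrix")
}

#' @export
print.persistence_matrix <- function(x, ...) {
  nz <- sum(x$matrix[upper.tri(x$matrix)] > 0)
  cat(sprintf("Persistence matrix (%s, cutoff %.2f nm, %d frames): %d interacting pairs\n",
              x$interaction_class, x$distance_cutoff, x$n_frames, nz))
  invisible(x)
}

#' Build the persistence-weighted interaction graph
#'
#' Residues are nodes; every pair whose interaction persistence reaches the
#' threshold becomes an undirected edge weighted by the persistence.
#'
#' @param pm a [contact_persistence()] matrix.
#' @param persistence_threshold minimum persistence for an edge (default 0.20).
#' @return an `igraph` undirected weighted graph whose vertex names are
#'   residue ids; attribute `persistence_threshold` records the cut.
#' @export
build_interaction_graph <- function(pm, persistence_threshold = 0.20) {
  stopifnot(inherits(pm, "persistence_matrix"))
  M <- pm$matrix
  keep <- which(upper.tri(M) & M >= persistence_threshold, arr.ind = TRUE)
  edges <- data.frame(from = as.character(pm$residue_ids[keep[, 1]]),
                      to = as.character(pm$residue_ids[keep[, 2]]),
                      weight = M[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(
                                       name = as.character(pm$residue_ids)))
  g <- igraph::set_graph_attr(g, "persistence_threshold",
                              persistence_threshold)
  igraph::set_graph_attr(g, "interaction_class", pm$interaction_class)
}

#' Hub residues of an interaction graph
#'
#' Residues meeting the degree threshold (default: involved in at least three
#' interactions; use `min_degree = 4` for the stricter "more than 3 edges"
#' convention).
#'
#' @param graph an igraph graph from [build_interaction_graph()].
#' @param min_degree minimum degree for a hub.
#' @return integer vector of hub residue ids, ascending.
#' @export
find_hubs <- function(graph, min_degree = 3) {
  deg <- igraph::degree(graph)
  sort(as.integer(names(deg)[deg >= min_degree]))
}

#' Connected components of an interaction graph
#'
#' Maximal sets of residues mutually reachable through interaction edges;
#' isolated residues (no interactions) are not reported. Components are
#' ordered by decreasing size.
#'
#' @param graph an igraph graph from [build_interaction_graph()].
#' @return list of integer vectors of residue ids, sizes descending.
#' @export
connected_components <- function(graph) {
  comp <- igraph::components(graph)
  sets <- split(as.integer(names(comp$membership)), comp$membership)
  sets <- lapply(sets, sort)
  sets <- sets[vapply(sets, length, 1L) >= 2]
  sets <- unname(sets[order(-vapply(sets, length, 1L),
                            vapply(sets, min, 1L))])
  sets
}

#' Enumerate all simple paths between two residues
#'
#' Depth-first enumeration of every cycle-free path (each node used at most
#' once per path) between `source` and `target`, returned in lexicographic
#' order of their node sequences. If more than `max_paths` exist the result is
#' truncated and flagged via the `truncated` attribute.
#'
#' @param graph an igraph graph from [build_interaction_graph()].
#' @param source,target residue ids (must differ and be present).
#' @param max_paths enumeration cap.
#' @return list of integer vectors (node sequences source -> target), with
#'   attribute `truncated`.
#' @export
enumerate_paths <- function(graph, source, target, max_paths = 10000L) {
  vs <- igraph::V(graph)$name
  if (!as.character(source) %in% vs) stop("source residue not in graph")
  if (!as.character(target) %in% vs) stop("target residue not in graph")
  if (identical(as.integer(source), as.integer(target)))
    stop("source and target must differ")
  ps <- igraph::all_simple_paths(graph, from = as.character(source),
                                 to = as.character(target))
  paths <- lapply(ps, function(p) as.integer(names(p)))
  if (length(paths) > 1) {
    key <- vapply(paths, function(p)
      paste(formatC(p, width = 8, flag = "0"), collapse = "/"), "")
    paths <- paths[order(key)]
  }
  truncated <- length(paths) > max_paths
  if (truncated) paths <- paths[seq_len(max_paths)]
  attr(paths, "truncated") <- truncated
  paths
}
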