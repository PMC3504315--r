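# Shared fixtures: ideal-torsion chains, random ensembles, rigid transforms.

# single-frame ensemble built from uniform torsions
torsion_ensemble <- function(phi, psi, n = 30, res = "ALA") {
  ch <- idpens:::build_chain(rep(phi, n), rep(psi, n), rep(res, n))
  conformational_ensemble(ch, array(ch$xyz, dim = c(nrow(ch$xyz), 3, 1)))
}

# ensemble of F frames of A free atoms with Gaussian coordinates
random_ensemble <- function(A = 10, F = 5, sd = 0.5, seed = 1) {
  set.seed(seed)
  top <- list(atom_names = rep("CA", A),
              residue_names = rep("ALA", A),
              residue_ids = seq_len(A),
              elements = rep("C", A))
  conformational_ensemble(top, array(rnorm(A * 3 * F, sd = sd),
                                     dim = c(A, 3, F)))
}

rotation_matrix <- function(theta, axis = c(0, 0, 1)) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

rigid_transform <- function(X, theta = 0.5, axis = c(0, 0, 1),
                            shift = c(1, -2, 0.5)) {
  sweep(X %*% rotation_matrix(theta, axis), 2, shift, `+`)
}

# independent brute-force greedy neighbour-count clustering (oracle)
gromos_oracle <- function(M, cutoff) {
  Fn <- nrow(M)
  adj <- M <= cutoff
  diag(adj) <- TRUE
  remaining <- rep(TRUE, Fn)
  out <- list()
  while (any(remaining)) {
    cnt <- vapply(seq_len(Fn), function(i)
      if (remaining[i]) sum(adj[i, remaining]) else -1L, 1L)
    ctr <- which(cnt == max(cnt))[1]
    mem <- which(remaining & adj[ctr, ])
    out[[length(out) + 1L]] <- mem
    remaining[mem] <- FALSE
  }
  out
}

# wrap an adjacency matrix (residue ids = 1..n) as a persistence matrix
fake_persistence <- function(M, ids = seq_len(nrow(M))) {
  dimnames(M) <- list(ids, ids)
  structure(list(matrix = M, interaction_class = "salt_bridge",
                 distance_cutoff = 0.5, n_frames = 100L,
                 residue_ids = as.integer(ids)),
            class = "persistence_matrix")
}

# exhaustive simple-path enumeration by checking every ordered node sequence
paths_oracle <- function(adj, from, to) {
  n <- nrow(adj)
  inner <- setdiff(seq_len(n), c(from, to))
  res <- list()
  subsets <- function(v) {
    if (length(v) == 0) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (s in subsets(inner)) {
    for (p in perms(s)) {
      seqn <- c(from, p, to)
      if (all(adj[cbind(seqn[-length(seqn)], seqn[-1])]))
        res[[length(res) + 1L]] <- seqn
    }
  }
  if (length(res) > 1) {
    key <- vapply(res, function(p)
      paste(formatC(p, width = 8, flag = "0"), collapse = "/"), "")
    res <- res[order(key)]
  }
  res
}

# connected components by boolean transitive closure (oracle)
components_oracle <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(n) > 0
  for (k in seq_len(n))
    reach <- reach | (reach %*% (reach * 1) > 0)
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- which(reach[i, ])
    seen[comp] <- TRUE
    if (length(comp) >= 2 && any(adj[comp, comp]))
      comps[[length(comps) + 1L]] <- comp
  }
  comps <- comps[vapply(comps, length, 1L) >= 2]
  comps[order(-vapply(comps, length, 1L), vapply(comps, min, 1L))]
}
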