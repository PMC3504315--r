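# Synthetic conformational-ensemble generator with known ground truth.
#
# Chains are built residue by residue from ideal internal coordinates (full
# backbone N, H, CA, C, O plus one side-chain reference pseudo-atom named CB
# per non-glycine residue), so that hydrogen-bond-based secondary-structure
# assignment and side-chain contact typing both operate on the generated
# frames. Compaction toward a state-specific target radius of gyration is
# achieved by greedy pivot moves on coil torsions, which preserve all internal
# geometry exactly (helical segments move as rigid bodies).

# ideal backbone geometry, nm / degrees
.geom <- list(b_NCA = 0.1458, b_CAC = 0.1525, b_CN = 0.1329, b_CO = 0.1231,
              b_NH = 0.100, a_CNCA = 121.7, a_NCAC = 111.2, a_CACN = 116.2,
              a_CACO = 120.8)

# distance from CA to the side-chain interaction centre (charge centre, ring
# centroid or aliphatic centroid), nm
.sc_dist <- c(ALA = 0.152, SER = 0.19, THR = 0.19, CYS = 0.21, VAL = 0.20,
              LEU = 0.26, ILE = 0.23, MET = 0.30, PRO = 0.19, PHE = 0.34,
              TYR = 0.39, TRP = 0.38, HIS = 0.31, LYS = 0.44, ARG = 0.42,
              ASP = 0.25, GLU = 0.31, ASN = 0.25, GLN = 0.31)

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

# A deterministic IDP-like default sequence: charge-rich, low hydrophobicity,
# with aromatics sprinkled in -- enough residue-type variety for every
# interaction class.
default_idp_sequence <- function(n_residues) {
  motif <- "GSKDESTRAEKLNDQERVKSFDGTKEYRDNSPEKARDQLESGKTNDVREKSYDAERKGINDF"
  s <- strsplit(motif, "")[[1]]
  paste(rep_len(s, n_residues), collapse = "")
}

#' Specification of a synthetic conformational ensemble
#'
#' Defines an ~`n_residues` chain with helical segments of given per-frame
#' occupancy, a mixture of conformational states of different compactness, and
#' a coordinate noise level. The generator is a pure function of the spec:
#' identical seeds give identical frames.
#'
#' @param n_residues chain length.
#' @param helical_segments data frame (or list of triples) with columns
#'   `start`, `end`, `occupancy`: residue ranges built with ideal alpha-helix
#'   torsions (phi = -57, psi = -47) in the fraction `occupancy` of frames.
#' @param states data frame with columns `label`, `weight`, `compactness`;
#'   weights sum to 1 and `compactness` multiplies the globular baseline
#'   radius of gyration 0.22 * N^0.38 nm to give the per-state target Rg.
#' @param n_frames number of frames to generate.
#' @param coordinate_noise_sigma isotropic Gaussian coordinate noise, nm.
#' @param seed integer RNG seed.
#' @param sequence optional 1-letter amino-acid string of length `n_residues`;
#'   default is a deterministic charge-rich disordered-protein-like sequence.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_residues = 70,
                          helical_segments = data.frame(start = c(12, 30),
                                                        end = c(24, 34),
                                                        occupancy = c(0.7, 0.4)),
                          states = data.frame(label = c("compact", "extended"),
                                              weight = c(0.5, 0.5),
                                              compactness = c(1.0, 2.5)),
                          n_frames = 100,
                          coordinate_noise_sigma = 0.002,
                          seed = 1,
                          sequence = NULL) {
  if (is.list(helical_segments) && !is.data.frame(helical_segments))
    helical_segments <- do.call(rbind, lapply(helical_segments, function(x)
      data.frame(start = x[1], end = x[2], occupancy = x[3])))
  states <- as.data.frame(states)
  if (any(states$weight < 0) || abs(sum(states$weight) - 1) > 1e-9)
    stop("state weights must be non-negative and sum to 1")
  if (nrow(helical_segments) > 0) {
    if (any(helical_segments$occupancy < 0 | helical_segments$occupancy > 1))
      stop("occupancy probabilities must lie in [0, 1]")
    if (any(helical_segments$start < 1 | helical_segments$end > n_residues) ||
        any(helical_segments$start > helical_segments$end))
      stop("helical segments out of range")
    o <- order(helical_segments$start)
    hs <- helical_segments[o, ]
    if (nrow(hs) > 1 && any(hs$start[-1] <= hs$end[-nrow(hs)]))
      stop("helical segments overlap")
  }
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (is.null(sequence)) sequence <- default_idp_sequence(n_residues)
  if (nchar(sequence) != n_residues)
    stop("sequence length must equal n_residues")
  structure(list(n_residues = as.integer(n_residues),
                 helical_segments = helical_segments,
                 states = states, n_frames = as.integer(n_frames),
                 coordinate_noise_sigma = coordinate_noise_sigma,
                 seed = as.integer(seed), sequence = sequence),
            class = "ensemble_spec")
}

# Build one chain from per-residue torsions. Returns list(xyz, topology rows).
build_chain <- function(phi, psi, res3) {
  g <- .geom
  R <- length(phi)
  names_ <- list(); resn <- list(); resi <- list(); elem <- list()
  xyz <- list()
  prevN <- prevCA <- prevC <- prevO <- NULL
  for (i in seq_len(R)) {
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(g$b_NCA, 0, 0)
      vref <- N + c(0, 1, 0)
      C <- place_atom(vref, N, CA, g$b_CAC, g$a_NCAC, 0)
    } else {
      N <- place_atom(prevN, prevCA, prevC, g$b_CN, g$a_CACN, psi[i - 1])
      CA <- place_atom(prevCA, prevC, N, g$b_NCA, g$a_CNCA, 180)
      C <- place_atom(prevC, N, CA, g$b_CAC, g$a_NCAC, phi[i])
    }
    O <- place_atom(N, CA, C, g$b_CO, g$a_CACO, psi[i] + 180)
    atoms <- list(N = N)
    if (i > 1 && res3[i] != "PRO")
      atoms$H <- N + g$b_NH * unit(prevC - prevO)
    atoms$CA <- CA
    if (res3[i] != "GLY") {
      d <- .sc_dist[[res3[i]]]
      if (is.null(d) || is.na(d)) d <- 0.25
      atoms$CB <- place_atom(C, N, CA, d, 110.5, -122.6)
    }
    atoms$C <- C
    atoms$O <- O
    nm <- names(atoms)
    names_[[i]] <- nm
    resn[[i]] <- rep(res3[i], length(nm))
    resi[[i]] <- rep(i, length(nm))
    elem[[i]] <- substr(nm, 1, 1)
    xyz[[i]] <- do.call(rbind, atoms)
    prevN <- N; prevCA <- CA; prevC <- C; prevO <- O
  }
  list(xyz = do.call(rbind, xyz),
       atom_names = unlist(names_), residue_names = unlist(resn),
       residue_ids = unlist(resi), elements = unlist(elem))
}

# Greedy pivot-move compaction/extension of one chain toward a target Calpha
# radius of gyration. Torsions of residues in `frozen` (helical segments) are
# never pivoted, so their internal geometry is untouched.
pivot_to_rg <- function(xyz, top, target_rg, frozen, tol = 0.05,
                        max_moves = 300) {
  ca_idx <- which(top$atom_names == "CA")
  rg <- radius_of_gyration(xyz[ca_idx, , drop = FALSE])
  if (abs(rg - target_rg) / target_rg <= tol) return(xyz)
  R <- max(top$residue_ids)
  movable <- setdiff(seq.int(2L, R - 1L), frozen)
  if (length(movable) == 0) return(xyz)
  res_of <- top$residue_ids
  A <- nrow(xyz)
  for (m in seq_len(max_moves)) {
    res <- sample(movable, 1)
    tors <- sample(c("phi", "psi"), 1)
    ridx <- which(res_of == res)
    anames <- top$atom_names[ridx]
    if (tors == "phi") {
      axis_from <- xyz[ridx[anames == "N"], ]
      axis_to <- xyz[ridx[anames == "CA"], ]
      first_moved <- ridx[anames == "CA"] + 1L  # CB, C, O + downstream
    } else {
      axis_from <- xyz[ridx[anames == "CA"], ]
      axis_to <- xyz[ridx[anames == "C"], ]
      first_moved <- ridx[anames == "C"] + 1L   # O + downstream
    }
    if (first_moved > A) next
    moved <- seq.int(first_moved, A)
    theta <- stats::runif(1, -120, 120)
    ca_moved <- intersect(moved, ca_idx)
    trial_ca <- xyz[ca_idx, , drop = FALSE]
    sub <- match(ca_moved, ca_idx)
    trial_ca <- rotate_about_axis(rbind(trial_ca), sub, axis_from,
                                  axis_to - axis_from, theta)
    new_rg <- radius_of_gyration(trial_ca)
    if (abs(new_rg - target_rg) < abs(rg - target_rg)) {
      xyz <- rotate_about_axis(xyz, moved, axis_from, axis_to - axis_from,
                               theta)
      rg <- new_rg
      if (abs(rg - target_rg) / target_rg <= tol) break
    }
  }
  xyz
}

#' Generate a synthetic conformational ensemble with ground truth
#'
#' Builds `n_frames` chains from ideal internal coordinates. Residues inside an
#' occupied helical segment receive ideal alpha-helix torsions
#' (phi = -57, psi = -47) with 2 degrees of jitter; all other residues draw
#' coil torsions from a broad beta/polyproline-II/alpha mixture. Each frame is
#' assigned to a state by the spec weights and driven toward that state's
#' target radius of gyration by pivot moves; isotropic Gaussian coordinate
#' noise is added last.
#'
#' @param spec an [ensemble_spec()].
#' @return a list of class `synthetic_ensemble` with elements `ensemble` (a
#'   [conformational_ensemble()]), `state` (per-frame state labels),
#'   `helix_occupancy` (`F x R` logical ground truth), `rg` (realized per-frame
#'   Calpha radius of gyration, nm) and `spec`.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_seed(spec$seed, {
    R <- spec$n_residues
    F_ <- spec$n_frames
    res3 <- unname(.aa3[strsplit(spec$sequence, "")[[1]]])
    if (anyNA(res3)) stop("sequence contains unknown amino-acid codes")
    segs <- spec$helical_segments
    states <- spec$states
    rg0 <- 0.22 * R^0.38
    state_of <- sample(states$label, F_, replace = TRUE, prob = states$weight)
    occupancy <- matrix(FALSE, F_, R)
    frames <- NULL
    topology <- NULL
    rg_out <- numeric(F_)
    for (f in seq_len(F_)) {
      phi <- numeric(R); psi <- numeric(R)
      # coil torsions: beta / ppII / alphaR / alphaL mixture
      comp <- sample(4, R, replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
      mu_phi <- c(-120, -75, -65, 60)[comp]
      mu_psi <- c(130, 145, -40, 45)[comp]
      sd_phi <- c(25, 15, 15, 15)[comp]
      phi <- stats::rnorm(R, mu_phi, sd_phi)
      psi <- stats::rnorm(R, mu_psi, sd_phi)
      frozen <- integer(0)
      if (nrow(segs) > 0) {
        for (s in seq_len(nrow(segs))) {
          if (stats::runif(1) < segs$occupancy[s]) {
            rng <- seq.int(segs$start[s], segs$end[s])
            phi[rng] <- -57 + stats::rnorm(length(rng), 0, 2)
            psi[rng] <- -47 + stats::rnorm(length(rng), 0, 2)
            occupancy[f, rng] <- TRUE
            frozen <- c(frozen, rng)
          }
        }
      }
      chain <- build_chain(phi, psi, res3)
      if (is.null(topology)) {
        topology <- chain[c("atom_names", "residue_names", "residue_ids",
                            "elements")]
        frames <- array(NA_real_, dim = c(nrow(chain$xyz), 3, F_))
      }
      st <- match(state_of[f], states$label)
      target <- states$compactness[st] * rg0
      xyz <- pivot_to_rg(chain$xyz, topology, target, frozen)
      if (spec$coordinate_noise_sigma > 0)
        xyz <- xyz + stats::rnorm(length(xyz), 0, spec$coordinate_noise_sigma)
      frames[, , f] <- xyz
      rg_out[f] <- radius_of_gyration(
        xyz[topology$atom_names == "CA", , drop = FALSE])
    }
    ens <- conformational_ensemble(topology, frames,
                                   frame_labels = state_of)
    structure(list(ensemble = ens, state = state_of,
                   helix_occupancy = occupancy, rg = rg_out, spec = spec),
              class = "synthetic_ensemble")
  })
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat("Synthetic ensemble:", n_frames(x$ensemble), "frames,",
      x$spec$n_residues, "residues; states:",
      paste(sprintf("%s (%d)", x$spec$states$label,
                    tabulate(match(x$state, x$spec$states$label),
                             nbins = nrow(x$spec$states))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Contact schedule with known ground-truth persistence
#'
#' Each scheduled residue pair carries a target persistence and either a
#' deterministic frame mask (contact present in exactly `round(p * F)` frames,
#' so the realized persistence equals the target as an exact rational) or a
#' Bernoulli per-frame probability.
#'
#' @param pairs data frame with columns `i`, `j` (residue ids) and
#'   `persistence` in `[0, 1]`.
#' @param mode `"deterministic"` (mask = first `round(p * F)` frames),
#'   `"probabilistic"`, or `"mask"` (explicit per-pair frame masks).
#' @param seed RNG seed used for probabilistic masks.
#' @param masks for `mode = "mask"`: a list, one logical vector (length F) or
#'   integer frame-index vector per pair.
#' @return an object of class `contact_schedule`.
#' @export
contact_schedule <- function(pairs,
                             mode = c("deterministic", "probabilistic", "mask"),
                             seed = 1, masks = NULL) {
  mode <- match.arg(mode)
  pairs <- as.data.frame(pairs)
  if (any(pairs$i == pairs$j)) stop("contact pairs must have i != j")
  if (mode == "mask") {
    if (is.null(masks) || length(masks) != nrow(pairs))
      stop("mode = 'mask' needs one mask per pair")
    if (is.null(pairs$persistence)) pairs$persistence <- NA_real_
  } else if (any(pairs$persistence < 0 | pairs$persistence > 1)) {
    stop("persistence must lie in [0, 1]")
  }
  structure(list(pairs = pairs, mode = mode, seed = as.integer(seed),
                 masks = masks),
            class = "contact_schedule")
}

#' Plant side-chain contacts with known persistence into an ensemble
#'
#' For every scheduled pair and scheduled frame the side-chain reference atom
#' of residue `j` is moved to 0.30 nm from that of residue `i`; in unscheduled
#' frames the pair is kept more than 0.7 nm apart. Pairs of scheduled residues
#' that are not in contact in a given frame are also pushed apart, so the
#' persistence measured among scheduled residues reproduces the schedule
#' exactly.
#'
#' @param ensemble a [conformational_ensemble()] whose residues carry a
#'   side-chain reference atom (`CB`).
#' @param schedule a [contact_schedule()].
#' @param contact_dist planted contact distance, nm.
#' @param background_dist minimum separation enforced for non-contact frames, nm.
#' @return a list with `ensemble` (modified) and `mask` (`F x n_pairs` logical
#'   ground truth).
#' @export
plant_contacts <- function(ensemble, schedule, contact_dist = 0.30,
                           background_dist = 0.85) {
  stopifnot(inherits(schedule, "contact_schedule"))
  top <- ensemble$topology
  F_ <- n_frames(ensemble)
  pairs <- schedule$pairs
  if (nrow(pairs) == 0) return(list(ensemble = ensemble,
                                    mask = matrix(FALSE, F_, 0)))
  sc_of <- function(res) {
    k <- which(top$residue_ids == res & top$atom_names == "CB")
    if (length(k) != 1)
      stop("residue ", res, " has no side-chain reference atom")
    k
  }
  ai <- vapply(pairs$i, sc_of, 1L)
  aj <- vapply(pairs$j, sc_of, 1L)
  mask <- matrix(FALSE, F_, nrow(pairs))
  if (schedule$mode == "deterministic") {
    for (p in seq_len(nrow(pairs)))
      mask[seq_len(round(pairs$persistence[p] * F_)), p] <- TRUE
  } else if (schedule$mode == "mask") {
    for (p in seq_len(nrow(pairs))) {
      m <- schedule$masks[[p]]
      if (is.logical(m)) {
        if (length(m) != F_) stop("logical mask must have length F")
        mask[, p] <- m
      } else {
        mask[as.integer(m), p] <- TRUE
      }
    }
  } else {
    mask[] <- with_seed(schedule$seed,
                        stats::runif(F_ * nrow(pairs)) <
                          rep(pairs$persistence, each = F_))
  }
  # Background separation is enforced only for unscheduled residue pairs that
  # could register as a contact of the same interaction class: opposite-charge
  # pairs, or any pair when residue types are uncharged. Same-charge residues
  # may stay close -- necessary so that one residue can hold several planted
  # partners (hub geometry).
  sched_atoms <- unique(c(ai, aj))
  rname_of_atom <- top$residue_names[sched_atoms]
  chg <- ifelse(rname_of_atom %in% c("LYS", "ARG"), 1L,
                ifelse(rname_of_atom %in% c("ASP", "GLU"), -1L, 0L))
  could_register <- function(a, b) chg[a] == 0L || chg[b] == 0L ||
    chg[a] != chg[b]
  frames <- ensemble$frames
  for (f in seq_len(F_)) {
    X <- frames[, , f]
    active <- unique(c(ai[mask[f, ]], aj[mask[f, ]]))
    for (sweep_it in seq_len(20)) {
      changed <- FALSE
      for (p in seq_len(nrow(pairs))) {
        v <- X[aj[p], ] - X[ai[p], ]
        d <- vnorm(v)
        u <- if (d < 1e-9) c(1, 0, 0) else v / d
        if (mask[f, p]) {
          if (abs(d - contact_dist) > 1e-9) {
            X[aj[p], ] <- X[ai[p], ] + contact_dist * u
            changed <- TRUE
          }
        } else if (d < background_dist) {
          X[aj[p], ] <- X[ai[p], ] + background_dist * u
          changed <- TRUE
        }
      }
      # keep non-scheduled combinations of scheduled residues apart
      for (a in seq_along(sched_atoms)) {
        for (b in seq_along(sched_atoms)) {
          if (b <= a) next
          ka <- sched_atoms[a]; kb <- sched_atoms[b]
          is_sched <- any((ai == ka & aj == kb) | (ai == kb & aj == ka))
          if (is_sched || !could_register(a, b)) next
          v <- X[kb, ] - X[ka, ]
          d <- vnorm(v)
          if (d < background_dist) {
            # move the atom without an active planted contact when possible
            if (kb %in% active && !(ka %in% active)) {
              tmp <- ka; ka <- kb; kb <- tmp
              v <- -v
            }
            u <- if (d < 1e-9) c(0, 0, 1) else v / d
            X[kb, ] <- X[ka, ] + background_dist * u
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    frames[, , f] <- X
  }
  list(ensemble = conformational_ensemble(top, frames,
                                          frame_labels = ensemble$frame_labels,
                                          source_units = ensemble$source_units),
       mask = mask)
}
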