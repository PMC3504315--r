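# Per-frame secondary-structure assignment and solvent-accessible surface.

#' Kabsch-Sander secondary-structure assignment
#'
#' Re-implementation of the DSSP hydrogen-bond criterion: the electrostatic
#' energy between the carbonyl of an acceptor residue and the amide of a donor
#' residue, `E = 0.084 * (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332 kcal/mol`
#' (distances in Angstrom), defines a hydrogen bond when `E < -0.5 kcal/mol`.
#' n-turns at `i -> i+3, i+4, i+5` give the three helix classes; two
#' consecutive n-turns are required to open a helix, with the DSSP priority
#' alpha (H) over 3-10 (G) over pi (I). Residues in a turn but not in a helix
#' are T, everything else C (strand bookkeeping is out of scope).
#'
#' Amide hydrogens are reconstructed at 0.1 nm from N along the
#' `C(i-1) - O(i-1)` direction (the DSSP convention), so assignments do not
#' depend on whether the input carries hydrogens.
#'
#' @param ensemble a [conformational_ensemble()] whose residues carry backbone
#'   N, CA, C and O atoms.
#' @return an object of class `ss_profile`: `assignments` (`F x R` character
#'   matrix over H, G, I, T, C), per-residue `persistence` (`R x 5`, rows sum
#'   to 1), and `residue_ids`.
#' @export
assign_secondary_structure <- function(ensemble) {
  top <- ensemble$topology
  rids <- unique(top$residue_ids)
  R <- length(rids)
  F_ <- n_frames(ensemble)
  bb_idx <- function(name) {
    k <- match(paste(rids, name), paste(top$residue_ids, top$atom_names))
    if (anyNA(k))
      stop("missing backbone atom ", name, " for residue ",
           rids[which(is.na(k))[1]])
    k
  }
  iN <- bb_idx("N"); iCA <- bb_idx("CA"); iC <- bb_idx("C"); iO <- bb_idx("O")
  classes <- c("H", "G", "I", "T", "C")
  assignments <- matrix("C", F_, R)
  for (f in seq_len(F_)) {
    X <- ensemble$frames[, , f] * 10  # nm -> Angstrom
    N <- X[iN, , drop = FALSE]; C <- X[iC, , drop = FALSE]
    O <- X[iO, , drop = FALSE]
    H <- N
    H[1, ] <- NA
    if (R > 1) {
      d <- C[-R, , drop = FALSE] - O[-R, , drop = FALSE]
      d <- d / sqrt(rowSums(d^2))
      H[-1, ] <- N[-1, , drop = FALSE] + d  # 1 Angstrom
    }
    # hbond[a, d]: CO of residue a accepts from NH of residue d
    dist2 <- function(P, Q) {
      outer(rowSums(P^2), rep(1, nrow(Q))) +
        outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * tcrossprod(P, Q)
    }
    rON <- sqrt(pmax(dist2(O, N), 0))
    rCN <- sqrt(pmax(dist2(C, N), 0))
    rOH <- sqrt(pmax(dist2(O, H), 0))
    rCH <- sqrt(pmax(dist2(C, H), 0))
    E <- 0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
    E[!is.finite(E)] <- 0
    sep <- abs(outer(seq_len(R), seq_len(R), `-`))
    hbond <- E < -0.5 & sep >= 2
    turn <- function(n) {
      out <- rep(FALSE, R)
      i <- seq_len(max(0, R - n))
      out[i] <- hbond[cbind(i, i + n)]
      out
    }
    t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
    ss <- rep("C", R)
    mark_helix <- function(ss, tn, n, code) {
      starts <- seq_len(max(0, R - n))
      for (i in starts[starts >= 2]) {
        if (tn[i - 1] && tn[i]) {
          span <- seq.int(i, i + n - 1)
          free <- ss[span] %in% c("C", "T")
          if (code == "H" || all(free)) ss[span][free] <- code
        }
      }
      ss
    }
    ss <- mark_helix(ss, t4, 4, "H")
    ss <- mark_helix(ss, t3, 3, "G")
    ss <- mark_helix(ss, t5, 5, "I")
    for (n in c(3, 4, 5)) {
      tn <- list(t3, t4, t5)[[n - 2]]
      for (i in which(tn)) {
        span <- seq.int(i + 1, min(i + n - 1, R))
        ss[span][ss[span] == "C"] <- "T"
      }
    }
    assignments[f, ] <- ss
  }
  persistence <- t(apply(assignments, 2, function(col)
    tabulate(factor(col, levels = classes), nbins = 5) / F_))
  colnames(persistence) <- classes
  structure(list(assignments = assignments, persistence = persistence,
                 residue_ids = rids, classes = classes),
            class = "ss_profile")
}

#' @export
print.ss_profile <- function(x, ...) {
  mean_h <- mean(x$assignments %in% c("H", "G", "I"))
  cat(sprintf("Secondary structure: %d frames x %d residues; mean helical content %.1f%%\n",
              nrow(x$assignments), ncol(x$assignments), 100 * mean_h))
  invisible(x)
}

#' Helical-content summary over a frame subset
#'
#' Per-frame counts of residues in each helix class (alpha = H, 3-10 = G,
#' pi = I), averaged and maximized over the chosen frames, plus the total
#' helical content as a percentage of the chain length.
#'
#' @param profile an [assign_secondary_structure()] profile.
#' @param frames frame indices (default all).
#' @return a list with `mean_alpha`, `mean_310`, `mean_pi`, `max_alpha`,
#'   `max_310`, `max_pi`, `total_helical_pct` and `n_residues`.
#' @export
helical_content_summary <- function(profile, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nrow(profile$assignments))
  if (length(frames) == 0) stop("frame subset is empty")
  A <- profile$assignments[frames, , drop = FALSE]
  R <- ncol(A)
  cnt <- function(code) rowSums(A == code)
  a <- cnt("H"); g <- cnt("G"); p <- cnt("I")
  list(mean_alpha = mean(a), mean_310 = mean(g), mean_pi = mean(p),
       max_alpha = max(a), max_310 = max(g), max_pi = max(p),
       total_helical_pct = 100 * mean(a + g + p) / R,
       n_residues = R)
}

# Deterministic molecule-fixed orientation: principal axes with signs fixed
# by the third moment of the projections (falling back to the largest
# projection). Quadrature performed in this frame is invariant under rigid
# motion of the input to numerical precision.
canonical_frame <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  n <- nrow(Xc)
  if (n == 1) return(Xc)
  if (n == 2) {
    # coverage on two collinear spheres is axially symmetric: aligning the
    # bond with x suffices
    e1 <- unit(Xc[2, ] - Xc[1, ])
    a <- diag(3)[, which.min(abs(e1))]
    e2 <- unit(pracma_cross(e1, a))
    e3 <- pracma_cross(e1, e2)
    return(Xc %*% cbind(e1, e2, e3))
  }
  V <- eigen(crossprod(Xc), symmetric = TRUE)$vectors
  scale3 <- (sqrt(sum(Xc^2) / n))^3
  for (k in 1:2) {
    p <- Xc %*% V[, k]
    s <- sum(p^3)
    if (abs(s) < 1e-9 * max(scale3, 1e-30)) s <- p[which.max(abs(p))]
    if (s < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- pracma_cross(V[, 1], V[, 2])
  Xc %*% V
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- (2 * i + 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# van der Waals radii, nm; side-chain pseudo-atoms are carbon-like
.vdw_radii <- c(C = 0.17, N = 0.155, O = 0.152, S = 0.18, H = 0.12, P = 0.18)

#' Shrake-Rupley solvent-accessible surface
#'
#' Sphere-point quadrature: each atom is inflated by the probe radius and
#' covered with a deterministic quasi-uniform point set; the accessible
#' fraction is the share of points lying outside every neighbouring inflated
#' sphere. The quadrature is evaluated in a canonical molecule-fixed frame
#' (principal axes, moment-fixed signs), so results are deterministic for a
#' fixed point count and invariant under rigid motion of the input.
#'
#' @param ensemble a [conformational_ensemble()].
#' @param probe_radius solvent probe radius, nm (water: 0.14).
#' @param n_points quadrature points per atom.
#' @param radii optional named vector of van der Waals radii by element, nm;
#'   defaults to C 0.17, N 0.155, O 0.152, S 0.18, H 0.12, P 0.18.
#' @param frames frame indices to evaluate (default all).
#' @return an object of class `sas_profile`: `total` per evaluated frame
#'   (nm^2), `per_residue` (`F x R`), `frames`, `probe_radius`, `n_points`.
#' @export
shrake_rupley_sas <- function(ensemble, probe_radius = 0.14, n_points = 960,
                              radii = NULL, frames = NULL) {
  top <- ensemble$topology
  if (is.null(radii)) radii <- .vdw_radii
  r_atom <- radii[top$elements]
  if (anyNA(r_atom))
    stop("no van der Waals radius configured for element(s): ",
         paste(unique(top$elements[is.na(r_atom)]), collapse = ", "))
  r_atom <- unname(r_atom) + probe_radius
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  A <- n_atoms(ensemble)
  rids <- unique(top$residue_ids)
  res_index <- match(top$residue_ids, rids)
  S <- sphere_points(n_points)
  total <- numeric(length(frames))
  per_res <- matrix(0, length(frames), length(rids))
  max_reach <- 2 * max(r_atom)
  for (fi in seq_along(frames)) {
    X <- canonical_frame(matrix(ensemble$frames[, , frames[fi]], ncol = 3))
    D2 <- as.matrix(stats::dist(X))^2
    area <- numeric(A)
    for (i in seq_len(A)) {
      Ri <- r_atom[i]
      nb <- which(D2[i, ] < (Ri + r_atom)^2 & seq_len(A) != i)
      if (length(nb) == 0) {
        frac <- 1
      } else {
        P <- S * Ri
        P <- sweep(P, 2, X[i, ], `+`)
        Y <- X[nb, , drop = FALSE]
        d2 <- outer(rowSums(P^2), rep(1, length(nb))) +
          outer(rep(1, n_points), rowSums(Y^2)) - 2 * tcrossprod(P, Y)
        covered <- d2 < matrix(r_atom[nb]^2, n_points, length(nb), byrow = TRUE)
        frac <- mean(rowSums(covered) == 0)
      }
      area[i] <- 4 * pi * Ri^2 * frac
    }
    total[fi] <- sum(area)
    per_res[fi, ] <- as.vector(tapply(area, res_index, sum))
  }
  structure(list(total = total, per_residue = per_res, frames = frames,
                 residue_ids = rids, probe_radius = probe_radius,
                 n_points = n_points),
            class = "sas_profile")
}

#' @export
print.sas_profile <- function(x, ...) {
  cat(sprintf("Solvent-accessible surface: %d frames, mean %.2f nm^2 (probe %.2f nm, %d points)\n",
              length(x$total), mean(x$total), x$probe_radius, x$n_points))
  invisible(x)
}

#' Per-basin secondary-structure and SAS report
#'
#' One row per basin: mean and maximum helical-class content, total helical
#' percentage, and SAS mean/min/max over the basin's frames. Empty basins are
#' omitted with a warning. The SAS profile may have been evaluated on a subset
#' of frames; only frames present in it contribute to the SAS columns.
#'
#' @param basin_labels per-frame basin labels (`NA` = unassigned).
#' @param ss_profile an [assign_secondary_structure()] profile over the same
#'   frames.
#' @param sas_profile a [shrake_rupley_sas()] profile (possibly on a frame
#'   subset).
#' @return data frame, one row per basin with at least one frame.
#' @export
basin_structure_report <- function(basin_labels, ss_profile, sas_profile) {
  labs <- sort(unique(stats::na.omit(basin_labels)))
  rows <- list()
  for (lab in labs) {
    fr <- which(basin_labels == lab)
    if (length(fr) == 0) {
      warning("basin ", lab, " has no frames; omitted")
      next
    }
    hs <- helical_content_summary(ss_profile, fr)
    sas_fr <- which(sas_profile$frames %in% fr)
    sas <- if (length(sas_fr) > 0) sas_profile$total[sas_fr] else NA_real_
    rows[[lab]] <- data.frame(
      basin = lab, n_frames = length(fr),
      helix_avg_alpha = hs$mean_alpha, helix_avg_310 = hs$mean_310,
      helix_avg_pi = hs$mean_pi,
      helix_max_alpha = hs$max_alpha, helix_max_310 = hs$max_310,
      helix_max_pi = hs$max_pi,
      total_helical_pct = hs$total_helical_pct,
      sas_mean = mean(sas), sas_min = suppressWarnings(min(sas)),
      sas_max = suppressWarnings(max(sas)))
  }
  if (length(rows) == 0) stop("no basin contains any frame")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
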