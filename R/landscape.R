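#' Estimate a two-dimensional free-energy landscape
#'
#' `G(q) = -kT ln P(q)` over two reaction coordinates (typically the first two
#' principal components, or one PC and the solvent-accessible surface), with
#' `P` the joint histogram probability of the ensemble. The surface is shifted
#' so its minimum over populated bins is zero; unpopulated bins are masked
#' (`NA`) rather than set to infinite energy.
#'
#' @param x,y per-frame reaction-coordinate values (equal length).
#' @param bins number of bins per axis, length 1 or 2 (default 32 x 32).
#' @param temperature_K simulation temperature, K.
#' @param pad fractional padding of the data range on each axis.
#' @param coord_names descriptors of the two coordinates.
#' @return an object of class `fel_surface`: free-energy matrix `G` (kJ/mol,
#'   `Nx x Ny`, `NA`-masked), probabilities `P`, bin `counts`, bin edges
#'   `xbreaks`/`ybreaks`, `kT` and the frame count.
#' @export
estimate_fel <- function(x, y, bins = c(32, 32), temperature_K = 300,
                         pad = 0.02, coord_names = c("q1", "q2")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("reaction coordinates must be finite")
  bins <- rep_len(as.integer(bins), 2)
  if (any(bins < 2)) stop("at least 2 bins per axis are required")
  F_ <- length(x)
  edge <- function(v, n) {
    r <- range(v)
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1) * 1e-6
    seq(r[1] - pad * w, r[2] + pad * w, length.out = n + 1)
  }
  xb <- edge(x, bins[1])
  yb <- edge(y, bins[2])
  ix <- findInterval(x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins[1], bins[2])
  for (f in seq_len(F_)) counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1L
  P <- counts / F_
  kT <- 0.0083145 * temperature_K  # kJ/mol
  G <- matrix(NA_real_, bins[1], bins[2])
  pop <- counts > 0
  G[pop] <- -kT * log(P[pop])
  G <- G - min(G, na.rm = TRUE)
  structure(list(G = G, P = P, counts = counts, xbreaks = xb, ybreaks = yb,
                 kT = kT, temperature_K = temperature_K, n_frames = F_,
                 coord_names = coord_names),
            class = "fel_surface")
}

#' @export
print.fel_surface <- function(x, ...) {
  cat(sprintf("Free-energy surface: %d x %d bins over (%s, %s), %d frames, kT = %.4f kJ/mol\n",
              nrow(x$G), ncol(x$G), x$coord_names[1], x$coord_names[2],
              x$n_frames, x$kT))
  cat(sprintf("  populated bins: %d; G range 0 .. %.2f kJ/mol\n",
              sum(!is.na(x$G)), max(x$G, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.fel_surface <- function(x, ...) {
  xc <- (x$xbreaks[-1] + x$xbreaks[-length(x$xbreaks)]) / 2
  yc <- (x$ybreaks[-1] + x$ybreaks[-length(x$ybreaks)]) / 2
  graphics::filled.contour(xc, yc, x$G,
                           color.palette = grDevices::terrain.colors,
                           xlab = x$coord_names[1], ylab = x$coord_names[2],
                           main = "Free-energy landscape (kJ/mol)", ...)
  invisible(x)
}

# 8-neighbourhood steepest-descent target of every populated bin.
# Returns, per populated bin, the linear index of the local minimum it drains
# to (ties among equally low neighbours broken by lowest linear index).
descend_bins <- function(G) {
  nx <- nrow(G); ny <- ncol(G)
  pop <- which(!is.na(G))
  target <- rep(NA_integer_, nx * ny)
  step_to <- rep(NA_integer_, nx * ny)
  for (lin in pop) {
    i <- (lin - 1L) %% nx + 1L
    j <- (lin - 1L) %/% nx + 1L
    best <- lin
    bestG <- Inf
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
      l2 <- ii + (jj - 1L) * nx
      g2 <- G[l2]
      if (is.na(g2) || g2 >= G[lin] - 1e-12) next  # only strictly downhill
      if (g2 < bestG - 1e-12 || (g2 <= bestG + 1e-12 && l2 < best)) {
        best <- l2; bestG <- g2
      }
    }
    step_to[lin] <- best
  }
  for (lin in pop) {
    cur <- lin
    for (it in seq_len(nx * ny)) {
      nxt <- step_to[cur]
      if (nxt == cur) break
      cur <- nxt
    }
    target[lin] <- cur
  }
  target
}

#' Decompose a free-energy surface into basins
#'
#' Every populated bin is assigned to its local minimum by steepest descent
#' over 8-neighbourhoods. Minima whose depth (lowest connecting saddle minus
#' basin minimum) is below `min_depth` are merged into the basin across their
#' lowest saddle, from the shallowest up. Basins are labelled `A`, `B`, ... by
#' increasing minimum free energy; basins holding less than `min_population`
#' of the frames are flagged as minor.
#'
#' @param fes an [estimate_fel()] surface.
#' @param min_depth minimum basin depth, kJ/mol (default 1 kT).
#' @param min_population population fraction below which a basin is minor.
#' @return an object of class `basin_set`: per-basin label, bin set, minimum
#'   bin, population fraction and minor flag, plus the bin-to-basin map.
#' @export
detect_basins <- function(fes, min_depth = fes$kT, min_population = 0.02) {
  stopifnot(inherits(fes, "fel_surface"))
  G <- fes$G
  nx <- nrow(G); ny <- ncol(G)
  assign_to <- descend_bins(G)
  pop_bins <- which(!is.na(G))

  repeat {
    mins <- sort(unique(assign_to[pop_bins]))
    if (length(mins) <= 1) break
    # lowest connecting saddle between each shallow basin and its neighbours
    saddle <- rep(Inf, length(mins))
    saddle_to <- rep(NA_integer_, length(mins))
    basin_of <- function(lin) match(assign_to[lin], mins)
    for (lin in pop_bins) {
      i <- (lin - 1L) %% nx + 1L
      j <- (lin - 1L) %/% nx + 1L
      b1 <- basin_of(lin)
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        l2 <- ii + (jj - 1L) * nx
        if (is.na(G[l2])) next
        b2 <- basin_of(l2)
        if (b2 == b1) next
        s <- max(G[lin], G[l2])
        if (s < saddle[b1]) {
          saddle[b1] <- s
          saddle_to[b1] <- mins[b2]
        }
      }
    }
    # basins with no populated adjacency (isolated islands) can only escape
    # over the highest observed energy; they merge toward the nearest basin
    gmax <- max(G, na.rm = TRUE)
    iso <- which(!is.finite(saddle))
    if (length(iso) > 0) {
      nx_ <- nx
      pos <- cbind((mins - 1L) %% nx_ + 1L, (mins - 1L) %/% nx_ + 1L)
      for (b in iso) {
        saddle[b] <- gmax
        others <- setdiff(seq_along(mins), b)
        dd <- (pos[others, 1] - pos[b, 1])^2 + (pos[others, 2] - pos[b, 2])^2
        near <- others[order(dd, G[mins[others]], mins[others])][1]
        saddle_to[b] <- mins[near]
      }
    }
    depth <- saddle - G[mins]
    shallow <- which(depth < min_depth)
    if (length(shallow) == 0) break
    victim <- shallow[which.min(depth[shallow])]
    assign_to[assign_to == mins[victim]] <- saddle_to[victim]
    # re-route: merged basin's bins now belong to the absorbing minimum
  }

  mins <- unique(assign_to[pop_bins])
  mins <- mins[order(G[mins])]
  labels <- make_basin_labels(length(mins))
  basins <- lapply(seq_along(mins), function(k) {
    bins_k <- pop_bins[assign_to[pop_bins] == mins[k]]
    pop_frac <- sum(fes$counts[bins_k]) / fes$n_frames
    list(label = labels[k], bins = bins_k, min_bin = mins[k],
         min_G = G[mins[k]], population = pop_frac,
         minor = pop_frac < min_population)
  })
  bin_to_basin <- rep(NA_character_, nx * ny)
  for (b in basins) bin_to_basin[b$bins] <- b$label
  structure(list(basins = basins, bin_to_basin = bin_to_basin,
                 min_depth = min_depth, min_population = min_population,
                 fes_dim = c(nx, ny)),
            class = "basin_set")
}

make_basin_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}

#' @export
print.basin_set <- function(x, ...) {
  cat("Basin decomposition:", length(x$basins), "basins\n")
  for (b in x$basins)
    cat(sprintf("  %s: population %.3f, min G %.2f kJ/mol%s\n",
                b$label, b$population, b$min_G,
                if (b$minor) " (minor)" else ""))
  invisible(x)
}

#' Assign ensemble frames to free-energy basins
#'
#' Each frame is mapped to the basin of its histogram bin; frames falling in
#' masked (unpopulated) bins or outside the grid are labelled `NA`
#' (unassigned).
#'
#' @param fes the [estimate_fel()] surface the basins were derived from.
#' @param basins a [detect_basins()] decomposition of `fes`.
#' @param x,y the per-frame reaction coordinates.
#' @return character vector of basin labels, one per frame (`NA` =
#'   unassigned).
#' @export
assign_frames_to_basins <- function(fes, basins, x, y) {
  stopifnot(inherits(fes, "fel_surface"), inherits(basins, "basin_set"))
  nx <- nrow(fes$G)
  ix <- findInterval(x, fes$xbreaks, rightmost.closed = TRUE)
  iy <- findInterval(y, fes$ybreaks, rightmost.closed = TRUE)
  out <- rep(NA_character_, length(x))
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ncol(fes$G)
  lin <- ix[ok] + (iy[ok] - 1L) * nx
  out[ok] <- basins$bin_to_basin[lin]
  out
}
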