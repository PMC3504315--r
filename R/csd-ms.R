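# Native ESI-MS charge-state-distribution deconvolution.
#
# Multimodal charge-state distributions of a protein electrosprayed under
# non-denaturing conditions indicate coexisting conformers; fitting the
# intensity-versus-charge profile with the minimal number of Gaussian
# components that remains stable quantifies their apparent relative
# abundances, and the mean charge of each component tracks the conformer's
# solvent-accessible surface.

#' Charge-state distribution
#'
#' Relative ion intensity versus (integer) charge, after the transformation
#' of an ESI spectrum from the m/z axis to the charge axis.
#'
#' @param charges integer charge states, strictly increasing, length >= 3.
#' @param intensities non-negative relative intensities.
#' @param metadata optional list (polarity, provenance, ...).
#' @return an object of class `charge_state_distribution`.
#' @export
charge_state_distribution <- function(charges, intensities, metadata = list()) {
  charges <- as.numeric(charges)
  if (length(charges) < 3) stop("at least 3 charge states are required")
  if (any(diff(charges) <= 0)) stop("charges must be strictly increasing")
  if (length(intensities) != length(charges) || any(intensities < 0))
    stop("intensities must be non-negative, one per charge state")
  structure(list(charges = charges, intensities = as.numeric(intensities),
                 metadata = metadata),
            class = "charge_state_distribution")
}

#' @export
print.charge_state_distribution <- function(x, ...) {
  cat(sprintf("Charge-state distribution: z = %g..%g (%d states), max at z = %g\n",
              min(x$charges), max(x$charges), length(x$charges),
              x$charges[which.max(x$intensities)]))
  invisible(x)
}

#' Specification of a synthetic charge-state distribution
#'
#' @param components data frame with columns `mean`, `sigma`, `area` (one
#'   Gaussian conformer component per row; areas > 0, sigma > 0).
#' @param z_range integer charge range `c(z_min, z_max)`.
#' @param noise_sigma relative intensity noise (multiplicative Gaussian).
#' @param seed RNG seed.
#' @return an object of class `csd_spec`.
#' @export
csd_spec <- function(components, z_range = c(1, 20), noise_sigma = 0.02,
                     seed = 1) {
  components <- as.data.frame(components)
  if (any(components$area <= 0)) stop("component areas must be positive")
  if (any(components$sigma <= 0)) stop("component widths must be positive")
  if (z_range[1] >= z_range[2]) stop("z_min must be below z_max")
  structure(list(components = components, z_range = z_range,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "csd_spec")
}

#' Generate a synthetic charge-state distribution with ground truth
#'
#' Intensity at every integer charge is the sum of the components' Gaussian
#' densities scaled by their areas, with optional multiplicative noise.
#'
#' @param spec a [csd_spec()].
#' @return a list: `csd` (a [charge_state_distribution()]) and `truth` (the
#'   component table with area fractions).
#' @export
generate_csd <- function(spec) {
  stopifnot(inherits(spec, "csd_spec"))
  z <- seq(spec$z_range[1], spec$z_range[2])
  clean <- rowSums(vapply(seq_len(nrow(spec$components)), function(k)
    spec$components$area[k] *
      stats::dnorm(z, spec$components$mean[k], spec$components$sigma[k]),
    numeric(length(z))))
  intens <- with_seed(spec$seed, {
    if (spec$noise_sigma > 0)
      pmax(0, clean * (1 + stats::rnorm(length(z), 0, spec$noise_sigma)))
    else clean
  })
  truth <- spec$components
  truth$fraction <- truth$area / sum(truth$area)
  list(csd = charge_state_distribution(z, intens,
                                       metadata = list(synthetic = TRUE)),
       truth = truth)
}

# least-squares fit of a k-component Gaussian mixture to (z, intensity);
# returns NULL on failure
fit_gaussians_k <- function(z, y, k, start = NULL) {
  if (is.null(start)) {
    w <- y / sum(y)
    cw <- cumsum(w)
    qs <- (seq_len(k) - 0.5) / k
    means <- vapply(qs, function(q) z[which.min(abs(cw - q))], 0)
    span <- diff(range(z))
    start <- list(means = means,
                  lsig = rep(log(span / (3 * k)), k),
                  larea = rep(log(sum(y) * (z[2] - z[1])/ k + 1e-12), k))
  }
  par0 <- c(start$means, start$lsig, start$larea)
  resid_fn <- function(p) {
    mu <- p[seq_len(k)]
    sg <- exp(p[k + seq_len(k)])
    ar <- exp(p[2 * k + seq_len(k)])
    y - rowSums(vapply(seq_len(k), function(i)
      ar[i] * stats::dnorm(z, mu[i], sg[i]), numeric(length(z))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  comp <- data.frame(mean_z = p[seq_len(k)],
                     sigma_z = exp(p[k + seq_len(k)]),
                     area = exp(p[2 * k + seq_len(k)]))
  comp <- comp[order(comp$mean_z), ]
  rss <- sum(resid_fn(p)^2)
  list(components = comp, rss = rss, par = p,
       fitted = y - resid_fn(p))
}

#' Deconvolve a charge-state distribution into Gaussian components
#'
#' Fits mixtures of k = 1..`max_components` Gaussians on the charge axis and
#' selects the minimal number leading to a stable fit. "Stable" is
#' operationalized as three requirements on a candidate mixture size:
#' component means must be mutually resolved (adjacent means separated by at
#' least `sep_factor` times the wider of the two sigmas, as expected for
#' distinct conformer modes) with every area fraction at least
#' `min_fraction`, residual-bootstrap refits from neutral starting values
#' must keep every component mean within `boot_mean_tol` charge units in at
#' least `boot_accept` of the replicates, and an extra component must improve
#' the information criterion (AIC) by more than `ic_margin` to be accepted.
#' Mixture sizes that are unresolved or bootstrap-unstable never count as
#' improvements. Components are returned sorted by mean charge with area
#' fractions.
#'
#' @param csd a [charge_state_distribution()].
#' @param max_components maximum mixture size to consider.
#' @param ic_margin required AIC improvement to accept an extra component.
#' @param n_boot residual-bootstrap replicates for the stability check.
#' @param boot_mean_tol allowed bootstrap drift of component means, z units.
#' @param boot_accept required fraction of stable bootstrap refits.
#' @param sep_factor required separation of adjacent means, in units of the
#'   wider of the two component sigmas.
#' @param min_fraction minimum area fraction of an admissible component.
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `csd_fit`: `components` (mean_z, sigma_z, area,
#'   fraction), `k`, per-k fit summaries, `stable` and `poor_fit` flags, and
#'   fitted intensities.
#' @export
fit_csd <- function(csd, max_components = 4, ic_margin = 2, n_boot = 30,
                    boot_mean_tol = 0.5, boot_accept = 0.8, sep_factor = 2,
                    min_fraction = 0.05, seed = 1) {
  stopifnot(inherits(csd, "charge_state_distribution"))
  z <- csd$charges
  y <- csd$intensities
  if (all(y == 0)) stop("all intensities are zero")
  n <- length(z)
  kmax <- min(max_components, floor((n - 1) / 3))
  if (kmax < 1) stop("fewer data points than fit parameters")
  fits <- vector("list", kmax)
  aic <- rep(NA_real_, kmax)
  resolved <- stable_k <- rep(FALSE, kmax)
  for (k in seq_len(kmax)) {
    fits[[k]] <- fit_gaussians_k(z, y, k)
    if (is.null(fits[[k]])) next
    f <- fits[[k]]
    aic[k] <- n * log(f$rss / n + 1e-300) + 2 * (3 * k)
    mu <- f$components$mean_z
    sg <- f$components$sigma_z
    fr <- f$components$area / sum(f$components$area)
    resolved[k] <- all(fr >= min_fraction) &&
      (k == 1 || all(diff(mu) >= sep_factor * pmax(sg[-k], sg[-1])))
    if (resolved[k]) {
      stable_k[k] <- with_seed(seed + k, {
        good <- 0
        for (b in seq_len(n_boot)) {
          yb <- pmax(0, f$fitted + sample(y - f$fitted, n, replace = TRUE))
          fb <- fit_gaussians_k(z, yb, k)  # neutral (quantile) starts
          if (!is.null(fb) &&
              all(abs(sort(fb$components$mean_z) - sort(mu)) <= boot_mean_tol))
            good <- good + 1
        }
        good / n_boot >= boot_accept
      })
    }
  }
  ok <- which(!is.na(aic))
  if (length(ok) == 0) stop("Gaussian fitting failed for every k")
  acceptable <- which(resolved & stable_k)
  if (length(acceptable) == 0) acceptable <- ok[1]
  k_sel <- acceptable[1]
  repeat {
    larger <- acceptable[acceptable > k_sel]
    if (length(larger) == 0) break
    if (aic[larger[1]] < aic[k_sel] - ic_margin) k_sel <- larger[1] else break
  }
  stable <- stable_k[k_sel]
  f <- fits[[k_sel]]
  comp <- f$components
  comp$fraction <- comp$area / sum(comp$area)
  ss_tot <- sum((y - mean(y))^2)
  poor_fit <- ss_tot <= 0 || (1 - f$rss / ss_tot) < 0.5
  structure(list(components = comp, k = k_sel, aic = aic,
                 rss = f$rss, fitted = f$fitted, stable = stable,
                 poor_fit = poor_fit, charges = z, intensities = y),
            class = "csd_fit")
}

#' @export
print.csd_fit <- function(x, ...) {
  cat(sprintf("CSD deconvolution: %d component(s)%s%s\n", x$k,
              if (!x$stable) " [unstable]" else "",
              if (x$poor_fit) " [poor fit]" else ""))
  with(x$components,
       cat(sprintf("  mean z = %.2f, sigma = %.2f, fraction = %.3f\n",
                   mean_z, sigma_z, fraction), sep = ""))
  invisible(x)
}

#' @export
plot.csd_fit <- function(x, ...) {
  graphics::plot(x$charges, x$intensities, type = "h", lwd = 3,
                 xlab = "charge z", ylab = "relative intensity", ...)
  zz <- seq(min(x$charges), max(x$charges), length.out = 200)
  tot <- rep(0, length(zz))
  for (i in seq_len(nrow(x$components))) {
    yi <- x$components$area[i] *
      stats::dnorm(zz, x$components$mean_z[i], x$components$sigma_z[i])
    graphics::lines(zz, yi, lty = 2)
    tot <- tot + yi
  }
  graphics::lines(zz, tot, col = 2, lwd = 2)
  invisible(x)
}

#' Relative abundances of fitted conformer components
#'
#' @param components a `csd_fit` or its component table.
#' @return numeric vector of area fractions summing to 1.
#' @export
component_abundances <- function(components) {
  tab <- if (inherits(components, "csd_fit")) components$components
  else as.data.frame(components)
  if (nrow(tab) < 1) stop("at least one component is required")
  tab$area / sum(tab$area)
}

#' Map a component's mean charge to an estimated accessible surface
#'
#' The extent of electrospray ionization of a folded-state conformer
#' correlates with its solvent-accessible surface; a power-law calibration
#' `SAS = a * z^b` maps the fitted mean charge to nm^2. The calibration
#' constants come from published charge-versus-surface regressions and must
#' be supplied explicitly.
#'
#' @param mean_z mean charge of a component (> 0).
#' @param calibration numeric `c(a, b)` (named or positional).
#' @return estimated SAS, nm^2, with the calibration recorded as an
#'   attribute.
#' @export
charge_to_sas <- function(mean_z, calibration = NULL) {
  if (is.null(calibration) || length(calibration) != 2 ||
      any(!is.finite(calibration)))
    stop("supply calibration = c(a, b) from a published charge-to-surface ",
         "regression; no default is assumed")
  if (any(mean_z <= 0)) stop("mean_z must be positive")
  a <- unname(calibration[1])
  b <- unname(calibration[2])
  out <- a * mean_z^b
  attr(out, "calibration") <- c(a = a, b = b)
  out
}
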