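## Solvent analysis: 1-D water density along the pathway by Gaussian kernel
## density estimation, conversion to number density, and Boltzmann inversion
## into a hydration free-energy profile.

.default_bulk_band <- function(s) {
  ## outermost 10% of the s-range at each end
  lo <- s[1L]; hi <- s[length(s)]
  w <- 0.1 * (hi - lo)
  list(c(lo, lo + w), c(hi - w, hi))
}

.band_mask <- function(s, bands) {
  if (is.numeric(bands)) bands <- list(bands)
  mask <- rep(FALSE, length(s))
  for (b in bands) mask <- mask | (s >= b[1L] & s <= b[2L])
  mask
}

#' Gaussian kernel density estimate along the pathway
#'
#' Estimates `P(s) = (1/N) sum_i K_h(s - s_i)` with a Gaussian kernel of
#' bandwidth `h` on a uniform grid.  The default bandwidth of 0.14 nm is
#' about the radius of a water molecule; it keeps pore densities comparable
#' between structures, whereas the AMISE-optimal bandwidth varies with pore
#' volume.
#'
#' @param samples pathway coordinates of the particles (nm).
#' @param bandwidth kernel bandwidth h in nm, or `"amise"` to use
#'   [amise_bandwidth()].
#' @param range evaluation range `c(lo, hi)`; default covers the samples
#'   plus 5 bandwidths on either side (so the density integrates to 1 over
#'   the range up to Gaussian tail mass < 1e-6).
#' @param spacing grid spacing; default `bandwidth / 5`.
#' @return a `Profile` of quantity `"density"` (nm^-1) with attribute
#'   `n_samples`.
#' @export
kde_1d <- function(samples, bandwidth = 0.14, range = NULL, spacing = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("kernel density estimation needs at least one sample")
  if (identical(bandwidth, "amise")) bandwidth <- amise_bandwidth(samples)
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  if (is.null(range))
    range <- c(min(samples) - 5 * bandwidth, max(samples) + 5 * bandwidth)
  if (is.null(spacing)) spacing <- bandwidth / 5
  grid <- .uniform_grid(range[1L], range[2L], spacing)
  dens <- vapply(grid, function(g) mean(dnorm(g, mean = samples, sd = bandwidth)),
                 numeric(1L))
  p <- new_profile(grid, dens, quantity = "density")
  attr(p, "n_samples") <- length(samples)
  attr(p, "bandwidth") <- bandwidth
  p
}

#' AMISE-optimal bandwidth (Gaussian reference rule)
#'
#' Bandwidth minimizing the asymptotic mean integrated square error of a
#' Gaussian-kernel density estimate under the normal reference:
#' `h = 1.06 * sd(x) * N^(-1/5)` (Silverman's rule).  A plug-in alternative
#' (`method = "sj"`, Sheather-Jones) is provided.
#'
#' @param samples numeric sample vector (at least 2 distinct values).
#' @param method `"silverman"` (default) or `"sj"`.
#' @return bandwidth in the units of `samples`.
#' @export
amise_bandwidth <- function(samples, method = c("silverman", "sj")) {
  method <- match.arg(method)
  samples <- as.numeric(samples)
  if (length(unique(samples)) < 2L || sd(samples) == 0)
    stop("bandwidth selection needs at least two distinct samples")
  switch(method,
         silverman = 1.06 * sd(samples) * length(samples)^(-1 / 5),
         sj = stats::bw.SJ(samples))
}

#' Water number density profile
#'
#' Converts the 1-D probability density into a number density assuming a
#' circular pore cross section: `n(s) = N * P(s) / (pi * R(s)^2)` in nm^-3.
#'
#' @param P density `Profile` from [kde_1d()].
#' @param R radius `Profile` on the same grid.
#' @param N number of water molecules behind `P`; defaults to the
#'   `n_samples` attribute of `P`.
#' @return a `Profile` of quantity `"number_density"`.
#' @export
number_density <- function(P, R, N = attr(P, "n_samples")) {
  stopifnot(inherits(P, "Profile"), inherits(R, "Profile"))
  if (length(P$s) != length(R$s) || max(abs(P$s - R$s)) > 1e-9)
    stop("density and radius profiles must share the same grid")
  if (any(R$value <= 0)) stop("radius profile must be positive everywhere")
  if (is.null(N)) stop("N (water count) is required")
  new_profile(P$s, N * P$value / (pi * R$value^2), quantity = "number_density")
}

#' Hydration free-energy profile by Boltzmann inversion
#'
#' Inverts the water density into `G(s) = -kT ln( P(s) / (pi R(s)^2) ) + C`,
#' with the additive constant fixed by the convention that the mean free
#' energy over the bulk band is zero.  Grid points where the estimated
#' density falls below the floor `1/(N * range)` are flagged as dehydrated;
#' there `G` is a lower bound computed at the floor (the true value is
#' singular for zero density).
#'
#' @param P density `Profile` from [kde_1d()].
#' @param R radius `Profile` on the same grid.
#' @param temperature simulation temperature in K.
#' @param bulk_band interval `c(lo, hi)` or list of intervals defining bulk
#'   water; default: the outermost 10% of the hydrated s-range at each end
#'   (grid points below the density floor are never counted as bulk).
#'   Prefer an explicit band inside well-sampled bulk when one is known.
#' @param N water count; defaults to the `n_samples` attribute of `P`.
#' @return a `Profile` of quantity `"free_energy"` (kJ/mol) with logical
#'   attribute `dehydrated`.
#' @export
free_energy <- function(P, R, temperature = 298.15, bulk_band = NULL,
                        N = attr(P, "n_samples")) {
  stopifnot(inherits(P, "Profile"), inherits(R, "Profile"), temperature > 0)
  if (length(P$s) != length(R$s) || max(abs(P$s - R$s)) > 1e-9)
    stop("density and radius profiles must share the same grid")
  if (is.null(N)) stop("N (water count) is required")
  kT <- .kB * temperature
  floor_eps <- 1 / (N * (P$s[length(P$s)] - P$s[1L]))
  dehydrated <- P$value < floor_eps
  if (is.null(bulk_band)) {
    ## default band: outermost 10% of the *hydrated* s-range at each end
    ## (the traced pathway often extends into unsolvated pore mouths, where
    ## a naive whole-grid band would contain no water at all)
    wet <- P$s[!dehydrated]
    if (!length(wet))
      stop("cannot normalize free energy: all grid points are dehydrated")
    bulk_band <- .default_bulk_band(wet)
  }
  q <- pmax(P$value, floor_eps) / (pi * R$value^2)
  G0 <- -kT * log(q)
  bulk <- .band_mask(P$s, bulk_band) & !dehydrated
  if (!any(bulk))
    stop("cannot normalize free energy: all bulk-band points are dehydrated")
  G <- G0 - mean(G0[bulk])
  out <- new_profile(P$s, G, quantity = "free_energy")
  attr(out, "dehydrated") <- dehydrated
  attr(out, "temperature") <- temperature
  attr(out, "floor") <- floor_eps
  attr(out, "bulk_band") <- bulk_band
  out
}

#' Detect de-wetted pathway segments
#'
#' Maximal runs of grid points whose number density falls below a fraction
#' of the bulk density and whose span is at least `min_length`.
#'
#' @param n number-density `Profile`.
#' @param fraction_of_bulk density threshold as a fraction of bulk density.
#' @param min_length minimum segment span in nm.
#' @param bulk_band interval(s) used to estimate bulk density; default the
#'   outermost 10% of the range at each end.
#' @param bulk_density optional explicit bulk density overriding `bulk_band`.
#' @return list of `c(s_start, s_end)` intervals (possibly empty).
#' @export
detect_dewetted <- function(n, fraction_of_bulk = 0.2, min_length = 0.3,
                            bulk_band = NULL, bulk_density = NULL) {
  stopifnot(inherits(n, "Profile"))
  if (is.null(bulk_density)) {
    if (is.null(bulk_band)) bulk_band <- .default_bulk_band(n$s)
    bulk_density <- mean(n$value[.band_mask(n$s, bulk_band)])
  }
  low <- n$value < fraction_of_bulk * bulk_density
  out <- list()
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    span <- n$s[ends[k]] - n$s[starts[k]]
    if (span >= min_length) out[[length(out) + 1L]] <- c(n$s[starts[k]], n$s[ends[k]])
  }
  out
}
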