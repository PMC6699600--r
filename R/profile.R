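## Profile: a scalar quantity on a uniform grid of the pathway coordinate s.

#' Construct a pathway profile
#'
#' @param s uniform, strictly increasing grid of pathway coordinates (nm),
#'   with s = 0 at the projection of the initial probe point.
#' @param value scalar values at the grid points.
#' @param quantity one of `"radius"`, `"hydrophobicity"`, `"density"`,
#'   `"number_density"`, `"free_energy"`.
#' @param bands optional list of per-grid-point summary vectors
#'   (`mean`, `sd`, `min`, `max`).
#' @return object of class `Profile`.
#' @export
new_profile <- function(s, value,
                        quantity = c("radius", "hydrophobicity", "density",
                                     "number_density", "free_energy"),
                        bands = NULL) {
  quantity <- match.arg(quantity)
  stopifnot(length(s) == length(value), length(s) >= 2L)
  ds <- diff(s)
  if (any(ds <= 0) || (max(ds) - min(ds)) > 1e-8 * mean(ds))
    stop("profile grid must be strictly increasing with uniform spacing")
  structure(list(s = as.numeric(s), value = as.numeric(value),
                 quantity = quantity, bands = bands),
            class = "Profile")
}

#' Evaluate a profile between grid points
#'
#' Natural cubic interpolation of the gridded values; outside the grid the
#' boundary value is extended (used e.g. for radius lookups of residues
#' slightly beyond the traced pathway).
#'
#' @param profile a `Profile`.
#' @param s query coordinates (nm).
#' @return numeric vector of interpolated values.
#' @export
profile_eval <- function(profile, s) {
  f <- splinefun(profile$s, profile$value, method = "natural")
  f(pmin(pmax(s, profile$s[1L]), profile$s[length(profile$s)]))
}

#' @export
print.Profile <- function(x, ...) {
  cat(sprintf("<Profile:%s> %d points, s in [%.3f, %.3f] nm, value in [%.4g, %.4g]\n",
              x$quantity, length(x$s), x$s[1L], x$s[length(x$s)],
              min(x$value, na.rm = TRUE), max(x$value, na.rm = TRUE)))
  invisible(x)
}

## uniform grid covering [lo, hi] with spacing <= by, endpoints included
.uniform_grid <- function(lo, hi, by) {
  n <- max(2L, ceiling((hi - lo) / by - 1e-9) + 1L)
  seq(lo, hi, length.out = n)
}
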