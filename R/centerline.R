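## Centerline: interpolate probe points into an arc-length parameterized
## cubic spline curve with an attached continuous radius profile.
##
## Construction: natural cubic interpolating splines per coordinate against
## the chord-length parameter, then reparameterization to arc length via
## per-panel Gauss-Legendre quadrature and a monotone (Hyman-filtered)
## inverse mapping.  The curve passes exactly through every probe point and
## is unit-speed in the arc-length parameter.

## 7-point Gauss-Legendre rule on [-1, 1]
.gl7_x <- c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
             0.4058451513773972,  0.7415311855993945,  0.9491079123427585)
.gl7_w <- c(0.1294849661688697, 0.2797053914892767, 0.3818300505051189,
            0.4179591836734694,
            0.3818300505051189, 0.2797053914892767, 0.1294849661688697)

#' Fit an arc-length parameterized centerline through probe points
#'
#' @param trace a `ProbeTrace` (at least 4 distinct points); duplicate
#'   consecutive points are merged with a warning.
#' @param dense_spacing spacing (nm) of the precomputed dense sampling used
#'   for point projection and the rotation-minimizing frame; defaults to a
#'   quarter of the probe step.
#' @return object of class `CenterlineSpline` with raw arc-length range
#'   `[0, L]` and `s_offset`, the arc length of the projection of the
#'   initial probe point (pathway coordinates are raw arc length minus this
#'   offset, so s = 0 at the initial point's projection).
#' @export
fit_centerline <- function(trace, dense_spacing = NULL) {
  stopifnot(inherits(trace, "ProbeTrace"))
  pts <- trace$points
  radii <- trace$radii
  keep <- c(TRUE, sqrt(rowSums((pts[-1L, , drop = FALSE] -
                                pts[-nrow(pts), , drop = FALSE])^2)) > 1e-9)
  if (!all(keep)) {
    warning("merged duplicate consecutive probe points")
    pts <- pts[keep, , drop = FALSE]
    radii <- radii[keep]
  }
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 distinct probe points to fit a centerline")

  ## chord-length parameterization
  chord <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-n, , drop = FALSE])^2))
  t_knots <- c(0, cumsum(chord))
  fx <- splinefun(t_knots, pts[, 1L], method = "natural")
  fy <- splinefun(t_knots, pts[, 2L], method = "natural")
  fz <- splinefun(t_knots, pts[, 3L], method = "natural")
  speed <- function(t)
    sqrt(fx(t, deriv = 1L)^2 + fy(t, deriv = 1L)^2 + fz(t, deriv = 1L)^2)

  ## cumulative arc length on a refined panel grid (8 panels per interval),
  ## each panel integrated with 7-point Gauss-Legendre
  m <- 8L
  t_fine <- c(t_knots[1L], unlist(lapply(seq_len(n - 1L), function(k) {
    sub <- seq(t_knots[k], t_knots[k + 1L], length.out = m + 1L)
    sub[m + 1L] <- t_knots[k + 1L]   # force exact knot values
    sub[-1L]
  })))
  a <- t_fine[-length(t_fine)]
  b <- t_fine[-1L]
  half <- (b - a) / 2
  mid <- (a + b) / 2
  panel <- numeric(length(a))
  for (j in seq_along(.gl7_x))
    panel <- panel + .gl7_w[j] * speed(mid + half * .gl7_x[j])
  panel <- panel * half
  s_fine <- c(0, cumsum(panel))

  t_of_s <- splinefun(s_fine, t_fine, method = "hyman")
  s_of_t <- splinefun(t_fine, s_fine, method = "hyman")
  s_knots <- s_fine[(seq_len(n) - 1L) * m + 1L]
  L <- s_fine[length(s_fine)]

  obj <- structure(list(fx = fx, fy = fy, fz = fz,
                        t_knots = t_knots, s_knots = s_knots,
                        t_of_s = t_of_s, s_of_t = s_of_t,
                        s_min = 0, s_max = L, s_offset = 0,
                        radii = radii, p0 = trace$p0,
                        probe_step = trace$probe_step,
                        dense = NULL),
                   class = "CenterlineSpline")

  if (is.null(dense_spacing)) dense_spacing <- trace$probe_step / 4
  obj$dense <- .cl_dense_frame(obj, dense_spacing)
  obj$s_offset <- project_point(obj, trace$p0)
  obj
}

## evaluate the curve at raw arc-length values
.cl_point_raw <- function(spline, s) {
  t <- spline$t_of_s(pmin(pmax(s, spline$s_min), spline$s_max))
  cbind(spline$fx(t), spline$fy(t), spline$fz(t))
}

## unit tangent at raw arc-length values
.cl_tangent_raw <- function(spline, s) {
  t <- spline$t_of_s(pmin(pmax(s, spline$s_min), spline$s_max))
  d <- cbind(spline$fx(t, deriv = 1L), spline$fy(t, deriv = 1L),
             spline$fz(t, deriv = 1L))
  d / sqrt(rowSums(d * d))
}

## dense sampling with a rotation-minimizing frame (double-reflection
## transport).  The RMF avoids the tangent-frame flips of the Frenet frame
## at inflection points; the reference normal is meaningful only relatively.
.cl_dense_frame <- function(spline, spacing) {
  s <- .uniform_grid(spline$s_min, spline$s_max, spacing)
  spacing <- (spline$s_max - spline$s_min) / (length(s) - 1L)  # actual
  P <- .cl_point_raw(spline, s)
  Tg <- .cl_tangent_raw(spline, s)
  n <- length(s)
  N <- matrix(0, n, 3L)
  axes <- diag(3)
  k <- which.min(abs(as.vector(axes %*% Tg[1L, ])))
  N[1L, ] <- .normalize3(axes[k, ] - sum(axes[k, ] * Tg[1L, ]) * Tg[1L, ])
  for (i in seq_len(n - 1L)) {
    v1 <- P[i + 1L, ] - P[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < .Machine$double.eps) { N[i + 1L, ] <- N[i, ]; next }
    rL <- N[i, ] - (2 / c1) * sum(v1 * N[i, ]) * v1
    tL <- Tg[i, ] - (2 / c1) * sum(v1 * Tg[i, ]) * v1
    v2 <- Tg[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    N[i + 1L, ] <- if (c2 < .Machine$double.eps) rL
                   else rL - (2 / c2) * sum(v2 * rL) * v2
    N[i + 1L, ] <- .normalize3(N[i + 1L, ] -
                               sum(N[i + 1L, ] * Tg[i + 1L, ]) * Tg[i + 1L, ])
  }
  list(s = s, P = P, T = Tg, N = N, spacing = spacing)
}

#' Evaluate the centerline curve
#'
#' @param spline a `CenterlineSpline`.
#' @param s pathway coordinates (nm; 0 at the initial probe point's
#'   projection), or raw arc length when `raw = TRUE`.
#' @param raw interpret `s` as raw arc length in `[0, L]`.
#' @return n x 3 matrix of curve points.
#' @export
centerline_eval <- function(spline, s, raw = FALSE) {
  stopifnot(inherits(spline, "CenterlineSpline"))
  .cl_point_raw(spline, if (raw) s else s + spline$s_offset)
}

#' @export
print.CenterlineSpline <- function(x, ...) {
  cat(sprintf("<CenterlineSpline> arc length %.3f nm, %d knots, s_offset %.3f nm\n",
              x$s_max, length(x$s_knots), x$s_offset))
  invisible(x)
}

#' Continuous radius profile along the centerline
#'
#' Cubic interpolation of the probe radii against the arc length of their
#' probe points, evaluated on a uniform grid in pathway coordinates.
#'
#' @param spline a `CenterlineSpline` fitted from `trace`.
#' @param trace the `ProbeTrace` used for the fit (supplies the radii).
#' @param spacing grid spacing in nm (default: the probe step).
#' @param grid optional explicit grid of pathway coordinates overriding
#'   `spacing`.
#' @return a `Profile` of quantity `"radius"`.
#' @export
radius_function <- function(spline, trace = NULL, spacing = NULL, grid = NULL) {
  stopifnot(inherits(spline, "CenterlineSpline"))
  radii <- if (is.null(trace)) spline$radii else trace$radii
  if (length(radii) != length(spline$s_knots))
    stop("trace does not match the fitted spline")
  f <- splinefun(spline$s_knots, radii, method = "natural")
  if (is.null(grid)) {
    if (is.null(spacing)) spacing <- spline$probe_step
    grid <- .uniform_grid(spline$s_min - spline$s_offset,
                          spline$s_max - spline$s_offset, spacing)
  }
  s_raw <- pmin(pmax(grid + spline$s_offset, spline$s_min), spline$s_max)
  new_profile(grid, f(s_raw), quantity = "radius")
}

#' Extrude a triangulated pore surface along the centerline
#'
#' Sweeps a circular cross section of local radius `R(s)` along the curve,
#' orienting each ring with the rotation-minimizing frame, and stitches
#' consecutive rings into triangles.
#'
#' @param spline a `CenterlineSpline`.
#' @param radius a radius `Profile`.
#' @param n_ring number of vertices per ring (>= 3).
#' @return object of class `PoreMesh`: list with `vertices` (V x 3) and
#'   `faces` (F x 3, 1-based indices).
#' @export
extrude_surface <- function(spline, radius, n_ring = 16L) {
  stopifnot(inherits(spline, "CenterlineSpline"), inherits(radius, "Profile"),
            n_ring >= 3L)
  s_raw <- radius$s + spline$s_offset
  ctr <- .cl_point_raw(spline, s_raw)
  idx <- vapply(s_raw, function(si)
    which.min(abs(spline$dense$s - si)), integer(1L))
  theta <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
  ng <- length(s_raw)
  verts <- matrix(0, ng * n_ring, 3L)
  for (i in seq_len(ng)) {
    Tg <- .cl_tangent_raw(spline, s_raw[i])[1L, ]
    N0 <- spline$dense$N[idx[i], ]
    N <- .normalize3(N0 - sum(N0 * Tg) * Tg)
    B <- .cross3(Tg, N)
    ring <- ctr[rep(i, n_ring), , drop = FALSE] +
      radius$value[i] * (cos(theta) %o% N + sin(theta) %o% B)
    verts[(i - 1L) * n_ring + seq_len(n_ring), ] <- ring
  }
  faces <- matrix(0L, 2L * (ng - 1L) * n_ring, 3L)
  fi <- 0L
  for (i in seq_len(ng - 1L)) {
    base <- (i - 1L) * n_ring
    for (j in seq_len(n_ring)) {
      jn <- if (j == n_ring) 1L else j + 1L
      faces[fi + 1L, ] <- c(base + j, base + jn, base + n_ring + j)
      faces[fi + 2L, ] <- c(base + jn, base + n_ring + jn, base + n_ring + j)
      fi <- fi + 2L
    }
  }
  structure(list(vertices = verts, faces = faces, n_ring = as.integer(n_ring)),
            class = "PoreMesh")
}

#' Write a mesh as Wavefront OBJ
#'
#' @param mesh a `PoreMesh`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "PoreMesh"))
  v <- sprintf("v %.6f %.6f %.6f",
               mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L])
  f <- sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L])
  writeLines(c("# porescope extruded pore surface", v, f), path)
  invisible(path)
}
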