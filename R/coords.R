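## Curvilinear pathway coordinates: map Cartesian positions to (s, rho, phi)
## relative to the centerline spline.  For a straight centerline this reduces
## exactly to canonical cylindrical coordinates.

## Vectorized global projection: coarse nearest-point search on the dense
## sampling followed by iterative 9-candidate bracket refinement (all
## vectorized across query points), finishing with a parabolic step.
## Returns raw arc-length parameters clamped to [s_min, s_max].
.project_points_raw <- function(spline, Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1L)
  nq <- nrow(Q)
  ds <- spline$dense
  ## coarse pass, chunked to bound memory
  best <- numeric(nq)
  chunk <- max(1L, floor(4e6 / length(ds$s)))
  for (lo in seq(1L, nq, by = chunk)) {
    hi <- min(nq, lo + chunk - 1L)
    D <- outer(Q[lo:hi, 1L], ds$P[, 1L], "-")^2 +
         outer(Q[lo:hi, 2L], ds$P[, 2L], "-")^2 +
         outer(Q[lo:hi, 3L], ds$P[, 3L], "-")^2
    best[lo:hi] <- ds$s[max.col(-D, ties.method = "first")]
  }
  ## bracketed refinement
  width <- ds$spacing
  offs <- seq(-1, 1, by = 0.25)
  for (round in 1:6) {
    cand <- pmin(pmax(rep(best, each = length(offs)) +
                      rep(offs * width, times = nq),
                      spline$s_min), spline$s_max)
    Pc <- .cl_point_raw(spline, cand)
    d2 <- (Pc[, 1L] - rep(Q[, 1L], each = length(offs)))^2 +
          (Pc[, 2L] - rep(Q[, 2L], each = length(offs)))^2 +
          (Pc[, 3L] - rep(Q[, 3L], each = length(offs)))^2
    d2m <- matrix(d2, nrow = length(offs))
    pick <- max.col(-t(d2m), ties.method = "first")
    best <- cand[(seq_len(nq) - 1L) * length(offs) + pick]
    width <- width / 4
  }
  ## parabolic polish on the final bracket
  h <- width
  s0 <- pmin(pmax(best, spline$s_min + h), spline$s_max - h)
  d2of <- function(s) {
    P <- .cl_point_raw(spline, s)
    (P[, 1L] - Q[, 1L])^2 + (P[, 2L] - Q[, 2L])^2 + (P[, 3L] - Q[, 3L])^2
  }
  f0 <- d2of(s0); fm <- d2of(s0 - h); fp <- d2of(s0 + h)
  denom <- fm - 2 * f0 + fp
  shift <- ifelse(abs(denom) > .Machine$double.eps,
                  0.5 * h * (fm - fp) / denom, 0)
  shift <- pmin(pmax(shift, -h), h)
  polished <- pmin(pmax(s0 + shift, spline$s_min), spline$s_max)
  improved <- d2of(polished) <= f0
  out <- ifelse(improved, polished, s0)
  ## keep exact boundary results when the true minimum sits at an endpoint
  at_lo <- best <= spline$s_min + 1e-12
  at_hi <- best >= spline$s_max - 1e-12
  out[at_lo] <- spline$s_min
  out[at_hi] <- spline$s_max
  out
}

#' Project a point onto the centerline
#'
#' Returns the raw arc-length parameter of the curve point closest to `Q`,
#' i.e. the global minimizer of `||S(s) - Q||` over `[0, L]` (coarse scan on
#' the dense sampling plus bracketed refinement).
#'
#' @param spline a `CenterlineSpline`.
#' @param Q length-3 position (nm), or an n x 3 matrix of positions.
#' @return raw arc-length parameter(s) in `[0, L]` (nm); subtract
#'   `spline$s_offset` for pathway coordinates.
#' @export
project_point <- function(spline, Q) {
  stopifnot(inherits(spline, "CenterlineSpline"))
  .project_points_raw(spline, Q)
}

#' Map positions into curvilinear pathway coordinates
#'
#' Computes, for each position, the pathway coordinate `s` (arc length of
#' the closest curve point minus the offset of the initial probe point's
#' projection), the distance `rho` to the centerline, and the angle `phi`
#' around it measured against a rotation-minimizing reference normal
#' (meaningful only relatively; it is integrated out in the 1-D density).
#' Positions whose closest curve point is an endpoint are assigned `s` by
#' signed extension along the endpoint tangent, so bulk particles beyond the
#' pore mouths receive finite coordinates.
#'
#' @param spline a `CenterlineSpline`.
#' @param Q length-3 position (nm) or n x 3 matrix.
#' @return data.frame with columns `s`, `rho`, `phi`.
#' @export
to_curvilinear <- function(spline, Q) {
  stopifnot(inherits(spline, "CenterlineSpline"))
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1L)
  s_raw <- .project_points_raw(spline, Q)
  P <- .cl_point_raw(spline, s_raw)
  Tg <- .cl_tangent_raw(spline, s_raw)

  ## endpoint extension: if the projection hit a boundary and the point lies
  ## beyond it (positive tangential component outward), extend linearly
  at_hi <- s_raw >= spline$s_max - 1e-12
  at_lo <- s_raw <= spline$s_min + 1e-12
  d <- Q - P
  tdot <- rowSums(d * Tg)
  ext_hi <- at_hi & tdot > 0
  ext_lo <- at_lo & tdot < 0
  ext <- ext_hi | ext_lo
  if (any(ext)) {
    s_raw[ext] <- s_raw[ext] + tdot[ext]
    P[ext, ] <- P[ext, , drop = FALSE] + tdot[ext] * Tg[ext, , drop = FALSE]
    d[ext, ] <- Q[ext, , drop = FALSE] - P[ext, , drop = FALSE]
  }

  rho <- sqrt(rowSums(d * d))
  ## reference normal from the rotation-minimizing frame at the nearest
  ## dense sample, re-orthogonalized against the local tangent
  idx <- pmin(pmax(round((pmin(pmax(s_raw, spline$s_min), spline$s_max) -
                          spline$s_min) / spline$dense$spacing) + 1L, 1L),
              length(spline$dense$s))
  N0 <- spline$dense$N[idx, , drop = FALSE]
  N <- N0 - rowSums(N0 * Tg) * Tg
  nn <- sqrt(rowSums(N * N))
  N <- N / nn
  B <- cbind(Tg[, 2L] * N[, 3L] - Tg[, 3L] * N[, 2L],
             Tg[, 3L] * N[, 1L] - Tg[, 1L] * N[, 3L],
             Tg[, 1L] * N[, 2L] - Tg[, 2L] * N[, 1L])
  phi <- atan2(rowSums(d * B), rowSums(d * N)) %% (2 * pi)
  phi[2 * pi - phi < 1e-9] <- 0       # keep phi in [0, 2*pi)
  phi[rho < 1e-12] <- 0
  data.frame(s = s_raw - spline$s_offset, rho = rho, phi = phi)
}
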