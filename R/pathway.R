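## Pathway finding: sweep a spherical probe through the hard-sphere protein,
## maximizing the probe radius in successive planes normal to the channel
## direction.

#' Pathway sweep configuration
#'
#' @param probe_step plane spacing Delta v along the channel direction (nm).
#'   0.1 nm (about one hydrogen vdW radius) resolves channel features;
#'   halving it changes profiles only minimally.
#' @param direction unit vector e_v giving the overall permeation direction
#'   (normalized internally).
#' @param init_point initial probe position P0 (nm); default (`NULL`) is the
#'   center of geometry of the non-water atoms.
#' @param simplex_iter number of Nelder-Mead iterations per plane; 100
#'   converges the radius profile to within ~0.001 nm.
#' @param stop_radius termination threshold (nm): the probe is deemed to
#'   have left the pore when its optimized radius exceeds this.
#' @param max_steps hard cap on the number of planes per sweep direction.
#' @return object of class `PathwayConfig`.
#' @export
pathway_config <- function(probe_step = 0.1, direction = c(0, 0, 1),
                           init_point = NULL, simplex_iter = 100L,
                           stop_radius = 1.0, max_steps = 10000L) {
  stopifnot(probe_step > 0, stop_radius > 0, length(direction) == 3L)
  structure(list(probe_step = probe_step,
                 direction = .normalize3(direction),
                 init_point = init_point,
                 simplex_iter = as.integer(simplex_iter),
                 stop_radius = stop_radius,
                 max_steps = as.integer(max_steps)),
            class = "PathwayConfig")
}

## hard-sphere set of a frame: coordinate matrix and radii of non-water atoms
.hard_spheres <- function(frame) {
  a <- frame$atoms
  sel <- !a$is_water
  if (!any(sel)) stop("frame has no protein atoms")
  if (anyNA(a$vdw[sel]))
    stop("vdW radii not assigned; call assign_vdw_radii() first")
  list(xyz = cbind(a$x[sel], a$y[sel], a$z[sel]), r = a$vdw[sel])
}

.probe_radius_hs <- function(P, hs) {
  dx <- hs$xyz[, 1L] - P[1L]
  dy <- hs$xyz[, 2L] - P[2L]
  dz <- hs$xyz[, 3L] - P[3L]
  min(sqrt(dx * dx + dy * dy + dz * dz) - hs$r)
}

#' Probe radius at a point
#'
#' Largest sphere centered at `P` that does not overlap the van der Waals
#' sphere of any non-water atom: `min_j (||Q_j - P|| - r_j)`.  Negative when
#' the point lies inside an atom's vdW sphere.
#'
#' @param P numeric length-3 position (nm).
#' @param frame a `Frame` with vdW radii assigned.
#' @return probe radius in nm.
#' @export
probe_radius <- function(P, frame) {
  .probe_radius_hs(P, .hard_spheres(frame))
}

.optimize_in_plane_hs <- function(hs, start, e_u, e_w, n_iter, simplex_scale) {
  f <- function(uw)
    -.probe_radius_hs(start + uw[1L] * e_u + uw[2L] * e_w, hs)
  res <- .nelder_mead_2d(f, c(0, 0), simplex_scale, n_iter)
  list(point = start + res$x[1L] * e_u + res$x[2L] * e_w, radius = -res$f)
}

#' Maximize the probe radius within a plane
#'
#' Runs a 2-D Nelder-Mead maximization of [probe_radius()] over the plane
#' through `start` spanned by `e_u` and `e_w`.  With `n_iter = 0` the seed
#' point and its probe radius are returned unchanged.
#'
#' @param frame a `Frame` with vdW radii assigned.
#' @param start seed point in the plane (nm).
#' @param e_u,e_w orthonormal in-plane basis vectors.
#' @param n_iter number of simplex iterations.
#' @param simplex_scale edge length of the initial simplex (nm); defaults to
#'   0.1 of the default probe step.
#' @return list with `point` (length-3, in the plane of `start`) and
#'   `radius` (nm).
#' @export
optimize_probe_in_plane <- function(frame, start, e_u, e_w, n_iter = 100L,
                                    simplex_scale = 0.01) {
  stopifnot(abs(sum(e_u * e_w)) < 1e-9,
            abs(.norm3(e_u) - 1) < 1e-9, abs(.norm3(e_w) - 1) < 1e-9)
  .optimize_in_plane_hs(.hard_spheres(frame), start, e_u, e_w,
                        as.integer(n_iter), simplex_scale)
}

#' Trace the permeation pathway of a frame
#'
#' Sweeps the probe from the initial point in the channel direction and then
#' in the reverse direction, optimizing the probe position within each plane
#' normal to `e_v`.  Each step is seeded at the previous optimum displaced
#' by the probe step; a sweep terminates when the optimized probe radius
#' exceeds `stop_radius` (probe left the pore) or `max_steps` is reached.
#'
#' @param frame a `Frame` with vdW radii assigned.
#' @param config a [pathway_config()].
#' @return object of class `ProbeTrace`: list with `points` (n x 3 matrix,
#'   ascending along `e_v`), `radii`, `i0` (row index of the plane that
#'   contains the initial point), `p0`, `direction`, `probe_step`.
#' @export
find_pathway <- function(frame, config = pathway_config()) {
  stopifnot(inherits(frame, "Frame"), inherits(config, "PathwayConfig"))
  hs <- .hard_spheres(frame)
  e_v <- config$direction
  basis <- .plane_basis(e_v)
  dv <- config$probe_step
  scale <- 0.1 * dv
  n_it <- config$simplex_iter

  P0 <- config$init_point
  if (is.null(P0)) P0 <- colMeans(hs$xyz)

  first <- .optimize_in_plane_hs(hs, P0, basis$e_u, basis$e_w, n_it, scale)
  if (first$radius > config$stop_radius)
    stop("initial point outside pore (optimized probe radius ",
         sprintf("%.3f", first$radius), " nm exceeds stop_radius); ",
         "supply an init_point inside the channel")

  sweep <- function(from, dir_sign) {
    pts <- list(); radii <- numeric(0)
    P <- from
    for (i in seq_len(config$max_steps)) {
      seed <- P + dir_sign * dv * e_v
      opt <- .optimize_in_plane_hs(hs, seed, basis$e_u, basis$e_w, n_it, scale)
      if (opt$radius > config$stop_radius) return(list(points = pts, radii = radii))
      pts[[length(pts) + 1L]] <- opt$point
      radii <- c(radii, opt$radius)
      P <- opt$point
    }
    warning("pathway sweep hit max_steps before leaving the pore")
    list(points = pts, radii = radii)
  }

  fwd <- sweep(first$point, +1)
  bwd <- sweep(first$point, -1)

  pts <- rbind(
    if (length(bwd$points)) do.call(rbind, rev(bwd$points)),
    matrix(first$point, nrow = 1L),
    if (length(fwd$points)) do.call(rbind, fwd$points)
  )
  radii <- c(rev(bwd$radii), first$radius, fwd$radii)
  structure(list(points = pts, radii = radii,
                 i0 = length(bwd$radii) + 1L,
                 p0 = P0, direction = e_v, probe_step = dv),
            class = "ProbeTrace")
}

#' @export
print.ProbeTrace <- function(x, ...) {
  cat(sprintf("<ProbeTrace> %d probe points, step %.3g nm, min radius %.4f nm\n",
              nrow(x$points), x$probe_step, min(x$radii)))
  invisible(x)
}
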