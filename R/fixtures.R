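## Synthetic pore fixtures: pseudo-atom pores with analytic ground truth
## (true centerline, true radius profile, known pore-lining/facing residue
## sets) and Boltzmann-consistent water placement.  These make every module
## testable without external structures.

.fixture_axis_profile <- function(shape, p) {
  switch(shape,
    cylinder = function(z) rep(p$radius, length(z)),
    hourglass = function(z)
      p$radius - (p$radius - p$waist_radius) *
        exp(-z^2 / (2 * p$waist_width^2)),
    funnel = function(z)
      p$waist_radius + (p$radius - p$waist_radius) *
        (z + p$length / 2) / p$length,
    bent = function(z) rep(p$radius, length(z)),
    stop("unknown fixture shape: ", shape))
}

## wall radius including the flared mouths that let the probe sweep
## terminate cleanly (radius exceeds any sensible stop threshold)
.fixture_wall_radius <- function(a_fn, p) {
  function(z) {
    a <- a_fn(pmin(pmax(z, -p$length / 2), p$length / 2))
    out <- abs(z) - p$length / 2
    flare <- out > 0
    a[flare] <- a[flare] + (p$flare_radius - a[flare]) *
      pmin(out[flare] / p$flare_length, 1)
    a
  }
}

## local axis frame: center point, tangent, two normals, for an axial
## station z (straight shapes) or its arc equivalent (bent shape)
.fixture_frame_at <- function(shape, p, z) {
  if (shape == "bent") {
    theta <- asin(pmin(pmax(z / p$bend_radius, -1), 1))
    list(C = c(p$bend_radius * (1 - cos(theta)), 0, p$bend_radius * sin(theta)),
         Tg = c(sin(theta), 0, cos(theta)),
         M1 = c(cos(theta), 0, -sin(theta)),
         M2 = c(0, 1, 0))
  } else {
    list(C = c(0, 0, z), Tg = c(0, 0, 1),
         M1 = c(1, 0, 0), M2 = c(0, 1, 0))
  }
}

#' Generate a synthetic pore structure with analytic ground truth
#'
#' Builds pseudo-atom walls as dense rings of hard spheres at the wall
#' radius `a(z)`, with flared mouths beyond each end so a probe sweep
#' terminates cleanly.  Optionally decorates the wall with three-atom
#' amino-acid "residues" of known classification: pore-facing residues have
#' their side-chain atoms on the wall and the alpha-carbon behind it,
#' pore-lining-only residues the reverse, and decoy residues sit 1 nm
#' outside the wall.  Residues near the waist are named LEU (a hydrophobic
#' ring motif), others SER, decoys GLY, so hydrophobicity profiles have
#' meaningful ground truth.  The generated geometry is self-checked: the
#' probe radius at interior ring centers must equal `a - r_wall` to 1e-9.
#'
#' @param shape `"cylinder"`, `"hourglass"`, `"funnel"` or `"bent"`.
#' @param length pore length (nm).
#' @param radius wall radius of the cylindrical sections (nm).
#' @param waist_radius minimal wall radius (hourglass waist / funnel mouth).
#' @param waist_width Gaussian width of the hourglass waist (nm).
#' @param bend_radius radius of curvature of the bent pore's arc axis (nm).
#' @param wall_spacing pseudo-atom spacing along and around the wall (nm);
#'   0.05 nm keeps the discretization error of the radius profile below
#'   0.001 nm for a 0.5 nm pore.
#' @param wall_radius van der Waals radius of the wall pseudo-atoms (nm).
#' @param flare_length,flare_radius geometry of the flared mouths.
#' @param with_residues decorate with classifiable residues.
#' @return object of class `PoreFixture`: list with `frame` (vdW radii
#'   pre-assigned), `shape`, `params`, `oracle` (functions `axis_point(z)`,
#'   `wall(z)`, and `radius(z)`, the analytic probe radius on the axis:
#'   minimum distance to the continuum wall surface minus `wall_radius`,
#'   which for sloped walls is smaller than `a(z) - r_wall`; interior
#'   `range`), and
#'   ground-truth residue keys `facing_keys`, `lining_only_keys`,
#'   `decoy_keys`.
#' @export
make_pore <- function(shape = c("cylinder", "hourglass", "funnel", "bent"),
                      length = 4, radius = 0.5, waist_radius = 0.2,
                      waist_width = 0.5, bend_radius = 4,
                      wall_spacing = 0.05, wall_radius = 0.12,
                      flare_length = 0.6, flare_radius = 1.6,
                      with_residues = TRUE) {
  shape <- match.arg(shape)
  p <- list(length = length, radius = radius, waist_radius = waist_radius,
            waist_width = waist_width, bend_radius = bend_radius,
            wall_spacing = wall_spacing, wall_radius = wall_radius,
            flare_length = flare_length, flare_radius = flare_radius)
  a_interior <- .fixture_axis_profile(shape, p)
  a_wall <- .fixture_wall_radius(a_interior, p)
  if (any(a_interior(seq(-length / 2, length / 2, length.out = 201L)) <=
          wall_radius))
    stop("pore is closed: wall radius function must exceed the pseudo-atom radius")

  zs <- seq(-(length / 2 + flare_length), length / 2 + flare_length,
            by = wall_spacing)
  xs <- list(); nm <- list(); rs <- list(); rid <- list(); rnm <- list()
  add <- function(pts, names, resid, resname) {
    xs[[base::length(xs) + 1L]] <<- pts
    nm[[base::length(nm) + 1L]] <<- names
    rid[[base::length(rid) + 1L]] <<- rep(resid, nrow(pts))
    rnm[[base::length(rnm) + 1L]] <<- rep(resname, nrow(pts))
  }

  ## wall rings (one collective non-classifiable residue)
  rings <- list()
  for (z in zs) {
    fr <- .fixture_frame_at(shape, p, z)
    a <- a_wall(z)
    rings[[base::length(rings) + 1L]] <- c(fr$C, fr$Tg, a)
    n_at <- max(8L, ceiling(2 * pi * a / wall_spacing))
    phi <- 2 * pi * (seq_len(n_at) - 1L) / n_at
    ring <- matrix(fr$C, n_at, 3L, byrow = TRUE) +
      a * (cos(phi) %o% fr$M1 + sin(phi) %o% fr$M2)
    add(ring, rep("W", n_at), 9999L, "POR")
  }

  facing_keys <- character(0); lining_only_keys <- character(0)
  decoy_keys <- character(0)
  if (with_residues) {
    res_z <- seq(-length / 2 + 0.3, length / 2 - 0.3, by = 0.4)
    resid <- 0L
    for (z in res_z) {
      fr <- .fixture_frame_at(shape, p, z)
      a <- a_wall(z)
      resname <- if (shape == "hourglass" && abs(z) < p$waist_width)
        "LEU" else "SER"
      for (ang_i in 1:4) {
        phi <- (ang_i - 1L) * pi / 2
        u <- cos(phi) * fr$M1 + sin(phi) * fr$M2
        dphi <- wall_spacing / a
        u2 <- cos(phi + dphi) * fr$M1 + sin(phi + dphi) * fr$M2
        resid <- resid + 1L
        key <- paste0("A:", resid)
        if (ang_i %% 2L == 1L) {       # pore-facing: side chain on the wall
          pts <- rbind(fr$C + (a + 0.2) * u, fr$C + a * u, fr$C + a * u2)
          add(pts, c("CA", "CB", "CG"), resid, resname)
          facing_keys <- c(facing_keys, key)
        } else {                       # lining only: CA on the wall
          pts <- rbind(fr$C + a * u, fr$C + (a + 0.2) * u, fr$C + (a + 0.2) * u2)
          add(pts, c("CA", "CB", "CG"), resid, resname)
          lining_only_keys <- c(lining_only_keys, key)
        }
      }
    }
    ## decoys well outside the pore surface cutoff
    for (z in seq(-length / 2 + 0.4, length / 2 - 0.4, by = 0.8)) {
      fr <- .fixture_frame_at(shape, p, z)
      a <- a_wall(z)
      for (phi in c(pi / 4, 5 * pi / 4)) {
        u <- cos(phi) * fr$M1 + sin(phi) * fr$M2
        resid <- resid + 1L
        pts <- rbind(fr$C + (a + 1.0) * u, fr$C + (a + 1.1) * u)
        add(pts, c("CA", "CB"), resid, "GLY")
        decoy_keys <- c(decoy_keys, paste0("A:", resid))
      }
    }
  }

  pts <- do.call(rbind, xs)
  atoms <- data.frame(
    id = seq_len(nrow(pts)),
    name = unlist(nm),
    resname = unlist(rnm),
    resid = unlist(rid),
    chain = ifelse(unlist(rnm) == "POR", "X", "A"),
    element = ifelse(unlist(nm) == "W", "C", substr(unlist(nm), 1L, 1L)),
    x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
    vdw = wall_radius, is_water = FALSE,
    stringsAsFactors = FALSE
  )
  frame <- new_frame(atoms)

  rings <- do.call(rbind, rings)   # columns: center, tangent, wall radius

  ## minimum distance from a point to the wall modelled as continuum rings
  ## (exact for on-axis points, where the nearest azimuth carries an atom)
  ring_dist <- function(X) {
    d <- sweep(rings[, 1:3, drop = FALSE], 2L, X)
    d_ax <- rowSums(d * rings[, 4:6, drop = FALSE])
    d_perp2 <- pmax(rowSums(d * d) - d_ax^2, 0)
    min(sqrt(d_ax^2 + (rings[, 7L] - sqrt(d_perp2))^2))
  }

  ## continuum sloped-wall oracle: the probe touches the nearest point of
  ## the wall surface, which for steep walls is not in the probe's plane
  zf <- seq(min(zs), max(zs), by = wall_spacing / 8)
  surf <- t(vapply(zf, function(zz) {
    fr <- .fixture_frame_at(shape, p, zz)
    c(fr$C, fr$Tg, a_wall(zz))
  }, numeric(7L)))
  radius_oracle <- function(z) {
    vapply(z, function(zz) {
      X <- .fixture_frame_at(shape, p, zz)$C
      d <- sweep(surf[, 1:3, drop = FALSE], 2L, X)
      d_ax <- rowSums(d * surf[, 4:6, drop = FALSE])
      d_perp2 <- pmax(rowSums(d * d) - d_ax^2, 0)
      min(sqrt(d_ax^2 + (surf[, 7L] - sqrt(d_perp2))^2)) - wall_radius
    }, numeric(1L))
  }

  oracle <- list(
    axis_point = function(z) t(vapply(z, function(zz)
      .fixture_frame_at(shape, p, zz)$C, numeric(3L))),
    wall = a_wall,
    radius = radius_oracle,
    range = c(-length / 2, length / 2)
  )

  ## self-check: probe radius at interior ring centers must equal the
  ## analytic ring-geometry minimum (detects walls leaky to the probe)
  hs <- .hard_spheres(frame)
  z_chk <- zs[abs(zs) <= length / 2]
  z_chk <- z_chk[seq(1L, base::length(z_chk), by = 4L)]
  for (z in z_chk) {
    C <- .fixture_frame_at(shape, p, z)$C
    got <- .probe_radius_hs(C, hs)
    want <- ring_dist(C) - wall_radius
    if (abs(got - want) > 1e-9)
      stop(sprintf("fixture self-check failed at z = %.3f: probe radius %.6f, expected %.6f (wall spacing too coarse?)",
                   z, got, want))
  }
  ## leak check: near-wall off-axis points must not see more clearance than
  ## the continuum wall allows, which happens when the probe can slip
  ## between sparse wall atoms
  for (z in c(-length / 4, 0, length / 4)) {
    fr <- .fixture_frame_at(shape, p, z)
    a <- a_wall(z)
    for (psi in 2 * pi * (0:15) / 16) {
      X <- fr$C + 0.7 * a * (cos(psi) * fr$M1 + sin(psi) * fr$M2)
      got <- .probe_radius_hs(X, hs)
      want <- ring_dist(X) - wall_radius
      if (got > want + 0.05)
        stop(sprintf("fixture wall is leaky at z = %.3f: off-axis probe radius %.3f exceeds analytic %.3f; decrease wall_spacing",
                     z, got, want))
    }
  }

  structure(list(frame = frame, shape = shape, params = p, oracle = oracle,
                 facing_keys = facing_keys,
                 lining_only_keys = lining_only_keys,
                 decoy_keys = decoy_keys),
            class = "PoreFixture")
}

#' @export
print.PoreFixture <- function(x, ...) {
  cat(sprintf("<PoreFixture:%s> %d atoms, length %.2f nm, min true radius %.3f nm\n",
              x$shape, nrow(x$frame$atoms), x$params$length,
              min(x$oracle$radius(seq(x$oracle$range[1L], x$oracle$range[2L],
                                      length.out = 101L)))))
  invisible(x)
}

#' Place water molecules in a fixture pore by rejection sampling
#'
#' Samples water oxygen positions with linear density proportional to
#' `pi R(z)^2 exp(-G(z)/kT)` along the pore axis and uniformly over the
#' circular cross section, so that Boltzmann inversion of the resulting
#' density recovers the prescribed free-energy profile.  Placement is
#' deterministic given the seed.
#'
#' @param fixture a `PoreFixture`.
#' @param N number of waters to place.
#' @param target_G free-energy profile in kJ/mol as a function of the axial
#'   coordinate z (nm, 0 at the pore center); `NULL` means flat (G = 0).
#' @param temperature temperature in K.
#' @param seed RNG seed.
#' @param range axial range to populate; defaults to the pore interior.
#' @return a `Frame`: the fixture frame with HOH oxygen atoms appended.
#' @export
place_waters <- function(fixture, N, target_G = NULL, temperature = 298.15,
                         seed = 1L, range = NULL) {
  stopifnot(inherits(fixture, "PoreFixture"), N >= 1)
  if (is.null(range)) range <- fixture$oracle$range
  Gfun <- if (is.null(target_G)) function(z) rep(0, length(z)) else target_G
  beta <- 1 / (.kB * temperature)
  Rfun <- function(z) fixture$oracle$radius(z)
  zz <- seq(range[1L], range[2L], length.out = 512L)
  wmax <- max(Rfun(zz)^2 * exp(-beta * (Gfun(zz) - min(Gfun(zz)))))
  Gmin <- min(Gfun(zz))

  withr::with_seed(seed, {
    kept_z <- numeric(0)
    tries <- 0
    while (length(kept_z) < N) {
      n_draw <- max(1000L, ceiling((N - length(kept_z)) * 2.5))
      z <- runif(n_draw, range[1L], range[2L])
      w <- Rfun(z)^2 * exp(-beta * (Gfun(z) - Gmin)) / wmax
      keep <- runif(n_draw) < w
      kept_z <- c(kept_z, z[keep])
      tries <- tries + n_draw
      if (tries > 1000 && length(kept_z) / tries < 1e-4)
        stop("water placement acceptance rate below 1e-4; rescale target_G")
    }
    kept_z <- kept_z[seq_len(N)]
    rho <- Rfun(kept_z) * sqrt(runif(N))
    phi <- runif(N, 0, 2 * pi)
  })

  if (fixture$shape == "bent") {
    theta <- asin(kept_z / fixture$params$bend_radius)
    Rb <- fixture$params$bend_radius
    pos <- cbind(Rb * (1 - cos(theta)) + rho * cos(phi) * cos(theta),
                 rho * sin(phi),
                 Rb * sin(theta) - rho * cos(phi) * sin(theta))
  } else {
    pos <- cbind(rho * cos(phi), rho * sin(phi), kept_z)
  }

  a <- fixture$frame$atoms
  wat <- data.frame(
    id = max(a$id) + seq_len(N),
    name = "O", resname = "HOH",
    resid = seq_len(N) %% 10000L, chain = "S",
    element = "O",
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    vdw = NA_real_, is_water = TRUE,
    stringsAsFactors = FALSE
  )
  frame <- fixture$frame
  frame$atoms <- rbind(a, wat)
  frame
}
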