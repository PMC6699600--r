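## Trajectory analysis: per-frame composition of the pathway, centerline,
## coordinate, solvent and hydrophobicity modules, plus time aggregation.

#' Full analysis configuration
#'
#' Collects the tunable parameters of every analysis stage.  Defaults
#' follow the package's recommended settings: probe step 0.1 nm, 100
#' simplex iterations, stop radius 1 nm, KDE bandwidth 0.14 nm (~radius of
#' a water molecule), 298.15 K, pore-surface cutoff 0.75 nm, smoothing span
#' 0.225 nm.
#'
#' @param probe_step,direction,init_point,simplex_iter,stop_radius,max_steps
#'   see [pathway_config()].
#' @param bandwidth KDE bandwidth in nm, or `"amise"`.
#' @param temperature temperature in K for Boltzmann inversion.
#' @param r_thres pore-surface cutoff for pore-lining classification (nm).
#' @param lambda hydrophobicity smoothing span (nm).
#' @param scale hydrophobicity scale name (see [list_scales()]) or a
#'   `HydrophobicityScale`.
#' @param bulk_band bulk-water band(s) for free-energy normalization
#'   (`NULL`: outermost 10% of the s-range at each end).
#' @param dewet_fraction,dewet_min_length de-wetting detection thresholds.
#' @param vdw_table radius table for [assign_vdw_radii()].
#' @param mode `"full"` (solvent analysis when waters are present) or
#'   `"geometry"` (skip solvent analysis).
#' @return object of class `PoreConfig`.
#' @export
pore_config <- function(probe_step = 0.1, direction = c(0, 0, 1),
                        init_point = NULL, simplex_iter = 100L,
                        stop_radius = 1.0, max_steps = 10000L,
                        bandwidth = 0.14, temperature = 298.15,
                        r_thres = 0.75, lambda = 0.225,
                        scale = "wimley_white_interface",
                        bulk_band = NULL,
                        dewet_fraction = 0.2, dewet_min_length = 0.3,
                        vdw_table = NULL,
                        mode = c("full", "geometry")) {
  structure(list(probe_step = probe_step, direction = direction,
                 init_point = init_point, simplex_iter = simplex_iter,
                 stop_radius = stop_radius, max_steps = max_steps,
                 bandwidth = bandwidth, temperature = temperature,
                 r_thres = r_thres, lambda = lambda, scale = scale,
                 bulk_band = bulk_band, dewet_fraction = dewet_fraction,
                 dewet_min_length = dewet_min_length, vdw_table = vdw_table,
                 mode = match.arg(mode)),
            class = "PoreConfig")
}

#' Analyse a single frame
#'
#' Deterministic composition of the per-frame pipeline: pathway sweep,
#' centerline fit, radius profile, residue classification, hydrophobicity
#' profile, and (in `"full"` mode, when waters are present) water density,
#' number density, free energy and de-wetted segment detection.  All
#' profiles are evaluated on a common grid so trajectory frames can be
#' aggregated pointwise.
#'
#' @param frame a `Frame`.
#' @param config a [pore_config()].
#' @param grid optional common grid of pathway coordinates; default: uniform
#'   grid over this frame's pathway at the probe step.
#' @return object of class `PoreAnalysis`.
#' @export
analyze_frame <- function(frame, config = pore_config(), grid = NULL) {
  stopifnot(inherits(frame, "Frame"), inherits(config, "PoreConfig"))
  a <- frame$atoms
  if (anyNA(a$vdw[!a$is_water])) {
    tab <- config$vdw_table
    if (is.null(tab)) tab <- vdw_radius_table()
    frame <- assign_vdw_radii(frame, tab)
  }
  pc <- pathway_config(probe_step = config$probe_step,
                       direction = config$direction,
                       init_point = config$init_point,
                       simplex_iter = config$simplex_iter,
                       stop_radius = config$stop_radius,
                       max_steps = config$max_steps)
  trace <- find_pathway(frame, pc)
  spline <- fit_centerline(trace)
  radius <- radius_function(spline, trace, grid = grid)
  grid <- radius$s

  scale <- config$scale
  if (is.character(scale)) scale <- load_scale(scale)
  ann <- classify_residues(frame, spline, radius,
                           R_thres = config$r_thres, scale = scale)
  hyd <- tryCatch(
    hydrophobicity_profile(ann, grid, lambda = config$lambda),
    error = function(e) NULL)

  solvent <- NULL
  wat <- frame$atoms[frame$atoms$is_water & frame$atoms$element == "O", ,
                     drop = FALSE]
  if (config$mode == "full" && nrow(wat) > 0L) {
    s_w <- to_curvilinear(spline, cbind(wat$x, wat$y, wat$z))$s
    P <- kde_1d(s_w, bandwidth = config$bandwidth,
                range = c(grid[1L], grid[length(grid)]),
                spacing = (grid[length(grid)] - grid[1L]) / (length(grid) - 1L))
    n <- number_density(P, radius)
    G <- free_energy(P, radius, temperature = config$temperature,
                     bulk_band = config$bulk_band)
    attr(n, "bulk_density") <-
      mean(n$value[.band_mask(n$s, attr(G, "bulk_band"))])
    dew <- detect_dewetted(n, fraction_of_bulk = config$dewet_fraction,
                           min_length = config$dewet_min_length,
                           bulk_band = attr(G, "bulk_band"))
    solvent <- list(density = P, number_density = n, free_energy = G,
                    dewetted = dew, n_waters = nrow(wat))
  }

  structure(list(trace = trace, spline = spline, radius = radius,
                 annotations = ann, hydrophobicity = hyd,
                 solvent = solvent, time = frame$time),
            class = "PoreAnalysis")
}

#' @export
print.PoreAnalysis <- function(x, ...) {
  cat(sprintf("<PoreAnalysis> t = %g ps, min radius %.3f nm, %d pore-facing residues%s\n",
              x$time, min(x$radius$value), sum(x$annotations$pore_facing),
              if (is.null(x$solvent)) "" else
                sprintf(", %d waters", x$solvent$n_waters)))
  invisible(x)
}

.profile_series <- function(bundles, field, times) {
  profs <- lapply(bundles, function(b) {
    if (field %in% c("radius", "hydrophobicity")) b[[field]]
    else b$solvent[[field]]
  })
  if (any(vapply(profs, is.null, logical(1L)))) return(NULL)
  s <- profs[[1L]]$s
  vals <- do.call(rbind, lapply(profs, function(p) {
    if (length(p$s) != length(s) || max(abs(p$s - s)) > 1e-9)
      stop("internal error: frames do not share a common profile grid")
    p$value
  }))
  mean_v <- colMeans(vals, na.rm = TRUE)
  sd_v <- sqrt(colMeans(sweep(vals, 2L, mean_v)^2, na.rm = TRUE))  # population
  list(quantity = profs[[1L]]$quantity, s = s, values = vals,
       mean = mean_v, sd = sd_v,
       min = apply(vals, 2L, min, na.rm = TRUE),
       max = apply(vals, 2L, max, na.rm = TRUE),
       times = times)
}

#' Aggregate per-frame analyses over time
#'
#' Pointwise mean, population standard deviation, minimum and maximum of
#' each profile quantity over frames; time-averaged residue indicator
#' variables; and the water-density heatmap (frames x s-grid).
#'
#' @param bundles list of `PoreAnalysis` objects on a common grid.
#' @return object of class `PoreSeriesSet` with elements `series` (one
#'   summary per quantity), `annotations` (time-averaged indicators in
#'   `[0, 1]`), `heatmap`, `n_frames`, `times`.
#' @export
aggregate_analyses <- function(bundles) {
  stopifnot(length(bundles) >= 1L,
            all(vapply(bundles, inherits, logical(1L), "PoreAnalysis")))
  times <- vapply(bundles, function(b) b$time, numeric(1L))
  series <- Filter(Negate(is.null), list(
    radius = .profile_series(bundles, "radius", times),
    hydrophobicity = .profile_series(bundles, "hydrophobicity", times),
    density = .profile_series(bundles, "density", times),
    number_density = .profile_series(bundles, "number_density", times),
    free_energy = .profile_series(bundles, "free_energy", times)
  ))

  ## time-average the residue indicators
  anns <- lapply(bundles, function(b) b$annotations)
  key <- function(a) paste(a$chain, a$resid, a$resname)
  all_keys <- sort(unique(unlist(lapply(anns, key))))
  lining <- facing <- matrix(0, length(bundles), length(all_keys))
  for (i in seq_along(anns)) {
    hit <- match(key(anns[[i]]), all_keys)
    lining[i, hit] <- as.numeric(anns[[i]]$pore_lining)
    facing[i, hit] <- as.numeric(anns[[i]]$pore_facing)
  }
  ref <- anns[[1L]][match(all_keys, key(anns[[1L]])), ]
  annotations <- data.frame(
    chain = ref$chain, resid = ref$resid, resname = ref$resname,
    s_cog = ref$s_cog, rho_cog = ref$rho_cog,
    hydrophobicity = ref$hydrophobicity,
    pore_lining = colMeans(lining), pore_facing = colMeans(facing),
    stringsAsFactors = FALSE
  )

  heatmap <- if (!is.null(series$number_density))
    list(times = times, s = series$number_density$s,
         matrix = series$number_density$values)
  else NULL

  structure(list(series = series, annotations = annotations,
                 heatmap = heatmap, n_frames = length(bundles),
                 times = times),
            class = "PoreSeriesSet")
}

#' Analyse a trajectory of frames
#'
#' Runs [analyze_frame()] independently on every frame (the pathway sweep
#' is re-run per frame; the s = 0 convention at the initial point's
#' projection keeps profiles aligned across frames), resamples all profiles
#' onto the grid of the first frame, and aggregates.  No alignment to a
#' reference structure is performed: the curvilinear system is internal to
#' each frame.
#'
#' @param frames list of `Frame` objects (e.g. from [read_structure()]).
#' @param config a [pore_config()].
#' @return list with `bundles` (per-frame `PoreAnalysis`) and `summary`
#'   (a `PoreSeriesSet`).
#' @export
analyze_trajectory <- function(frames, config = pore_config()) {
  if (inherits(frames, "Frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  first <- analyze_frame(frames[[1L]], config)
  grid <- first$radius$s
  bundles <- c(list(first),
               lapply(frames[-1L], function(f)
                 analyze_frame(f, config, grid = grid)))
  list(bundles = bundles, summary = aggregate_analyses(bundles))
}
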