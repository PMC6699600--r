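# Shared fixtures and geometry runs, cached across test files (pathway
# sweeps are the expensive step; every result is deterministic).

.cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .cache)) assign(key, fn(), envir = .cache)
  get(key, envir = .cache)
}

fixture_pore <- function(shape, ...) {
  args <- list(...)
  key <- paste0("fx_", shape, "_", paste(names(args), unlist(args),
                                         sep = "=", collapse = "_"))
  cached(key, function() do.call(make_pore, c(list(shape = shape), args)))
}

# pathway + centerline + default-grid radius profile for a fixture
geometry_of <- function(shape, probe_step = 0.1, simplex_iter = 100L, ...) {
  args <- list(...)
  key <- paste0("geom_", shape, "_", probe_step, "_", simplex_iter, "_",
                paste(names(args), unlist(args), sep = "=", collapse = "_"))
  cached(key, function() {
    fx <- do.call(fixture_pore, c(list(shape = shape), args))
    tr <- find_pathway(fx$frame,
                       pathway_config(probe_step = probe_step,
                                      simplex_iter = simplex_iter))
    sp <- fit_centerline(tr)
    list(fixture = fx, trace = tr, spline = sp,
         radius = radius_function(sp, tr))
  })
}

# hand-built probe trace (bypasses the sweep) for analytic spline tests
synthetic_trace <- function(points, radii, probe_step = 0.1,
                            p0 = points[1L, ]) {
  structure(list(points = points, radii = radii, i0 = 1L, p0 = p0,
                 direction = c(0, 0, 1), probe_step = probe_step),
            class = "ProbeTrace")
}

# straight-line spline along z: the cylindrical-limit reference object
straight_spline <- function(z_from = 0, z_to = 4, radius = 0.38,
                            probe_step = 0.1) {
  z <- seq(z_from, z_to, by = probe_step)
  pts <- cbind(0, 0, z)
  fit_centerline(synthetic_trace(pts, rep(radius, length(z)),
                                 probe_step = probe_step))
}
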