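## Single-command entry point: run the full pipeline on a structure or
## multi-model trajectory and write a structured report bundle.

.profile_json <- function(p, dehydrated = NULL) {
  out <- list(quantity = p$quantity, units = switch(p$quantity,
    radius = "nm", hydrophobicity = "dimensionless", density = "nm^-1",
    number_density = "nm^-3", free_energy = "kJ/mol"),
    s = p$s, value = p$value)
  if (!is.null(dehydrated)) out$dehydrated <- dehydrated
  if (!is.null(attr(p, "bulk_density"))) {
    out$bulk_density <- attr(p, "bulk_density")
    out$value_relative_to_bulk <- p$value / attr(p, "bulk_density")
  }
  out
}

.series_json <- function(ss) {
  lapply(ss, function(x) list(
    quantity = x$quantity, s = x$s,
    bands = list(mean = x$mean, sd = x$sd, min = x$min, max = x$max)))
}

#' Run the full pore annotation pipeline
#'
#' Reads a structure (or multi-model trajectory), analyses every frame, and
#' writes a report bundle to `out_dir`: `report.json` (config echo, profiles,
#' time-series bands, residue annotations, de-wetted intervals),
#' `annotated.pdb` (pore-lining indicator in the occupancy column,
#' pore-facing in the B-factor column), `density_matrix.csv` (frames x
#' s-grid water number density, when waters are present), optionally
#' `surface.obj`, and `run.log`.
#'
#' @param input path to a PDB file, a `Frame`, or a list of frames.
#' @param out_dir output directory (created if needed).
#' @param config a [pore_config()]; its `mode` selects `"geometry"` (no
#'   solvent analysis) or `"full"`.
#' @param mesh also write the extruded pore surface as Wavefront OBJ.
#' @return (invisibly) list with the analysis results and output paths.
#' @export
run_porescope <- function(input, out_dir, config = pore_config(),
                          mesh = FALSE) {
  t_start <- Sys.time()
  frames <- if (inherits(input, "Frame")) list(input)
            else if (is.list(input)) input
            else read_structure(input)
  res <- analyze_trajectory(frames, config)
  b1 <- res$bundles[[1L]]
  summ <- res$summary

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("porescope %s", as.character(utils::packageVersion("porescope"))),
    sprintf("frames analysed: %d", summ$n_frames),
    sprintf("mode: %s", config$mode))

  report <- list(
    schema_version = "1.0",
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1L))],
    n_frames = summ$n_frames,
    profiles = Filter(Negate(is.null), list(
      radius = .profile_json(b1$radius),
      hydrophobicity = if (!is.null(b1$hydrophobicity))
        .profile_json(b1$hydrophobicity),
      density = if (!is.null(b1$solvent)) .profile_json(b1$solvent$density),
      number_density = if (!is.null(b1$solvent))
        .profile_json(b1$solvent$number_density),
      free_energy = if (!is.null(b1$solvent))
        .profile_json(b1$solvent$free_energy,
                      attr(b1$solvent$free_energy, "dehydrated"))
    )),
    series = .series_json(summ$series),
    annotations = summ$annotations,
    dewetted_intervals = if (!is.null(b1$solvent)) b1$solvent$dewetted
                         else list()
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  pdb_path <- file.path(out_dir, "annotated.pdb")
  write_annotated_pdb(frames[[1L]], summ$annotations, path = pdb_path)

  csv_path <- NULL
  if (!is.null(summ$heatmap)) {
    csv_path <- file.path(out_dir, "density_matrix.csv")
    mat <- summ$heatmap$matrix
    colnames(mat) <- sprintf("s=%.4f", summ$heatmap$s)
    utils::write.csv(cbind(time_ps = summ$heatmap$times, mat), csv_path,
                     row.names = FALSE)
  }

  obj_path <- NULL
  if (mesh) {
    obj_path <- file.path(out_dir, "surface.obj")
    write_obj(extrude_surface(b1$spline, b1$radius), obj_path)
  }

  log_lines <- c(log_lines,
                 sprintf("elapsed: %.2f s",
                         as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(bundles = res$bundles, summary = summ,
                 paths = Filter(Negate(is.null),
                                list(report = report_path, pdb = pdb_path,
                                     density_matrix = csv_path,
                                     surface = obj_path))))
}
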