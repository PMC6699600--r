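## Structure I/O: fixed-width PDB reading/writing, frames, vdW radius tables.
## Internal unit is nm; PDB files carry Angstroem.

#' Residue names recognized as water
#'
#' Default set of residue names used to flag solvent water during PDB
#' parsing.  Dialects differ between crystallographic and MD-derived files.
#' @export
WATER_RESIDUE_NAMES <- c("HOH", "SOL", "WAT", "TIP3", "TIP3P", "TIP", "W")

#' Construct a structural frame
#'
#' A frame is one structural configuration: an atom table plus a time stamp
#' (ps; 0 for static structures) and an optional box.
#'
#' @param atoms data.frame with columns `id`, `name`, `resname`, `resid`,
#'   `chain`, `element`, `x`, `y`, `z` (nm), `vdw` (nm, `NA` until assigned)
#'   and `is_water` (logical).
#' @param time time in ps.
#' @param box optional numeric length-3 box vector (nm).
#' @return object of class `Frame`.
#' @export
new_frame <- function(atoms, time = 0, box = NULL) {
  required <- c("id", "name", "resname", "resid", "chain", "element",
                "x", "y", "z", "vdw", "is_water")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!any(!atoms$is_water))
    stop("frame must contain at least one non-water atom")
  if (anyDuplicated(atoms$id))
    stop("atom ids must be unique within a frame")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("atom positions must be finite")
  structure(list(atoms = atoms, time = time, box = box), class = "Frame")
}

#' @export
print.Frame <- function(x, ...) {
  nw <- sum(x$atoms$is_water)
  cat(sprintf("<Frame> %d atoms (%d water), t = %g ps\n",
              nrow(x$atoms), nw, x$time))
  invisible(x)
}

.substr_trim <- function(lines, from, to) trimws(substr(lines, from, to))

.parse_num_field <- function(txt, lines_idx, what) {
  out <- suppressWarnings(as.numeric(txt))
  bad <- which(!is.finite(out) & nzchar(txt))
  bad2 <- which(!nzchar(txt))
  bad <- sort(c(bad, bad2))
  if (length(bad))
    stop(sprintf("unparseable %s in ATOM/HETATM record at line %d",
                 what, lines_idx[bad[1L]]))
  out
}

.guess_element <- function(name) {
  # strip digits and primes, use leading character(s); hydrogens may be
  # written 1HB etc.
  core <- gsub("[0-9'\"]", "", name)
  ifelse(core == "", "X",
         ifelse(substr(core, 1L, 1L) == "H", "H", substr(core, 1L, 1L)))
}

#' Read a PDB structure into frames
#'
#' Parses `ATOM`/`HETATM`/`MODEL`/`ENDMDL` records of a PDB file.  One
#' `Frame` is returned per `MODEL` block; files without `MODEL` records
#' yield a single frame.  Coordinates are converted from Angstroem to nm.
#' Waters are identified by residue name.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param water_names residue names treated as water.
#' @param dt time step in ps assigned to successive models.
#' @return list of [new_frame()] objects.
#' @export
read_structure <- function(pdb, water_names = WATER_RESIDUE_NAMES, dt = 1) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb))
    readLines(pdb) else unlist(strsplit(pdb, "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records found: empty input")

  model_of <- cumsum(is_model)
  if (!any(is_model)) model_of <- rep(1L, length(lines))
  model_of[model_of == 0L] <- 1L

  idx <- which(is_atom)
  al <- lines[idx]
  # pad short lines so fixed-width extraction is safe
  al <- formatC(al, width = -80)
  atoms <- data.frame(
    id       = as.integer(.parse_num_field(.substr_trim(al, 7, 11), idx, "serial")),
    name     = .substr_trim(al, 13, 16),
    resname  = .substr_trim(al, 18, 20),
    resid    = as.integer(.parse_num_field(.substr_trim(al, 23, 26), idx, "residue number")),
    chain    = substr(al, 22, 22),
    element  = .substr_trim(al, 77, 78),
    x        = .parse_num_field(.substr_trim(al, 31, 38), idx, "x coordinate") / 10,
    y        = .parse_num_field(.substr_trim(al, 39, 46), idx, "y coordinate") / 10,
    z        = .parse_num_field(.substr_trim(al, 47, 54), idx, "z coordinate") / 10,
    stringsAsFactors = FALSE
  )
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- .guess_element(atoms$name[noel])
  atoms$vdw <- NA_real_
  atoms$is_water <- atoms$resname %in% water_names

  groups <- split(seq_along(idx), model_of[idx])
  frames <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    a <- atoms[groups[[k]], , drop = FALSE]
    rownames(a) <- NULL
    frames[[k]] <- new_frame(a, time = (k - 1L) * dt)
  }
  frames
}

.format_atom_name <- function(name, element) {
  # names start in column 14 when the element symbol has one character and
  # the name fits in three characters; otherwise column 13
  ifelse(nchar(name) < 4L & nchar(element) == 1L,
         sprintf(" %-3s", name), sprintf("%-4s", name))
}

.format_atom_lines <- function(atoms, occ, bfac) {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$is_water, "HETATM", "ATOM"),
          atoms$id %% 100000L,
          .format_atom_name(atoms$name, atoms$element), "",
          atoms$resname, atoms$chain, atoms$resid %% 10000L, "",
          atoms$x * 10, atoms$y * 10, atoms$z * 10,
          occ, bfac, toupper(atoms$element))
}

#' Write frames as PDB text
#'
#' Multi-frame input is written as `MODEL`/`ENDMDL` blocks.  Coordinates are
#' converted from nm to Angstroem; occupancy and B-factor are written as
#' 1.00 and 0.00.
#'
#' @param frames a `Frame` or list of frames.
#' @param path optional output file; if `NULL` the text is returned.
#' @return character vector of PDB lines (invisibly when `path` is given).
#' @export
write_structure <- function(frames, path = NULL) {
  if (inherits(frames, "Frame")) frames <- list(frames)
  multi <- length(frames) > 1L
  out <- character(0)
  for (k in seq_along(frames)) {
    a <- frames[[k]]$atoms
    body <- .format_atom_lines(a, rep(1, nrow(a)), rep(0, nrow(a)))
    if (multi) body <- c(sprintf("MODEL     %4d", k), body, "ENDMDL")
    out <- c(out, body)
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Van der Waals radius table
#'
#' Lookup table mapping elements (and optionally residue/atom-name pairs) to
#' hard-sphere radii in nm.  The bundled default is a standard atomic
#' radius set (Bondi-type radii); it is deliberately swappable because
#' published pore-annotation tools do not agree on a single set.
#'
#' @param elements named numeric vector of radii (nm) keyed by element symbol.
#' @param overrides optional named numeric vector keyed as `"RES:NAME"`.
#' @param default fallback radius in nm, or `NA` to make unknown elements an
#'   error.
#' @return object of class `VdwRadiusTable`.
#' @export
vdw_table <- function(elements, overrides = NULL, default = NA_real_) {
  radii <- c(elements, overrides, if (is.finite(default)) default)
  if (any(radii <= 0.05 | radii >= 0.35))
    stop("vdW radii must lie in (0.05, 0.35) nm")
  structure(list(elements = elements, overrides = overrides,
                 default = default), class = "VdwRadiusTable")
}

#' @rdname vdw_table
#' @param file path to a two-column (element, radius_nm) whitespace table;
#'   defaults to the bundled set.
#' @export
vdw_radius_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "vdw_radii.tsv", package = "porescope")
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  vdw_table(stats::setNames(tab$radius_nm, tab$element), default = 0.17)
}

#' Assign van der Waals radii to a frame
#'
#' Lookup precedence: (residue name, atom name) override, then element, then
#' the table default.  Waters are excluded from the hard-sphere set and keep
#' `NA` radii.
#'
#' @param frame a `Frame`.
#' @param table a [vdw_table()].
#' @return the frame with the `vdw` column filled for non-water atoms.
#' @export
assign_vdw_radii <- function(frame, table = vdw_radius_table()) {
  stopifnot(inherits(frame, "Frame"), inherits(table, "VdwRadiusTable"))
  a <- frame$atoms
  sel <- !a$is_water
  r <- rep(NA_real_, nrow(a))
  if (!is.null(table$overrides)) {
    key <- paste0(a$resname, ":", a$name)
    hit <- match(key, names(table$overrides))
    r[!is.na(hit)] <- table$overrides[hit[!is.na(hit)]]
  }
  el <- match(a$element, names(table$elements))
  fill <- is.na(r) & !is.na(el)
  r[fill] <- table$elements[el[fill]]
  if (is.finite(table$default)) r[is.na(r)] <- table$default
  if (any(sel & is.na(r))) {
    off <- a[sel & is.na(r), ]
    stop("no vdW radius for atoms (element unknown, no default): ",
         paste(utils::head(unique(paste0(off$element, "/", off$name)), 10L),
               collapse = ", "))
  }
  a$vdw[sel] <- r[sel]
  frame$atoms <- a
  frame
}

#' Write a residue-annotated PDB
#'
#' Writes the pore-lining indicator to the occupancy column (55-60) and the
#' pore-facing indicator to the B-factor column (61-66).  For trajectories
#' the indicators are time averages in `[0, 1]`.  Residues absent from the
#' annotation table default to 0 with a warning.
#'
#' @param frame a `Frame`.
#' @param annotations data.frame with columns `chain`, `resid`,
#'   `pore_lining`, `pore_facing` (values in `[0, 1]`).
#' @param path optional output file.
#' @return character vector of PDB lines (invisibly when `path` is given).
#' @export
write_annotated_pdb <- function(frame, annotations, path = NULL) {
  stopifnot(inherits(frame, "Frame"))
  a <- frame$atoms
  key_atoms <- paste(a$chain, a$resid)
  key_ann <- paste(annotations$chain, annotations$resid)
  hit <- match(key_atoms, key_ann)
  miss <- is.na(hit) & !a$is_water
  if (any(miss))
    warning(sprintf("%d residues lack annotations; indicators set to 0",
                    length(unique(key_atoms[miss]))))
  occ <- ifelse(is.na(hit), 0, annotations$pore_lining[hit])
  bf <- ifelse(is.na(hit), 0, annotations$pore_facing[hit])
  out <- c(.format_atom_lines(a, occ, bf), "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
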