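## Hydrophobicity: pore-lining / pore-facing residue classification,
## normalized amino-acid hydrophobicity scales, and the kernel-smoothed
## hydrophobicity profile along the pathway.

#' List bundled hydrophobicity scales
#'
#' @return character vector of scale names accepted by [load_scale()].
#' @export
list_scales <- function() {
  dir <- system.file("extdata", "scales", package = "porescope")
  sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$"))
}

#' Load a bundled hydrophobicity scale
#'
#' Bundled scales (raw literature values, kcal/mol or index units):
#' `wimley_white_interface` (default elsewhere; water-to-POPC-interface
#' transfer free energies), `wimley_white_octanol`, `kyte_doolittle`
#' (hydropathy index), and `hessa` (translocon apparent transfer free
#' energies).  Each file records its orientation; transfer-free-energy
#' scales have hydrophobic residues at negative values and are flipped
#' during normalization.
#'
#' @param name scale name from [list_scales()], or path to a custom
#'   two-column (residue, value) file with an optional
#'   `# higher_is_hydrophobic: true|false` header line.
#' @return a normalized `HydrophobicityScale` (see [normalize_scale()]).
#' @export
load_scale <- function(name = "wimley_white_interface") {
  path <- if (file.exists(name)) name
          else system.file("extdata", "scales", paste0(name, ".tsv"),
                           package = "porescope")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown hydrophobicity scale: ", name,
         " (bundled: ", paste(list_scales(), collapse = ", "), ")")
  hdr <- readLines(path, n = 5L)
  flag <- grep("higher_is_hydrophobic", hdr, value = TRUE)
  higher <- if (length(flag)) grepl("true", flag, ignore.case = TRUE) else TRUE
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  raw <- stats::setNames(tab$value, toupper(tab$residue))
  normalize_scale(raw, higher_is_hydrophobic = higher,
                  name = sub("\\.tsv$", "", basename(path)))
}

#' Normalize a hydrophobicity scale to [-1, +1]
#'
#' Orients the scale so larger means more hydrophobic (flipping
#' transfer-free-energy scales), then rescales two-sidedly: positive values
#' are divided by the maximum positive value and negative values by the
#' magnitude of the minimum, so the most hydrophobic residue maps to +1, the
#' most hydrophilic to -1, and the natural zero is preserved.
#'
#' @param raw named numeric vector, residue 3-letter code to value.
#' @param higher_is_hydrophobic orientation of `raw`.
#' @param name scale label.
#' @return object of class `HydrophobicityScale` with elements `name`,
#'   `raw`, `normalized`.
#' @export
normalize_scale <- function(raw, higher_is_hydrophobic = TRUE, name = "custom") {
  if (!length(raw)) stop("empty hydrophobicity scale")
  v <- if (higher_is_hydrophobic) raw else -raw
  if (all(v == 0)) stop("hydrophobicity scale is identically zero")
  norm <- v
  if (any(v > 0)) norm[v > 0] <- v[v > 0] / max(v[v > 0])
  if (any(v < 0)) norm[v < 0] <- v[v < 0] / abs(min(v[v < 0]))
  structure(list(name = name, raw = raw, normalized = norm,
                 higher_is_hydrophobic = higher_is_hydrophobic),
            class = "HydrophobicityScale")
}

#' @export
print.HydrophobicityScale <- function(x, ...) {
  cat(sprintf("<HydrophobicityScale:%s> %d residues, normalized range [%.3g, %.3g]\n",
              x$name, length(x$normalized), min(x$normalized), max(x$normalized)))
  invisible(x)
}

#' Classify pore-lining and pore-facing residues
#'
#' A residue is pore-lining if its center of geometry lies within `R_thres`
#' of the pore surface, i.e. `rho_cog <= R(s_cog) + R_thres` (inclusive).
#' A pore-lining residue is pore-facing if its alpha-carbon is at least as
#' far from the centerline as its center of geometry (side chain points
#' inward), `rho_ca >= rho_cog` (inclusive).  Centers of geometry are taken
#' over all non-hydrogen atoms of the residue.  Residues without an
#' alpha-carbon are excluded with a warning.
#'
#' @param frame a `Frame`.
#' @param spline a `CenterlineSpline` for this frame.
#' @param R radius `Profile` for this frame.
#' @param R_thres pore-surface cutoff in nm; ~0.75 nm suits an alpha-helical
#'   pore.
#' @param scale optional `HydrophobicityScale` used to attach normalized
#'   hydrophobicity values.
#' @return data.frame with one row per residue: `chain`, `resid`, `resname`,
#'   `s_cog`, `rho_cog`, `s_ca`, `rho_ca`, `pore_lining`, `pore_facing`,
#'   `hydrophobicity`.
#' @export
classify_residues <- function(frame, spline, R, R_thres = 0.75, scale = NULL) {
  stopifnot(inherits(frame, "Frame"), inherits(spline, "CenterlineSpline"),
            inherits(R, "Profile"), R_thres > 0)
  a <- frame$atoms[!frame$atoms$is_water, , drop = FALSE]
  key <- paste(a$chain, a$resid, a$resname, sep = "\r")
  grp <- split(seq_len(nrow(a)), key)

  has_ca <- vapply(grp, function(i) any(a$name[i] == "CA"), logical(1L))
  if (any(!has_ca)) {
    warning(sprintf("%d residues without alpha-carbon excluded from classification",
                    sum(!has_ca)))
    grp <- grp[has_ca]
  }
  if (!length(grp)) stop("no residues with alpha-carbons to classify")

  cog <- t(vapply(grp, function(i) {
    j <- i[a$element[i] != "H"]
    if (!length(j)) j <- i
    c(mean(a$x[j]), mean(a$y[j]), mean(a$z[j]))
  }, numeric(3L)))
  ca <- t(vapply(grp, function(i) {
    j <- i[a$name[i] == "CA"][1L]
    c(a$x[j], a$y[j], a$z[j])
  }, numeric(3L)))

  cc <- to_curvilinear(spline, cog)
  cv <- to_curvilinear(spline, ca)
  R_at <- profile_eval(R, cc$s)
  lining <- cc$rho <= R_at + R_thres
  facing <- lining & (cv$rho >= cc$rho)

  parts <- strsplit(names(grp), "\r", fixed = TRUE)
  resname <- vapply(parts, `[`, character(1L), 3L)
  hydro <- rep(NA_real_, length(grp))
  if (!is.null(scale)) {
    stopifnot(inherits(scale, "HydrophobicityScale"))
    hit <- match(toupper(resname), names(scale$normalized))
    hydro[!is.na(hit)] <- scale$normalized[hit[!is.na(hit)]]
  }
  out <- data.frame(
    chain = vapply(parts, `[`, character(1L), 1L),
    resid = as.integer(vapply(parts, `[`, character(1L), 2L)),
    resname = resname,
    s_cog = cc$s, rho_cog = cc$rho,
    s_ca = cv$s, rho_ca = cv$rho,
    pore_lining = lining, pore_facing = facing,
    hydrophobicity = hydro,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$chain, out$resid), ]
}

#' Kernel-smoothed hydrophobicity profile
#'
#' Nadaraya-Watson kernel-weighted average of the normalized hydrophobicity
#' values of pore-facing residues along the pathway,
#' `H(s) = sum_i K(s - s_i) H_i / (w0 + sum_i K(s - s_i))` with unnormalized
#' Gaussian kernel `K(d) = exp(-d^2 / (2 lambda^2))`.  The constant
#' pseudo-weight `w0 = exp(-9/2)` (the kernel at 3 lambda) regularizes the
#' denominator so the profile decays to zero far from any residue instead of
#' locking onto the nearest residue's value.
#'
#' @param annotations output of [classify_residues()]; only rows with
#'   `pore_facing = TRUE` and a finite hydrophobicity are used.
#' @param grid evaluation grid of pathway coordinates (nm), or a radius
#'   `Profile` whose grid is reused.
#' @param lambda smoothing span in nm.  An alpha-helix rises ~0.15 nm per
#'   residue and roughly every third residue faces the pore, so 0.225 nm
#'   (kernel width ~0.45 nm) matches the axial spacing of pore-facing
#'   residues.
#' @return a `Profile` of quantity `"hydrophobicity"`.
#' @export
hydrophobicity_profile <- function(annotations, grid, lambda = 0.225) {
  stopifnot(lambda > 0)
  if (inherits(grid, "Profile")) grid <- grid$s
  use <- annotations$pore_facing & is.finite(annotations$hydrophobicity)
  if (!any(use))
    stop("no pore-facing residues with hydrophobicity values")
  si <- annotations$s_cog[use]
  Hi <- annotations$hydrophobicity[use]
  w0 <- exp(-4.5)
  vals <- vapply(grid, function(g) {
    k <- exp(-(g - si)^2 / (2 * lambda^2))
    sum(k * Hi) / (w0 + sum(k))
  }, numeric(1L))
  new_profile(grid, vals, quantity = "hydrophobicity")
}

#' Liquid-vapor free-energy difference of a cylindrical pore
#'
#' Macroscopic estimate of the grand-potential difference between the vapor
#' (de-wetted) and liquid (hydrated) states of a cylindrical nanopore:
#' `2 pi R gamma_lv (R + L cos(theta_e))`.  Positive values favor the liquid
#' state; hydrophobic walls (large contact angle) drive it negative for long
#' narrow pores.
#'
#' @param R pore radius (nm).
#' @param L pore length (nm).
#' @param gamma_lv liquid-vapor surface tension of water (kJ/mol/nm^2).
#' @param theta_e equilibrium contact angle (radians).
#' @return free-energy difference in kJ/mol.
#' @export
dewetting_free_energy <- function(R, L, gamma_lv, theta_e) {
  stopifnot(R > 0, L > 0)
  2 * pi * R * gamma_lv * (R + L * cos(theta_e))
}
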