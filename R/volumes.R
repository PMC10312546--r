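## Per-atom "adjusted" excluded volumes.
##
## Each atom's displaced-solvent volume is its van der Waals sphere clipped by
## the sphere-sphere intersection planes of overlapping neighbors, evaluated
## on a fine per-atom Boolean voxel grid. Clipping removes the density shared
## with covalently bonded neighbors, so the summed adjusted volumes estimate
## the total displaced bulk solvent without a global expansion factor.

.atom_radii <- function(atoms, radii = NULL) {
  if (is.null(radii)) radii <- vdw_radius(atoms$element)
  if (length(radii) != nrow(atoms)) stop("one radius per atom required", call. = FALSE)
  if (any(radii <= 0)) stop("non-positive van der Waals radius", call. = FALSE)
  radii
}

#' Adjusted excluded volume of one atom
#'
#' Implements the four-step fine-grid clipping: (1) mark voxels of a miniature
#' Boolean grid inside the primary atom's van der Waals sphere; (2) select
#' neighbors within `neighbor_cutoff` (center-to-center); (3) for each
#' overlapping neighbor, clip voxels beyond the radical plane of the
#' sphere-sphere intersection (the plane of the intersection circle when the
#' spheres overlap, extended continuously otherwise); (4) return the volume of
#' the remaining voxels. A voxel belongs to the sphere when its center does.
#'
#' @param atoms Atom data.frame.
#' @param index Index of the primary atom.
#' @param radii Optional per-atom radii (Angstrom); defaults to Bondi values.
#' @param fine_grid_n Voxels per side of the miniature grid (default 16, about
#'   0.2 A voxels for carbon).
#' @param neighbor_cutoff Neighbor search radius in Angstrom (default 5).
#' @return List of class `adjusted_volume`: `atom_index`, `volume` (cubic
#'   Angstrom), `source = "explicit-calculation"`.
#' @examples
#' a <- atom_table(0, 0, 0, "C")
#' unique_volume(a, 1)$volume   # ~ (4/3) pi 1.7^3 = 20.58
#' @export
unique_volume <- function(atoms, index, radii = NULL, fine_grid_n = 16,
                          neighbor_cutoff = 5.0) {
  stopifnot(index >= 1, index <= nrow(atoms))
  radii <- .atom_radii(atoms, radii)
  xyz <- atom_coords(atoms)
  c1 <- xyz[index, ]
  r1 <- radii[index]

  n <- as.integer(fine_grid_n)
  h <- 2 * r1 / n
  ax <- -r1 + (seq_len(n) - 0.5) * h          # voxel centers, atom at origin
  vx <- rep(ax, times = n * n)
  vy <- rep(rep(ax, each = n), times = n)
  vz <- rep(ax, each = n * n)
  mask <- (vx * vx + vy * vy + vz * vz) <= r1 * r1

  d2 <- colSums((t(xyz) - c1)^2)
  nbr <- which(d2 <= neighbor_cutoff^2 & seq_len(nrow(atoms)) != index)
  for (j in nbr) {
    d <- sqrt(d2[j])
    if (d < 1e-6) {
      warning("atoms ", index, " and ", j, " share coordinates; neighbor skipped",
              call. = FALSE)
      next
    }
    if (d >= r1 + radii[j]) next              # no overlap, plane beyond sphere
    t_plane <- (d * d + r1 * r1 - radii[j]^2) / (2 * d)
    u <- (xyz[j, ] - c1) / d
    proj <- vx * u[1] + vy * u[2] + vz * u[3]
    mask <- mask & (proj <= t_plane)
    if (!any(mask)) break
  }
  vol <- sum(mask) * h^3
  if (vol <= 0)
    warning("atom ", index, " fully engulfed by neighbors; adjusted volume is zero",
            call. = FALSE)
  structure(list(atom_index = index, volume = vol, source = "explicit-calculation"),
            class = "adjusted_volume")
}

#' Adjusted volumes for every atom of a model
#'
#' @inheritParams unique_volume
#' @return data.frame with columns `atom_index`, `volume`, `source`.
#' @export
unique_volumes <- function(atoms, radii = NULL, fine_grid_n = 16,
                           neighbor_cutoff = 5.0) {
  radii <- .atom_radii(atoms, radii)
  vols <- vapply(seq_len(nrow(atoms)), function(i) {
    unique_volume(atoms, i, radii, fine_grid_n, neighbor_cutoff)$volume
  }, numeric(1))
  data.frame(atom_index = seq_len(nrow(atoms)), volume = vols,
             source = "explicit-calculation", stringsAsFactors = FALSE)
}

#' Build a volume dictionary from a model corpus
#'
#' Averages explicitly calculated adjusted volumes per (residue name, atom
#' name) key over a corpus of models with explicit hydrogens. The same atom
#' name in different residue types gets distinct entries, since mean adjusted
#' volumes differ across residues even for identical names.
#'
#' @param models List of atom data.frames.
#' @param fine_grid_n,neighbor_cutoff Passed to [unique_volume()].
#' @return Object of class `volume_dictionary`: data.frame with columns
#'   `residue_name`, `atom_name`, `volume`, `count`, with provenance metadata
#'   in attributes.
#' @export
build_volume_dictionary <- function(models, fine_grid_n = 16, neighbor_cutoff = 5.0) {
  if (length(models) == 0) stop("empty model corpus", call. = FALSE)
  keys <- character(0); vols <- numeric(0)
  for (m in models) {
    v <- unique_volumes(m, fine_grid_n = fine_grid_n, neighbor_cutoff = neighbor_cutoff)
    keys <- c(keys, paste(trimws(m$residue_name), trimws(m$atom_name), sep = "|"))
    vols <- c(vols, v$volume)
  }
  mean_v <- tapply(vols, keys, mean)
  cnt <- tapply(vols, keys, length)
  parts <- strsplit(names(mean_v), "|", fixed = TRUE)
  dict <- data.frame(residue_name = vapply(parts, `[`, character(1), 1),
                     atom_name = vapply(parts, `[`, character(1), 2),
                     volume = as.numeric(mean_v), count = as.integer(cnt),
                     stringsAsFactors = FALSE)
  rownames(dict) <- NULL
  attr(dict, "n_models") <- length(models)
  attr(dict, "date") <- format(Sys.Date())
  class(dict) <- c("volume_dictionary", "data.frame")
  dict
}

#' Write / read a volume dictionary as tab-separated text
#'
#' @param dict A `volume_dictionary`.
#' @param path File path.
#' @return `write_volume_dictionary` returns `path` invisibly;
#'   `read_volume_dictionary` returns a `volume_dictionary`.
#' @export
write_volume_dictionary <- function(dict, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# adjusted-volume dictionary; corpus of ",
                      attr(dict, "n_models"), " model(s), ", attr(dict, "date")),
               "residue_name\tatom_name\tvolume\tcount"), con)
  writeLines(sprintf("%s\t%s\t%.6f\t%d", dict$residue_name, dict$atom_name,
                     dict$volume, dict$count), con)
  invisible(path)
}

#' @rdname write_volume_dictionary
#' @export
read_volume_dictionary <- function(path) {
  dict <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
  class(dict) <- c("volume_dictionary", "data.frame")
  dict
}

#' Per-atom volumes with dictionary lookup and explicit fallback
#'
#' Looks up each atom's (residue name, atom name) in a volume dictionary and
#' falls back to the explicit fine-grid calculation for atoms not found.
#'
#' @param atoms Atom data.frame.
#' @param dictionary Optional `volume_dictionary`; `NULL` forces explicit
#'   calculation for every atom.
#' @inheritParams unique_volume
#' @return data.frame with columns `atom_index`, `volume`, `source`.
#' @export
volumes_for_model <- function(atoms, dictionary = NULL, radii = NULL,
                              fine_grid_n = 16, neighbor_cutoff = 5.0) {
  n <- nrow(atoms)
  vol <- rep(NA_real_, n)
  src <- rep("explicit-calculation", n)
  if (!is.null(dictionary)) {
    key <- paste(trimws(atoms$residue_name), trimws(atoms$atom_name), sep = "|")
    dkey <- paste(dictionary$residue_name, dictionary$atom_name, sep = "|")
    hit <- match(key, dkey)
    vol[!is.na(hit)] <- dictionary$volume[hit[!is.na(hit)]]
    src[!is.na(hit)] <- "dictionary-lookup"
  }
  todo <- which(is.na(vol))
  if (length(todo) > 0) {
    radii <- .atom_radii(atoms, radii)
    for (i in todo)
      vol[i] <- unique_volume(atoms, i, radii, fine_grid_n, neighbor_cutoff)$volume
  }
  if (!is.null(dictionary))
    message("volumes_for_model: ", n - length(todo), " dictionary hit(s), ",
            length(todo), " explicit calculation(s)")
  data.frame(atom_index = seq_len(n), volume = vol, source = src,
             stringsAsFactors = FALSE)
}

#' Apply per-element volume scale factors
#'
#' Multiplies each adjusted volume by a per-element factor correcting for
#' solvent-inaccessible voids between atoms. Elements without a factor are
#' left unchanged.
#'
#' @param volumes data.frame from [unique_volumes()] or [volumes_for_model()].
#' @param elements Per-atom element symbols (same order as `volumes`).
#' @param scale Named numeric vector of positive factors, e.g.
#'   `c(H = 1.05, C = 1.1)`.
#' @return The `volumes` data.frame with scaled volumes.
#' @export
apply_volume_scale_factors <- function(volumes, elements, scale) {
  if (length(scale) == 0) return(volumes)
  if (any(scale <= 0)) stop("non-positive volume scale factor", call. = FALSE)
  el <- .norm_element(elements)
  names(scale) <- .norm_element(names(scale))
  f <- scale[el]
  f[is.na(f)] <- 1
  volumes$volume <- volumes$volume * as.numeric(f)
  volumes
}

#' Default volume scale factors
#'
#' Reads the packaged scale-factor configuration. The shipped defaults are
#' identity factors flagged as uncalibrated; [calibrate_scale_factors()]
#' reproduces the calibration procedure against a benchmark profile.
#'
#' @param path Optional path to an alternative JSON configuration.
#' @return Named numeric vector of factors.
#' @export
default_scale_factors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "volume_scale_factors.json", package = "swaxsmap")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(cfg$factors)
}

#' Calibrate per-element volume scale factors against a benchmark profile
#'
#' Optimizes H/C/N/O volume scale factors by Nelder-Mead to minimize the
#' profile chi-square against benchmark data while restraining the bulk
#' solvent density to `rho0_fixed` (the hydration-shell contrast is still
#' fitted at each step, guarding against overfitting through the solvent
#' density).
#'
#' @param atoms Atom data.frame (with hydrogens).
#' @param data Experimental `swaxs_profile` with errors.
#' @param rho0_fixed Fixed bulk solvent density, e/A^3.
#' @param elements Elements to calibrate.
#' @param spec Optional [make_grid()] spec; built from `atoms` by default.
#' @param base_volumes Optional precomputed unscaled volumes.
#' @param maxit Nelder-Mead iteration cap.
#' @return Named numeric vector of calibrated factors with attributes `chi2`
#'   and `convergence`.
#' @export
calibrate_scale_factors <- function(atoms, data, rho0_fixed = 0.334,
                                    elements = c("H", "C", "N", "O"),
                                    spec = NULL, base_volumes = NULL,
                                    maxit = 400) {
  if (!"sigma" %in% names(data)) stop("benchmark profile needs errors", call. = FALSE)
  if (is.null(spec)) spec <- make_grid(atoms)
  if (is.null(base_volumes)) base_volumes <- unique_volumes(atoms)
  elements <- .norm_element(elements)
  present <- elements %in% .norm_element(atoms$element)
  if (!all(present)) elements <- elements[present]

  Fv <- sharpen(map_to_structure_factors(in_vacuo_map(atoms, spec)))
  Fs <- map_to_structure_factors(shell_map(atoms, spec))
  lat <- .bin_lattice(spec)
  keep <- data$q <= max(lat$q_centers)
  expd <- swaxs_profile(data$q[keep], data$I[keep], data$sigma[keep])

  eval_factors <- function(f) {
    scale <- stats::setNames(f, elements)
    vols <- apply_volume_scale_factors(base_volumes, atoms$element, scale)
    Fx <- map_to_structure_factors(excluded_volume_map(atoms, vols, spec))
    terms <- binned_cross_terms(Fv, Fx, Fs, lattice = lat)
    ## rho0 restrained; only the shell contrast is refit (1D, bracketed)
    chi_of_drho <- function(dr) {
      ci <- interpolate_profile(profile_from_terms(terms, rho0_fixed, dr / 0.019),
                                expd$q)
      chi2_profile(expd, ci)$chi2
    }
    stats::optimize(chi_of_drho, interval = c(-0.1, 0.15), tol = 1e-9)$objective
  }
  obj <- function(p) eval_factors(exp(p))
  o <- stats::optim(rep(0, length(elements)), obj, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-10))
  o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-10))
  if (o2$convergence != 0)
    warning("scale-factor optimization did not fully converge; ",
            "returning best factors found", call. = FALSE)
  out <- stats::setNames(exp(o2$par), elements)
  attr(out, "chi2") <- o2$value
  attr(out, "convergence") <- o2$convergence
  out
}
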