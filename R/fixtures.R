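## Synthetic test inputs with known analytic answers: single atoms, a
## hand-built glycine tripeptide with explicit hydrogens, uniform spheres,
## and a seeded synthetic-data generator for parameter-recovery studies.

#' Single-atom synthetic model
#'
#' One atom at the origin. The analytic profile oracle is `|f(q)|^2` from the
#' Cromer-Mann parameterization; at q = 0 it equals the squared electron
#' count, independent of the B-factor.
#'
#' @param element Chemical symbol.
#' @param b_factor Model B-factor, squared Angstrom.
#' @return Atom data.frame with attribute `oracle`, a function of q returning
#'   the analytic in vacuo intensity.
#' @export
make_single_atom <- function(element, b_factor = 0) {
  atoms <- atom_table(0, 0, 0, element, b_factor = b_factor)
  co <- ff_coeffs(element)
  attr(atoms, "oracle") <- function(q) form_factor(co, q)^2
  atoms
}

#' Glycine tripeptide with explicit hydrogens
#'
#' A deterministic extended Gly-Gly-Gly model (21 atoms, 7 per residue:
#' N, H, CA, HA2, HA3, C, O) with idealized bond lengths, used as the toy
#' peptide for electron-conservation, volume and parameter-recovery tests.
#'
#' @return Atom data.frame.
#' @export
make_gly3 <- function() {
  res <- data.frame(
    atom_name = c("N", "H", "CA", "HA2", "HA3", "C", "O"),
    element   = c("N", "H", "C", "H", "H", "C", "O"),
    x = c(0.00, -0.33, 1.22, 1.22, 1.22, 2.55, 2.60),
    y = c(0.30, 1.25, -0.48, -1.10, -1.10, 0.28, 1.51),
    z = c(0.00, 0.00, 0.00, 0.88, -0.88, 0.00, 0.00),
    stringsAsFactors = FALSE)
  parts <- lapply(0:2, function(i) {
    r <- res
    r$x <- r$x + 3.8 * i
    r$resno <- i + 1L
    r
  })
  all <- do.call(rbind, parts)
  atom_table(all$x, all$y, all$z, all$element, all$atom_name,
             residue_name = "GLY", resno = all$resno)
}

#' Closed-form scattering intensity of a uniform sphere
#'
#' `I(q) = (drho * V * 3 (sin(qR) - qR cos(qR)) / (qR)^3)^2` with first
#' minimum at `qR ~ 4.493`.
#'
#' @param q Momentum transfer, inverse Angstrom.
#' @param radius Sphere radius, Angstrom.
#' @param density Sphere density contrast (default 1).
#' @return Numeric intensities.
#' @export
sphere_intensity <- function(q, radius, density = 1) {
  V <- 4 / 3 * pi * radius^3
  x <- q * radius
  amp <- ifelse(x < 1e-6, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  (density * V * amp)^2
}

#' Paint a uniform ball into a density grid
#'
#' Voxels whose centers lie inside the sphere get `density`; the analytic
#' profile oracle is [sphere_intensity()].
#'
#' @param radius Sphere radius, Angstrom.
#' @param density Density value.
#' @param spec Grid spec; the sphere is centered in the box and must fit.
#' @param center Optional sphere center (defaults to the box center).
#' @return `swaxs_map` with role `"in_vacuo"`.
#' @export
make_uniform_sphere <- function(radius, density, spec, center = NULL) {
  if (is.null(center)) center <- spec$origin + spec$side / 2
  if (any(center - radius < spec$origin) ||
      any(center + radius > spec$origin + spec$side))
    stop("sphere clipped by the box", call. = FALSE)
  ax <- lapply(1:3, function(k) .axis_coords(spec, k))
  r2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, "+"),
              (ax[[3]] - center[3])^2, "+")
  vals <- array(0, rep(spec$n, 3))
  vals[r2 <= radius^2] <- density
  .new_map(spec, vals, "in_vacuo")
}

#' Generate a synthetic experimental profile from a model
#'
#' Runs the full forward pipeline (explicit volumes, Gaussian excluded
#' volume, water-form-factor shell) at stated `(rho0, drho)`, interpolates to
#' an oversampled q grid emulating an experimental measurement, and adds
#' seeded multiplicative Gaussian noise of fractional size `noise_fraction`
#' (a simple stand-in for counting statistics). The reported `sigma` column
#' is the true noise sigma; for noiseless data `sigma` is set to 1% of the
#' intensity so chi-square weights remain defined.
#'
#' @param atoms Atom data.frame (e.g. [make_gly3()]).
#' @param rho0 Bulk solvent density used for generation, e/A^3.
#' @param drho Shell mean contrast used for generation, e/A^3.
#' @param noise_fraction Fractional noise level (>= 0).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param n_points Number of experimental q points.
#' @param q_range Range of the synthetic measurement; defaults to
#'   `[dq, 0.85 * pi/voxel]` of the model's grid.
#' @param spec Optional grid spec.
#' @param terms Optional precomputed `swaxs_terms` for the model (skips the
#'   map/FFT stage; useful when generating many noise realizations).
#' @return A `swaxs_profile` with errors; attributes `rho0`, `drho`, `terms`
#'   (the precomputed cross terms, reusable for fitting) and `shell_contrast`.
#' @export
make_synthetic_data <- function(atoms, rho0 = 0.334, drho = 0.019,
                                noise_fraction = 0, seed = 1, n_points = 300,
                                q_range = NULL, spec = NULL, terms = NULL) {
  if (noise_fraction < 0) stop("negative noise_fraction", call. = FALSE)
  if (is.null(spec)) spec <- make_grid(atoms)
  if (is.null(terms)) {
    vols <- unique_volumes(atoms)
    Fv <- sharpen(map_to_structure_factors(in_vacuo_map(atoms, spec)))
    Fx <- map_to_structure_factors(excluded_volume_map(atoms, vols, spec))
    Fs <- map_to_structure_factors(shell_map(atoms, spec))
    terms <- binned_cross_terms(Fv, Fx, Fs)
  }
  prof <- profile_from_terms(terms, rho0, drho / 0.019)
  if (is.null(q_range))
    q_range <- c(2 * pi / spec$side, 0.85 * pi / spec$voxel)
  qe <- seq(q_range[1], q_range[2], length.out = n_points)
  I_true <- interpolate_profile(prof, qe)$I
  sig <- if (noise_fraction > 0) noise_fraction * abs(I_true) else 0.01 * abs(I_true)
  I_obs <- I_true
  if (noise_fraction > 0) {
    set.seed(as.integer(seed))
    I_obs <- I_true + sig * stats::rnorm(n_points)
  }
  out <- swaxs_profile(qe, I_obs, sig)
  attr(out, "rho0") <- rho0
  attr(out, "drho") <- drho
  attr(out, "terms") <- terms
  attr(out, "shell_contrast") <- 0.019
  out
}
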