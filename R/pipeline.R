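## End-to-end orchestration: model -> maps -> structure factors -> profile
## (-> fit against data), plus the artifact writer behind the command-line
## driver in inst/scripts/pdb2swaxs.R.

#' Forward SWAXS calculation from an atomic model
#'
#' Builds the grid, the three density maps and their structure factors, and
#' returns the spherically averaged profile at the given solvent parameters
#' together with the reusable pieces (maps, structure factors, binned cross
#' terms).
#'
#' @param atoms Atom data.frame.
#' @param rho0 Bulk solvent density, e/A^3 (default 0.334, pure water).
#' @param drho Hydration-shell mean contrast, e/A^3 (default 0.019).
#' @param voxel_size,box_factor,max_n Grid controls, see [make_grid()].
#' @param exvol_method `"gaussian"` (dummy-atom Gaussians with adjusted
#'   volumes) or `"cube"` (flat density in the van der Waals envelope).
#' @param use_model_b Include the model's atomic B-factors (default off).
#' @param b_smear Sampling smear B-factor, squared Angstrom.
#' @param dictionary Optional `volume_dictionary` for volume lookup.
#' @param scale_factors Named per-element volume scale factors; defaults to
#'   the packaged configuration.
#' @param explicit_volumes Force explicit per-atom volume calculation even
#'   when a dictionary is supplied.
#' @param spec Optional precomputed grid spec.
#' @return List of class `swaxs_calc`: `profile` (a `swaxs_profile`),
#'   `maps` (in_vacuo, exvol, shell), `terms`, `spec`, `volumes`,
#'   `rho0`, `drho`, `shell_contrast`.
#' @export
calc_profile <- function(atoms, rho0 = 0.334, drho = 0.019, voxel_size = 1.0,
                         box_factor = 3.0, max_n = 256,
                         exvol_method = c("gaussian", "cube"),
                         use_model_b = FALSE, b_smear = 7.0,
                         dictionary = NULL, scale_factors = NULL,
                         explicit_volumes = FALSE, spec = NULL) {
  exvol_method <- match.arg(exvol_method)
  if (is.null(spec))
    spec <- make_grid(atoms, voxel_size = voxel_size, box_factor = box_factor,
                      max_n = max_n)
  if (is.null(scale_factors)) scale_factors <- default_scale_factors()

  vols <- NULL
  if (exvol_method == "gaussian") {
    vols <- volumes_for_model(atoms,
                              dictionary = if (explicit_volumes) NULL else dictionary)
    vols <- apply_volume_scale_factors(vols, atoms$element, scale_factors)
    mx <- excluded_volume_map(atoms, vols, spec)
  } else {
    mx <- excluded_volume_map_cube(atoms, spec)
  }
  mv <- in_vacuo_map(atoms, spec, use_model_b = use_model_b, b_smear = b_smear)
  ms <- shell_map(atoms, spec, b_smear = b_smear)

  Fv <- sharpen(map_to_structure_factors(mv), b = -b_smear)
  Fx <- map_to_structure_factors(mx)
  Fs <- map_to_structure_factors(ms)
  terms <- binned_cross_terms(Fv, Fx, Fs)
  profile <- profile_from_terms(terms, rho0, drho / 0.019)
  structure(list(profile = profile, maps = list(in_vacuo = mv, exvol = mx, shell = ms),
                 terms = terms, spec = spec, volumes = vols,
                 rho0 = rho0, drho = drho, shell_contrast = 0.019),
            class = "swaxs_calc")
}

#' Total contrast map at given solvent parameters
#'
#' Real-space counterpart of the three-term amplitude: in vacuo minus
#' `rho0` times the excluded-volume shape plus the shell scaled to `drho`.
#'
#' @param calc A `swaxs_calc` from [calc_profile()].
#' @param rho0,drho Solvent parameters, e/A^3; default to the values stored
#'   in `calc`.
#' @return `swaxs_map` with role `"total"`.
#' @export
total_map <- function(calc, rho0 = calc$rho0, drho = calc$drho) {
  vals <- calc$maps$in_vacuo$values - rho0 * calc$maps$exvol$values +
    (drho / calc$shell_contrast) * calc$maps$shell$values
  .new_map(calc$spec, vals, "total")
}

#' Run the full pipeline and write artifacts
#'
#' Command-line-equivalent entry point: reads a model (and optionally an
#' experimental profile), calculates or fits the SWAXS profile, and writes
#' the four CCP4/MRC maps (`<prefix>_invacuo.mrc`, `_exvol.mrc`, `_shell.mrc`,
#' `_total.mrc`), the calculated profile (`<prefix>_calc.dat`) and, when data
#' are given, the 4-column fit file (`<prefix>_fit.dat`).
#'
#' @param model_path PDB file with explicit hydrogens.
#' @param data_path Optional experimental profile (`q I sigma`).
#' @param output_prefix Prefix for output files.
#' @param fit_rho0,fit_drho,fit_offset Which parameters to fit when data are
#'   given; `no_fit` overrides all three.
#' @param no_fit Evaluate the defaults without optimization.
#' @param q_unit Unit of the experimental q column (`"A"` or `"nm"`).
#' @param truncate Drop data points beyond the calculated qmax.
#' @param write_maps Write the MRC maps (default `TRUE`).
#' @param ... Passed to [calc_profile()] (`voxel_size`, `exvol_method`,
#'   `use_model_b`, `dictionary`, `scale_factors`, ...).
#' @return Invisibly, a list with the `swaxs_calc` and (if fitted) the
#'   `swaxs_fit`.
#' @export
run_pipeline <- function(model_path, data_path = NULL, output_prefix = "swaxsmap",
                         fit_rho0 = TRUE, fit_drho = TRUE, fit_offset = FALSE,
                         no_fit = FALSE, q_unit = "A", truncate = FALSE,
                         write_maps = TRUE, ...) {
  t0 <- proc.time()[["elapsed"]]
  atoms <- read_pdb(model_path)
  message("model: ", nrow(atoms), " atoms, total electrons ",
          format(sum(n_electrons(atoms$element) * atoms$occupancy)))
  calc <- calc_profile(atoms, ...)
  message(sprintf("grid: Dmax %.2f A, %d voxels of %.4f A",
                  calc$spec$dmax, calc$spec$n, calc$spec$voxel))

  fit <- NULL
  if (!is.null(data_path)) {
    expd <- read_profile(data_path, require_sigma = TRUE, q_unit = q_unit)
    fit <- fit_parameters(expd, calc$terms,
                          fit_rho0 = fit_rho0 && !no_fit,
                          fit_drho = fit_drho && !no_fit,
                          fit_offset = fit_offset && !no_fit,
                          truncate = truncate)
    print(fit)
    write_fit(fit, paste0(output_prefix, "_fit.dat"))
  }

  rho0 <- if (!is.null(fit)) fit$rho0 else calc$rho0
  drho <- if (!is.null(fit)) fit$drho else calc$drho
  prof <- profile_from_terms(calc$terms, rho0, drho / calc$shell_contrast)
  write_profile(prof, paste0(output_prefix, "_calc.dat"),
                header = sprintf("calculated SWAXS profile; rho0 %.4f drho %.4f",
                                 rho0, drho))
  if (write_maps) {
    write_mrc(calc$maps$in_vacuo, paste0(output_prefix, "_invacuo.mrc"))
    write_mrc(calc$maps$exvol, paste0(output_prefix, "_exvol.mrc"))
    write_mrc(calc$maps$shell, paste0(output_prefix, "_shell.mrc"))
    write_mrc(total_map(calc, rho0, drho), paste0(output_prefix, "_total.mrc"))
  }
  message(sprintf("done in %.2f s", proc.time()[["elapsed"]] - t0))
  invisible(list(calc = calc, fit = fit))
}
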