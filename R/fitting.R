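## Fitting the calculated profile to experimental data: cubic-spline
## interpolation to the experimental q values, chi-square with a least-squares
## scale (and optional offset) applied to the data, and Nelder-Mead
## optimization of the bulk solvent density and shell contrast.

#' Interpolate a calculated profile to new q values
#'
#' Cubic-spline (Forsythe-Malcolm-Moler) interpolation; the spline reproduces
#' its nodes exactly and polynomials up to degree three. No extrapolation: the
#' experimental q range must lie inside the calculated one.
#'
#' @param calc A calculated `swaxs_profile`.
#' @param q_target Target q values, inverse Angstrom.
#' @return A `swaxs_profile` at `q_target`.
#' @export
interpolate_profile <- function(calc, q_target) {
  if (min(q_target) < min(calc$q) - 1e-12 || max(q_target) > max(calc$q) + 1e-12)
    stop("target q range [", format(min(q_target)), ", ", format(max(q_target)),
         "] outside calculated range [", format(min(calc$q)), ", ",
         format(max(calc$q)), "]; reduce the voxel size to extend qmax",
         call. = FALSE)
  f <- stats::splinefun(calc$q, calc$I, method = "fmm")
  swaxs_profile(q_target, f(q_target))
}

#' Profile chi-square with least-squares scale and optional offset
#'
#' Computes `chi2 = (1/N) sum_i ((c*Iexp_i + b - Icalc_i) / (c*sigma_i))^2`
#' where the scale `c` (and, when enabled, the offset `b`) minimize the
#' weighted residual by linear least squares. The scale and offset are applied
#' to the data, not the calculated profile, so background-subtraction errors
#' are corrected where they arise; dividing by `c*sigma` makes chi2 invariant
#' under rescaling of the data and its errors.
#'
#' @param expd Experimental `swaxs_profile` with `sigma`.
#' @param calc_interp Calculated profile already interpolated to `expd$q`.
#' @param fit_offset Also fit the constant offset `b` (default off).
#' @return List with `chi2`, `scale_c`, `offset_b`.
#' @export
chi2_profile <- function(expd, calc_interp, fit_offset = FALSE) {
  if (nrow(expd) != nrow(calc_interp)) stop("length mismatch", call. = FALSE)
  if (!"sigma" %in% names(expd) || any(expd$sigma <= 0))
    stop("experimental profile needs positive sigma", call. = FALSE)
  Ie <- expd$I; Ic <- calc_interp$I; w <- 1 / expd$sigma^2
  if (all(Ic == 0)) stop("calculated profile is identically zero", call. = FALSE)
  ## reparameterize: (c Ie + b - Ic)/(c s) = (Ie + beta - u Ic)/s with
  ## u = 1/c, beta = b/c; linear least squares in (u, beta)
  if (fit_offset) {
    ## minimize sum w (Ie + beta - u Ic)^2:
    ##   d/dbeta = 0 -> beta = (u swx - swy)/sw
    ##   d/du    = 0 -> sxy + beta swx - u sxx = 0
    sw <- sum(w); swx <- sum(w * Ic); swy <- sum(w * Ie)
    sxx <- sum(w * Ic^2); sxy <- sum(w * Ic * Ie)
    det <- sw * sxx - swx^2
    if (abs(det) < 1e-300) stop("degenerate least-squares system", call. = FALSE)
    u <- (sw * sxy - swx * swy) / det
    beta <- (u * swx - swy) / sw
  } else {
    u <- sum(w * Ie * Ic) / sum(w * Ic^2)
    beta <- 0
  }
  res <- (Ie + beta - u * Ic) / expd$sigma
  chi2 <- mean(res^2)
  c_scale <- 1 / u
  list(chi2 = chi2, scale_c = c_scale, offset_b = beta * c_scale)
}

#' Fit bulk solvent density and hydration-shell contrast
#'
#' Nelder-Mead optimization of the enabled continuous parameters against an
#' experimental profile, starting at the physical defaults
#' `(rho0, drho) = (0.334, 0.019)` e/A^3. The objective recombines the
#' precomputed radial cross terms, interpolates to the experimental q values
#' and evaluates [chi2_profile()]. With no parameter enabled the defaults are
#' evaluated once ("no fit" mode). The best evaluated point is returned even
#' if the optimizer terminates early, so enabling parameters can never worsen
#' the reported chi2. The solvent density is restrained softly to the
#' physically plausible aqueous range `[0.28, 0.40]` e/A^3.
#'
#' @param expd Experimental `swaxs_profile` with errors.
#' @param terms `swaxs_terms` from [binned_cross_terms()] (with the in vacuo
#'   term already sharpened).
#' @param fit_rho0,fit_drho,fit_offset Which parameters to optimize.
#' @param rho0,drho Starting (or fixed) values, e/A^3.
#' @param shell_contrast Mean contrast at which the shell map was built.
#' @param truncate Drop experimental points beyond the calculated qmax (with a
#'   reported count) instead of failing.
#' @param maxit,reltol Nelder-Mead controls.
#' @return Object of class `swaxs_fit`: list with `rho0`, `drho`, `scale_c`,
#'   `offset_b`, `chi2`, `fitted_profile` (calculated profile at the
#'   experimental q values), `n_points`, `flags`, `convergence`.
#' @export
fit_parameters <- function(expd, terms, fit_rho0 = TRUE, fit_drho = TRUE,
                           fit_offset = FALSE, rho0 = 0.334, drho = 0.019,
                           shell_contrast = 0.019, truncate = FALSE,
                           maxit = 1000, reltol = 1e-10) {
  if (!"sigma" %in% names(expd))
    stop("experimental profile needs errors for fitting", call. = FALSE)
  qmax_calc <- max(terms$q)
  if (max(expd$q) > qmax_calc) {
    if (!truncate)
      stop("experimental qmax ", format(max(expd$q)), " exceeds calculated qmax ",
           format(qmax_calc), "; reduce the voxel size or pass truncate = TRUE",
           call. = FALSE)
    n_drop <- sum(expd$q > qmax_calc)
    message("fit_parameters: dropped ", n_drop, " point(s) beyond calculated qmax")
    keep <- expd$q <= qmax_calc
    expd <- swaxs_profile(expd$q[keep], expd$I[keep], expd$sigma[keep])
  }

  eval_at <- function(r0, dr) {
    prof <- profile_from_terms(terms, r0, dr / shell_contrast)
    ci <- interpolate_profile(prof, expd$q)
    chi2_profile(expd, ci, fit_offset = fit_offset)
  }
  penalty <- function(r0) {
    1e8 * (max(0, r0 - 0.40)^2 + max(0, 0.28 - r0)^2)
  }

  best <- NULL
  track <- function(r0, dr) {
    fit <- eval_at(r0, dr)
    if (is.null(best) || fit$chi2 < best$chi2)
      best <<- c(fit, list(rho0 = r0, drho = dr))
    fit$chi2
  }
  track(rho0, drho)   # start point / no-fit evaluation

  free <- c(rho0 = fit_rho0, drho = fit_drho)
  conv <- 0L
  if (any(free)) {
    p0 <- c(rho0, drho)[free]
    obj <- function(p) {
      full <- c(rho0, drho)
      full[free] <- p
      track(full[1], full[2]) + penalty(full[1])
    }
    ctl <- list(maxit = maxit, reltol = reltol,
                parscale = rep(0.05, sum(free)))  # initial simplex steps 0.005
    o <- suppressWarnings(stats::optim(p0, obj, method = "Nelder-Mead", control = ctl))
    o <- suppressWarnings(stats::optim(o$par, obj, method = "Nelder-Mead", control = ctl))
    conv <- o$convergence
    if (conv != 0)
      warning("parameter optimization hit the iteration cap; ",
              "returning the best point found", call. = FALSE)
  }

  prof <- profile_from_terms(terms, best$rho0, best$drho / shell_contrast)
  fitted <- interpolate_profile(prof, expd$q)
  structure(list(rho0 = best$rho0, drho = best$drho, scale_c = best$scale_c,
                 offset_b = best$offset_b, chi2 = best$chi2,
                 fitted_profile = fitted, data = expd, n_points = nrow(expd),
                 flags = list(rho0 = fit_rho0, drho = fit_drho, offset = fit_offset),
                 convergence = conv),
            class = "swaxs_fit")
}

#' @export
print.swaxs_fit <- function(x, ...) {
  cat(sprintf(paste0("SWAXS fit over %d points:\n",
                     "  rho0 = %.4f e/A^3%s\n  drho = %.4f e/A^3%s\n",
                     "  scale c = %.6g, offset b = %.6g\n  chi2 = %.4f\n"),
              x$n_points,
              x$rho0, if (x$flags$rho0) " (fitted)" else " (fixed)",
              x$drho, if (x$flags$drho) " (fitted)" else " (fixed)",
              x$scale_c, x$offset_b, x$chi2))
  invisible(x)
}

#' Write a fit as a 4-column ASCII file
#'
#' Columns are `q`, `c*Iexp + b`, `c*sigma`, `Icalc`; header lines record the
#' fitted parameters.
#'
#' @param fit A `swaxs_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rho0 %.6f e/A^3  drho %.6f e/A^3  scale_c %.8g  offset_b %.8g  chi2 %.6f",
                     fit$rho0, fit$drho, fit$scale_c, fit$offset_b, fit$chi2), con)
  writeLines("# q  c*Iexp+b  c*sigma  Icalc", con)
  writeLines(sprintf("%.8e %.8e %.8e %.8e", fit$data$q,
                     fit$scale_c * fit$data$I + fit$offset_b,
                     fit$scale_c * fit$data$sigma, fit$fitted_profile$I), con)
  invisible(path)
}
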