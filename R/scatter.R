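## Reciprocal space: structure factors, B-factor sharpening, and spherical
## averaging of 3D intensities into a 1D profile.
##
## Reciprocal lattice convention: q components are 2*pi*k/side for signed
## integer frequencies k; the FFT is scaled by the voxel volume so F(0) equals
## the map integral (total electrons for the in vacuo map). Radial bins have
## width dq = 2*pi/side; a voxel joins bin floor(|q|/dq); the q=0 voxel is the
## sole member of the first bin (reported at q = 0) and later bins are
## reported at their centers (k + 0.5)*dq.

#' Structure factors of a density map
#'
#' Discrete Fourier transform of the map scaled by the voxel volume.
#'
#' @param map A `swaxs_map`.
#' @return Object of class `swaxs_sf`: list with complex array `F`, the grid
#'   `spec` and the map `role`.
#' @export
map_to_structure_factors <- function(map) {
  F <- stats::fft(map$values) * map$spec$voxel^3
  structure(list(F = F, spec = map$spec, role = map$role), class = "swaxs_sf")
}

#' @export
print.swaxs_sf <- function(x, ...) {
  cat(sprintf("structure factors [%s]: %d^3, F(0) = %.6g\n",
              x$role, x$spec$n, Re(x$F[1, 1, 1])))
  invisible(x)
}

## reciprocal lattice |q| values, squared |q|, bin indices and bin centers
.bin_lattice <- function(spec) {
  key <- paste0("lat_", spec$n, "_", format(spec$side, digits = 12))
  hit <- .swx_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- spec$n
  k <- ((0:(n - 1) + n %/% 2) %% n) - n %/% 2
  q1sq <- (2 * pi * k / spec$side)^2
  q2 <- outer(outer(q1sq, q1sq, "+"), q1sq, "+")
  dq <- 2 * pi / spec$side
  bidx <- as.integer(floor(sqrt(q2) / dq))
  nb <- max(bidx) + 1L
  counts <- tabulate(bidx + 1L, nbins = nb)
  qc <- (seq_len(nb) - 1 + 0.5) * dq
  qc[1] <- 0
  out <- list(q2 = q2, bidx = bidx, counts = counts, q_centers = qc, dq = dq,
              nonempty = counts > 0)
  if (n <= 160) assign(key, out, envir = .swx_cache)  # keep the cache small
  out
}

## radial mean of a real-valued lattice field
.bin_mean <- function(x, lat) {
  s <- numeric(length(lat$counts))
  rs <- rowsum(as.vector(x), lat$bidx)
  s[as.integer(rownames(rs)) + 1L] <- rs[, 1]
  (s / pmax(lat$counts, 1L))[lat$nonempty]
}

#' Reciprocal-space B-factor sharpening
#'
#' Multiplies structure factors by the Debye-Waller amplitude factor
#' `exp(-b q^2 / (16 pi^2))`. With `b = -b_smear` this exactly undoes, in the
#' continuum limit, the real-space sampling smear applied by
#' [in_vacuo_map()]; it is applied to the in vacuo term only.
#'
#' @param sf A `swaxs_sf`.
#' @param b Sharpening B-factor in squared Angstrom (default -7).
#' @return Sharpened `swaxs_sf`.
#' @export
sharpen <- function(sf, b = -7.0) {
  if (b == 0) return(sf)
  lat <- .bin_lattice(sf$spec)
  sf$F <- sf$F * exp(-b * lat$q2 / (16 * pi^2))
  sf
}

.check_same_lattice <- function(...) {
  sfs <- Filter(Negate(is.null), list(...))
  ns <- vapply(sfs, function(s) s$spec$n, integer(1))
  sides <- vapply(sfs, function(s) s$spec$side, numeric(1))
  if (length(unique(ns)) != 1 || diff(range(sides)) > 1e-9)
    stop("structure-factor grids do not share one lattice", call. = FALSE)
  sfs[[1]]$spec
}

#' Combine structure factors and spherically average
#'
#' Forms the three-term scattering amplitude
#' `F = F_invacuo - rho0 * F_exvol + s * F_shell` per reciprocal voxel, takes
#' the squared modulus, and averages over spherical bins of width
#' `2*pi/side`. `drho_scale = 1` corresponds to the shell map's built-in mean
#' contrast, so for a shell built at 0.019 e/A^3 the physical contrast is
#' `drho = 0.019 * drho_scale`.
#'
#' @param Fv In vacuo `swaxs_sf` (already sharpened).
#' @param Fx Excluded-volume `swaxs_sf`, or `NULL` to omit the term.
#' @param Fs Shell `swaxs_sf`, or `NULL` to omit the term.
#' @param rho0 Bulk solvent density, e/A^3.
#' @param drho_scale Dimensionless multiplier on the shell term.
#' @return A `swaxs_profile` of the spherically averaged intensity.
#' @export
combine_and_average <- function(Fv, Fx = NULL, Fs = NULL, rho0 = 0,
                                drho_scale = 0) {
  spec <- .check_same_lattice(Fv, Fx, Fs)
  A <- Fv$F
  if (!is.null(Fx) && rho0 != 0) A <- A - rho0 * Fx$F
  if (!is.null(Fs) && drho_scale != 0) A <- A + drho_scale * Fs$F
  lat <- .bin_lattice(spec)
  I <- Re(A * Conj(A))
  swaxs_profile(lat$q_centers[lat$nonempty], .bin_mean(I, lat))
}

#' Precompute radially binned cross terms of the three-component amplitude
#'
#' The intensity is bilinear in `(1, rho0, s)`, so the six radial profiles
#' `<|Fv|^2>, <|Fx|^2>, <|Fs|^2>, <Re Fv Fx*>, <Re Fv Fs*>, <Re Fx Fs*>`
#' determine the 1D profile for every parameter pair. Fitting then costs one
#' linear combination per evaluation instead of a full 3D pass.
#'
#' @param Fv,Fx,Fs Structure factors on a common lattice (`Fx`, `Fs` may be
#'   `NULL`; their terms are zero).
#' @param lattice Optional precomputed lattice from the internal cache.
#' @return Object of class `swaxs_terms`.
#' @export
binned_cross_terms <- function(Fv, Fx = NULL, Fs = NULL, lattice = NULL) {
  spec <- .check_same_lattice(Fv, Fx, Fs)
  lat <- if (is.null(lattice)) .bin_lattice(spec) else lattice
  zero <- numeric(sum(lat$nonempty))
  bm <- function(x) if (is.null(x)) zero else .bin_mean(x, lat)
  terms <- list(
    q = lat$q_centers[lat$nonempty],
    vv = bm(Re(Fv$F * Conj(Fv$F))),
    xx = if (is.null(Fx)) zero else bm(Re(Fx$F * Conj(Fx$F))),
    ss = if (is.null(Fs)) zero else bm(Re(Fs$F * Conj(Fs$F))),
    vx = if (is.null(Fx)) zero else bm(Re(Fv$F * Conj(Fx$F))),
    vs = if (is.null(Fs)) zero else bm(Re(Fv$F * Conj(Fs$F))),
    xs = if (is.null(Fx) || is.null(Fs)) zero else bm(Re(Fx$F * Conj(Fs$F))),
    spec = spec)
  class(terms) <- "swaxs_terms"
  terms
}

#' Profile from precomputed cross terms
#'
#' @param terms A `swaxs_terms` object.
#' @param rho0 Bulk solvent density, e/A^3.
#' @param drho_scale Shell multiplier (1 = built-in mean contrast).
#' @return A `swaxs_profile`.
#' @export
profile_from_terms <- function(terms, rho0 = 0, drho_scale = 0) {
  I <- terms$vv + rho0^2 * terms$xx + drho_scale^2 * terms$ss -
    2 * rho0 * terms$vx + 2 * drho_scale * terms$vs -
    2 * rho0 * drho_scale * terms$xs
  swaxs_profile(terms$q, I)
}
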