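## Real-space density maps on a cubic voxel grid.
##
## Grid convention: the box corner is `origin`; voxel centers sit at
## origin + (i + 0.5) * voxel_size for i = 0 .. n-1 along each axis.

#' Maximum dimension of a point set
#'
#' Largest pairwise distance between atom coordinates (Dmax). Exact for small
#' models; for large models the diameter is computed over directional extreme
#' points, which is exact in practice for molecular shapes.
#'
#' @param atoms Atom data.frame.
#' @return Dmax in Angstrom.
#' @export
max_dimension <- function(atoms) {
  xyz <- atom_coords(atoms)
  n <- nrow(xyz)
  if (n == 1) return(0)
  if (n > 2500) {
    u <- matrix(stats::rnorm(3 * 60), ncol = 3)
    u <- rbind(diag(3), u / sqrt(rowSums(u^2)))
    proj <- xyz %*% t(u)
    ext <- unique(c(apply(proj, 2, which.min), apply(proj, 2, which.max)))
    xyz <- xyz[ext, , drop = FALSE]
  }
  max(stats::dist(xyz))
}

#' Build the cubic voxel grid for a model
#'
#' The box side is `box_factor` times the particle's maximum dimension
#' (default 3, comfortably beyond the Shannon minimum of twice Dmax), rounded
#' up to an even number of voxels of size `voxel_size`. If that count exceeds
#' `max_n`, the count is capped and the voxel size grows to compensate, which
#' lowers the maximum usable q (`qmax = pi/voxel_size` at the Nyquist limit).
#' The particle is centered in the box. A degenerate single-atom model gets a
#' minimum box of 20 A.
#'
#' @param atoms Atom data.frame.
#' @param voxel_size Target voxel size, Angstrom (default 1).
#' @param box_factor Box side as a multiple of Dmax (default 3).
#' @param max_n Cap on voxels per side (default 256).
#' @param min_side Minimum box side in Angstrom.
#' @return Object of class `grid_spec`: list with `n` (voxels per side),
#'   `voxel` (A), `side` (A), `origin` (corner, A), `dmax`.
#' @export
make_grid <- function(atoms, voxel_size = 1.0, box_factor = 3.0, max_n = 256,
                      min_side = 20) {
  if (nrow(atoms) < 1) stop("no atoms", call. = FALSE)
  dmax <- max_dimension(atoms)
  side <- max(box_factor * dmax, min_side)
  n <- 2 * ceiling(side / voxel_size / 2)
  if (n > max_n) {
    n <- as.integer(max_n)
    voxel_size <- side / n
  } else {
    side <- n * voxel_size
  }
  xyz <- atom_coords(atoms)
  centroid <- (apply(xyz, 2, min) + apply(xyz, 2, max)) / 2
  structure(list(n = as.integer(n), voxel = voxel_size, side = side,
                 origin = unname(centroid - side / 2), dmax = dmax),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d^3 voxels of %.5g A (side %.5g A), Dmax %.4g A\n",
              x$n, x$voxel, x$side, x$dmax))
  invisible(x)
}

## voxel-center coordinates along one axis
.axis_coords <- function(spec, k) spec$origin[k] + (seq_len(spec$n) - 0.5) * spec$voxel

## index window along each axis within `win` of a point; NULL if empty
.window_idx <- function(spec, center, win) {
  lapply(1:3, function(k) {
    lo <- max(1L, as.integer(ceiling((center[k] - win - spec$origin[k]) / spec$voxel + 0.5)))
    hi <- min(spec$n, as.integer(floor((center[k] + win - spec$origin[k]) / spec$voxel + 0.5)))
    if (lo > hi) integer(0) else lo:hi
  })
}

.new_map <- function(spec, values, role) {
  structure(list(spec = spec, values = values, role = role), class = "swaxs_map")
}

#' @export
print.swaxs_map <- function(x, ...) {
  cat(sprintf("density map [%s]: %d^3 voxels of %.4g A, integral %.6g\n",
              x$role, x$spec$n, x$spec$voxel, map_integral(x)))
  invisible(x)
}

#' Integral of a density map
#'
#' Voxel sum times voxel volume (electrons for the in vacuo map).
#'
#' @param map A `swaxs_map`.
#' @return Numeric scalar.
#' @export
map_integral <- function(map) sum(map$values) * map$spec$voxel^3

#' In vacuo electron density map
#'
#' Deposits each atom's real-space form factor (four offset-free Gaussians,
#' see [realspace_coeffs()]) smeared by a B-factor
#' `B_j = b_smear + model B (optional)`. A small `b_smear` (~7 A^2, a 0.3 A
#' displacement) spreads density that would otherwise fall between voxel
#' centers; the matching reciprocal-space sharpening is applied by
#' [sharpen()]. Each atom's deposited density is rescaled so its integral is
#' exactly its electron count times its occupancy.
#'
#' @param atoms Atom data.frame.
#' @param spec Grid spec from [make_grid()].
#' @param use_model_b Add each atom's model B-factor (default off: solution
#'   scattering is poorly served by crystallographic B-factors).
#' @param b_smear Sampling B-factor in squared Angstrom (default 7).
#' @param window Deposition radius around each atom, Angstrom (default 3);
#'   enlarged automatically with the B-factor.
#' @return `swaxs_map` with role `"in_vacuo"`.
#' @export
in_vacuo_map <- function(atoms, spec, use_model_b = FALSE, b_smear = 7.0,
                         window = 3.0) {
  vals <- array(0, rep(spec$n, 3))
  ax <- lapply(1:3, function(k) .axis_coords(spec, k))
  dv <- spec$voxel^3
  coeffs <- lapply(stats::setNames(nm = unique(atoms$element)), realspace_coeffs)
  zs <- n_electrons(atoms$element)
  for (i in seq_len(nrow(atoms))) {
    bfac <- b_smear + if (use_model_b) atoms$b_factor[i] else 0
    win <- window + 0.3 * sqrt(max(bfac, 0) / 7)
    ctr <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    idx <- .window_idx(spec, ctr, win)
    if (any(lengths(idx) == 0))
      stop("atom ", i, " lies outside the grid", call. = FALSE)
    r2 <- outer(outer((ax[[1]][idx[[1]]] - ctr[1])^2,
                      (ax[[2]][idx[[2]]] - ctr[2])^2, "+"),
                (ax[[3]][idx[[3]]] - ctr[3])^2, "+")
    rho <- .rho_radial(coeffs[[atoms$element[i]]], bfac, r2)
    tot <- sum(rho) * dv
    if (tot <= 0) stop("zero deposited density for atom ", i, call. = FALSE)
    vals[idx[[1]], idx[[2]], idx[[3]]] <-
      vals[idx[[1]], idx[[2]], idx[[3]]] + rho * (zs[i] * atoms$occupancy[i] / tot)
  }
  .new_map(spec, vals, "in_vacuo")
}

#' Gaussian dummy-atom excluded-volume map
#'
#' Deposits, per atom, the unit-amplitude Gaussian
#' `rho_j(r) = exp(-pi r^2 / V_j^(2/3))` whose analytic integral equals the
#' atom's adjusted volume `V_j`. The map stores shape only; multiplication by
#' the bulk solvent density happens in reciprocal space when the three terms
#' are combined.
#'
#' @param atoms Atom data.frame.
#' @param volumes data.frame with per-atom `volume` (from [unique_volumes()],
#'   [volumes_for_model()], or scaled versions), one row per atom.
#' @param spec Grid spec.
#' @return `swaxs_map` with role `"excluded_volume"`.
#' @export
excluded_volume_map <- function(atoms, volumes, spec) {
  v <- volumes$volume
  if (length(v) != nrow(atoms)) stop("one volume per atom required", call. = FALSE)
  if (any(v <= 0)) stop("non-positive adjusted volume", call. = FALSE)
  vals <- array(0, rep(spec$n, 3))
  ax <- lapply(1:3, function(k) .axis_coords(spec, k))
  for (i in seq_len(nrow(atoms))) {
    s2 <- v[i]^(2 / 3)
    win <- sqrt(16 * s2 / pi)          # exp(-16) tail cut keeps >99.9% of V_j
    ctr <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    idx <- .window_idx(spec, ctr, win)
    if (any(lengths(idx) == 0))
      stop("atom ", i, " lies outside the grid", call. = FALSE)
    r2 <- outer(outer((ax[[1]][idx[[1]]] - ctr[1])^2,
                      (ax[[2]][idx[[2]]] - ctr[2])^2, "+"),
                (ax[[3]][idx[[3]]] - ctr[3])^2, "+")
    vals[idx[[1]], idx[[2]], idx[[3]]] <-
      vals[idx[[1]], idx[[2]], idx[[3]]] + exp(-pi * r2 / s2)
  }
  .new_map(spec, vals, "excluded_volume")
}

## signed distance from every voxel center to the union-of-vdW-spheres
## surface, evaluated only out to max_dist (Inf beyond); negative inside
.surface_distance <- function(atoms, spec, radii, max_dist) {
  dist <- array(Inf, rep(spec$n, 3))
  ax <- lapply(1:3, function(k) .axis_coords(spec, k))
  for (i in seq_len(nrow(atoms))) {
    ctr <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    idx <- .window_idx(spec, ctr, radii[i] + max_dist)
    if (any(lengths(idx) == 0)) next
    r <- sqrt(outer(outer((ax[[1]][idx[[1]]] - ctr[1])^2,
                          (ax[[2]][idx[[2]]] - ctr[2])^2, "+"),
                    (ax[[3]][idx[[3]]] - ctr[3])^2, "+")) - radii[i]
    dist[idx[[1]], idx[[2]], idx[[3]]] <- pmin(dist[idx[[1]], idx[[2]], idx[[3]]], r)
  }
  dist
}

#' Flat "cube-method" excluded-volume support map
#'
#' Binary map marking voxels whose centers fall inside any atom's van der
#' Waals sphere (a union-of-spheres solvent envelope). Multiplied by the bulk
#' solvent density downstream, this is the flat alternative to the Gaussian
#' dummy-atom model; at 1 A voxels the support volume is quantized at the
#' single-voxel level, which is part of why this method fits worse.
#'
#' @param atoms Atom data.frame.
#' @param spec Grid spec.
#' @param radii Optional per-atom radii; Bondi defaults.
#' @return `swaxs_map` with role `"excluded_volume"` and 0/1 values.
#' @export
excluded_volume_map_cube <- function(atoms, spec, radii = NULL) {
  radii <- .atom_radii(atoms, radii)
  d <- .surface_distance(atoms, spec, radii, max_dist = spec$voxel)
  vals <- array(0, rep(spec$n, 3))
  vals[d <= 0] <- 1
  .new_map(spec, vals, "excluded_volume")
}

#' Implicit hydration-shell contrast map
#'
#' Places the shell's density peak one water radius outside the van der Waals
#' surface: each voxel within `(0, water_radius + shell_extent]` of the
#' surface (by signed distance to the union-of-spheres surface, which lets the
#' shell penetrate interior cavities and channels) is assigned the real-space
#' form factor of a single-site water molecule evaluated at
#' `|distance - water_radius|`, then the map is rescaled so the mean density
#' over the shell support equals `mean_contrast`.
#'
#' @param atoms Atom data.frame.
#' @param spec Grid spec.
#' @param radii Optional per-atom radii; Bondi defaults.
#' @param water_radius Water-molecule radius, Angstrom (default 1.4).
#' @param mean_contrast Mean shell contrast, e/A^3 (default 0.019). Negative
#'   values are allowed (fitting may drive the contrast negative) and are
#'   reported, not rejected.
#' @param shell_extent Shell support beyond the peak, Angstrom (default 3;
#'   the water form factor is negligible farther out).
#' @param b_smear Smearing B-factor for the water form factor, matching the
#'   grid-sampling smear of the solute maps.
#' @return `swaxs_map` with role `"shell"`; attribute `mean_contrast` stores
#'   the built-in scale.
#' @export
shell_map <- function(atoms, spec, radii = NULL, water_radius = 1.4,
                      mean_contrast = 0.019, shell_extent = 3.0, b_smear = 7.0) {
  radii <- .atom_radii(atoms, radii)
  if (mean_contrast < 0)
    message("shell_map: negative mean contrast (", mean_contrast, ") requested")
  d <- .surface_distance(atoms, spec, radii, max_dist = water_radius + shell_extent)
  sel <- which(d > 0 & d <= water_radius + shell_extent)
  vals <- array(0, rep(spec$n, 3))
  if (length(sel) > 0) {
    w <- realspace_coeffs("HOH")
    t2 <- (d[sel] - water_radius)^2
    prof <- .rho_radial(w, b_smear, t2)
    vals[sel] <- prof * (mean_contrast / mean(prof))
  }
  out <- .new_map(spec, vals, "shell")
  attr(out, "mean_contrast") <- mean_contrast
  out
}
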