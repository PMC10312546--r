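---
title: "Calculating and fitting SWAXS profiles from atomic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calculating and fitting SWAXS profiles from atomic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaxsmap)
```

## The model

A dilute solution scattering experiment measures the spherically averaged
intensity of the particle's contrast against the solvent. `swaxsmap` computes
it from three real-space electron density maps built on one cubic voxel grid:

$$I(q) = \left\langle \left| F_\mathrm{vac}(\vec q) - \rho_0 F_\mathrm{ex}(\vec q)
  + \delta\rho\, F_\mathrm{sh}(\vec q) \right|^2 \right\rangle_\Omega$$

where $F_\mathrm{vac}$ is the Fourier transform of the solute's in vacuo
electron density, $F_\mathrm{ex}$ that of the displaced bulk solvent (the
excluded volume), $F_\mathrm{sh}$ that of the hydration shell,
$\rho_0$ the bulk solvent density (default 0.334 e/&#8491;&#179;, pure water at
room temperature) and $\delta\rho$ the mean shell contrast (default
0.019 e/&#8491;&#179;). The angle brackets denote the spherical average,
implemented by binning the 3D intensities by $|\vec q|$. Only $\rho_0$ and
$\delta\rho$ are fitted; the excluded volume carries no free parameter because
the per-atom displaced volumes are computed from the coordinates themselves.

The method assumes a rigid solute (an ensemble is better served by averaging
profiles over its members), dilute non-interacting particles, explicit
hydrogens in the model, and a hydration shell whose contrast varies with
distance from the surface but not laterally across it.

## Grid

The box side is three times the particle's maximum dimension
(`box_factor = 3`), comfortably beyond the Shannon minimum of $2 D_\mathrm{max}$,
with 1 &#8491; voxels by default. That box yields reciprocal bins of width
$\Delta q = 2\pi/\mathrm{side}$, i.e. about 1.5 calculated points per Shannon
channel $\pi/D_\mathrm{max}$. If the side would exceed 256 voxels the count is
capped and the voxel grows, trading away the widest angles
($q_\mathrm{Nyquist} = \pi/\mathrm{voxel}$). A voxel joins radial bin
$\lfloor |\vec q|/\Delta q \rfloor$; the $q = 0$ voxel forms its own first bin
reported at $q = 0$, later bins are reported at their centers
$(k + 0.5)\Delta q$. Single-atom models get a minimum 20 &#8491; box.

## In vacuo density

Each atom deposits the real-space form of its X-ray form factor. The tabulated
Cromer-Mann parameterization is four Gaussians plus a constant offset; the
offset corresponds to a delta function in real space and cannot live on a
voxel grid, so per element the package refits a pure four-Gaussian model (both
amplitudes and widths free, relative-error weighted) to the full five-term
curve over $q \in [0, 14]$ &#8491;&#8315;&#185;. The refit reproduces the
tabulated amplitude to within 0.23% over $q \le 12$ for H, C, N and O; it is
computed once per session and cached.

Sampling a bare atom on a 1 &#8491; grid fails badly — for nitrogen a large
fraction of the density lies within a few hundredths of an &#8491;ngstr&#246;m
of the center. Every atom therefore receives a sampling B-factor of
7 &#8491;&#178; (a 0.3 &#8491; displacement) before deposition, and the exact
inverse Debye-Waller factor $\exp(+7 q^2/16\pi^2)$ is applied to
$F_\mathrm{vac}$ in reciprocal space. The cycle is exact in the continuum
limit; on the grid the residual is aliasing of the narrowest refit Gaussians,
which shrinks rapidly with the voxel size. Density is deposited within 3 &#8491;
of each atom (grown with the B-factor), and each atom's deposit is rescaled so
its integral is exactly its electron count times its occupancy — electron
conservation then holds to machine precision by construction, and the exact
redistribution of the dropped offset becomes immaterial to totals.

Model B-factors can be added (`use_model_b = TRUE`) but are off by default:
crystallographic displacement parameters modify structure-factor amplitudes,
which is the wrong bookkeeping for a dilute solution where disorder should add
in intensities, and in practice they degrade fits.

## Excluded volume

Each atom displaces a volume of bulk solvent smaller than its van der Waals
sphere because bonded neighbors overlap it. The per-atom *adjusted volume* is
computed by clipping: the atom's Bondi sphere is voxelized into a miniature
Boolean grid (16 voxels per side across the sphere diameter, about
0.2 &#8491;), every neighbor within 5 &#8491; (center-to-center) that overlaps
the sphere cuts away the voxels beyond the radical plane of the sphere-sphere
intersection, and the surviving voxel volume is $V_j$. The radical plane at
distance $(d^2 + r_1^2 - r_2^2)/2d$ from the atom is the plane of the
intersection circle when the spheres overlap and extends continuously
otherwise; the formula automatically leaves non-overlapping neighbors harmless
and lets an engulfing neighbor clip the sphere to zero (reported as a
warning, as are coincident atoms, whose degenerate plane is skipped). A voxel
belongs to a sphere when its center does — the convention that makes
volume-by-voxel-count converge with grid refinement.

Against the closed-form sphere-minus-cap volume, the n = 16 grid is accurate
to about 1.5% for configurations in general position; bonds aligned with a
grid axis are the worst case (an entire voxel slab flips at once) and can
reach ~5% for a single atom. Averaged over a model's many bond orientations
the error is far smaller, and `fine_grid_n = 48` reaches ~0.5% in general
position.

Because clipping ignores solvent-inaccessible voids between atoms, the summed
adjusted volumes underestimate the true excluded volume. Per-element scale
factors (H, C, N, O) correct this; `calibrate_scale_factors()` fits them to a
benchmark profile while holding $\rho_0$ at 0.334 e/&#8491;&#179; to avoid
leaking solvent density into the volumes. The shipped configuration contains
identity factors flagged as uncalibrated — calibrating requires an external
benchmark dataset, and users with one can persist their own factors.

`build_volume_dictionary()` averages explicit volumes per (residue name, atom
name) over a model corpus so that production runs can look volumes up instead
of recomputing them; the same atom name gets separate entries per residue
type, since its mean volume genuinely differs. Atoms missing from the
dictionary silently fall back to the explicit calculation (with a logged
count). No dictionary ships with the package; lookup is an optimization, not
a requirement.

The excluded-volume map itself deposits, per atom, the unit-amplitude
Gaussian $\exp(-\pi r^2/V_j^{2/3})$, whose analytic integral is $V_j$; the
map stores shape only and is multiplied by $\rho_0$ in reciprocal space. The
alternative "cube" method (`exvol_method = "cube"`) paints a binary
union-of-spheres support instead; it is retained for comparison and fits
measurably worse.

## Hydration shell

The shell's density peak sits one water radius (1.4 &#8491;) outside the van
der Waals surface. For every voxel the package evaluates the signed distance
to the union-of-spheres surface, $\min_j(|\vec r - \vec r_j| - R_j)$ — exact
for the analytic surface that a lattice distance transform would only
approximate, and free of any transform dependency. Voxels between the surface
and 4.4 &#8491; out (peak + 3 &#8491;, beyond which the water form factor is
negligible) receive the real-space form factor of a single-site composite
water (O plus two H summed into one 10-electron scatterer, refit and smeared
like the solute atoms) evaluated at |distance &#8722; 1.4 &#8491;|. Interior
cavities and channels reachable by this distance are wetted like the outer
surface. Finally the map is rescaled so its mean over the shell support
equals the target contrast; fitted contrasts may legitimately go negative
(reported, not rejected). Lateral variation of contrast across the surface is
out of scope.

## Fitting

The coarse calculated profile is interpolated to the experimental $q$ values
with a cubic spline (no extrapolation — data beyond the calculated
$q_\mathrm{max}$ are fatal unless `truncate = TRUE` drops them with a count).
The goodness of fit is

$$\chi^2 = \frac{1}{N}\sum_i \left( \frac{c\,I_\mathrm{exp}(q_i) + b -
I_\mathrm{calc}(q_i)}{c\,\sigma(q_i)} \right)^2$$

with the scale $c$ (and optional offset $b$, default off) determined by
linear least squares and applied to the *data*, so background-subtraction
errors are corrected where they arise; the $c\sigma$ denominator makes
$\chi^2$ invariant under rescaling the data and errors together. $\rho_0$ and
$\delta\rho$ are then optimized by Nelder-Mead from (0.334, 0.019) with
initial simplex steps of 0.005 e/&#8491;&#179;, relative convergence tolerance
$10^{-10}$, one restart from the optimum, and a soft quadratic penalty
confining $\rho_0$ to the physically plausible aqueous range
[0.28, 0.40] e/&#8491;&#179;. The best point ever evaluated (including the
start) is returned, so enabling parameters can never worsen the reported
$\chi^2$, and the whole pipeline is deterministic. Because the intensity is
bilinear in $(1, \rho_0, \delta\rho)$, six radially binned cross terms
computed once make each objective evaluation a cheap linear combination
rather than a 3D pass.

## Synthetic data and what the tests show

`make_synthetic_data()` runs the forward pipeline at stated parameters,
resamples the profile onto an oversampled experimental-style $q$ grid (300
points by default) and adds seeded multiplicative Gaussian noise
$\sigma_i = f \cdot I_i$ — a deliberate simplification of counting
statistics. It emulates oversampling and signal-proportional noise; it does
not emulate Poisson statistics at low counts, instrumental smearing, buffer
mismatch, radiation damage, or real hydration-shell physics. Passing the
recovery tests therefore demonstrates internal consistency of the forward
model and optimizer (no identifiability or convergence pathologies), not
agreement with any particular experiment — the latter requires benchmark
SWAXS datasets with their fitted atomic models.

Test problem sizes were chosen to exercise every code path at desk scale: a
21-atom glycine tripeptide with explicit hydrogens in a 32&#179; box for
pipeline and fitting tests, single atoms at 0.25 &#8491; voxels (with a
widened 5 &#8491; deposition window, so that window truncation does not mask
the smear/sharpen behavior being measured) for the form-factor oracle, a
20 &#8491; uniform ball in a 120&#179; box for the sphere oracle, and 10 noise
seeds for the $\chi^2 \approx 1$ check.

## Known limitations

* Model B-factors use the crystallographic amplitude convention and reliably
  worsen solution fits; a solution-appropriate ensemble treatment is future
  work.
* The shell contrast is radially structured but laterally uniform.
* Shipped volume scale factors are identity (uncalibrated); accuracy of
  absolute excluded volumes on real proteins benefits from calibration
  against a benchmark profile.
* Axis-aligned bonds are the worst case of the Boolean volume grid; the
  default n = 16 is a speed/accuracy compromise tuned for corpus averaging.
* At the default 1 &#8491; voxels the calculated profile is reliable to
  roughly half the Nyquist momentum transfer (~1.6 &#8491;&#8315;&#185;);
  wide-angle work beyond that should reduce the voxel size.
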