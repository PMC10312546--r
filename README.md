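# swaxsmap

Small- and wide-angle X-ray scattering (SWAXS) profiles computed from atomic
models by way of high-resolution real-space electron density maps, with
two-parameter solvent fitting against experimental data.

Solution scattering probes the structure of biological macromolecules in
their native aqueous state, but comparing an atomic model to a measured
profile requires modeling two solvent contributions on top of the solute
itself: the bulk solvent displaced by the particle (the *excluded volume*)
and the weakly ordered *hydration shell* at its surface. `swaxsmap` builds
all three components as density maps on one cubic voxel grid, Fourier
transforms them, and spherically averages the combined intensity

$$I(q) = \left\langle\, \left| F_\mathrm{vac} - \rho_0 F_\mathrm{ex} +
\delta\rho\, F_\mathrm{sh} \right|^2 \,\right\rangle_\Omega$$

where $\rho_0$ is the bulk solvent density (0.334 e/Å³ for water) and
$\delta\rho$ the mean hydration-shell contrast (default 0.019 e/Å³) — the
only two fitted parameters. The usual third knob of implicit-solvent
programs, a global atomic-volume expansion factor, is eliminated: each
atom's displaced-solvent volume is computed directly from the coordinates by
clipping its van der Waals sphere against the radical planes of overlapping
neighbors on a fine Boolean voxel grid, so bonding overlap is accounted for
atom by atom. Fits minimize

$$\chi^2 = \frac{1}{N}\sum_i \left(\frac{c\,I_\mathrm{exp}(q_i) + b -
I_\mathrm{calc}(q_i)}{c\,\sigma(q_i)}\right)^2$$

over $\rho_0$ and $\delta\rho$ by Nelder-Mead, with the scale $c$ (and an
optional offset $b$) determined by least squares. It is intended for
structural biologists validating crystal, cryo-EM or predicted structures
against SAXS/WAXS data, and as a forward model for density-based hybrid
modeling.

## Worked example

Everything below is self-contained: a glycine tripeptide with explicit
hydrogens and a synthetic "experimental" profile generated from it at known
solvent parameters (ρ₀ = 0.337, δρ = 0.022, 1% noise).

```r
library(swaxsmap)

atoms <- make_gly3()
write_pdb(atoms, "gly3.pdb")
d <- make_synthetic_data(atoms, rho0 = 0.337, drho = 0.022,
                         noise_fraction = 0.01, seed = 42)
write_profile(d, "gly3_saxs.dat")

run_pipeline("gly3.pdb", "gly3_saxs.dat", output_prefix = "gly3")
#> model: 21 atoms, total electrons 90
#> grid: Dmax 10.53 A, 32 voxels of 1.0000 A
#> SWAXS fit over 300 points:
#>   rho0 = 0.3369 e/A^3 (fitted)
#>   drho = 0.0220 e/A^3 (fitted)
#>   scale c = 1.00047, offset b = 0
#>   chi2 = 0.9690
#> done in 0.40 s
```

The fit recovers the generating parameters (0.3369 vs 0.337 and 0.0220 vs
0.022) and χ² ≈ 0.97, as expected when the noise model is correctly
specified. On disk the run leaves the four density maps in CCP4/MRC format
(`gly3_invacuo.mrc`, `gly3_exvol.mrc`, `gly3_shell.mrc`, `gly3_total.mrc` —
viewable in PyMOL or ChimeraX), the calculated profile `gly3_calc.dat`, and
the 4-column fit file `gly3_fit.dat` (`q`, `c·Iexp+b`, `c·σ`, `Icalc`).

The same run is available from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/pdb2swaxs.R", package="swaxsmap"))') \
    -m gly3.pdb -d gly3_saxs.dat -o gly3
```

with flags for the run modes (`--no-fit`, `--no-fit-rho0`, `--no-fit-shell`,
`--fit-offset`, `--exvol cube`, `--use-b-factors`, `--explicit-volumes`,
`--vdict`, `--scale-factors`, `--nm`, `--truncate`).

For real data: prepare a model with explicit hydrogens (e.g. via Reduce),
supply the measured profile as whitespace-delimited `q I sigma` with q in
1/Å (or `--nm`), and reduce `voxel_size` if your data extend beyond
q ≈ 1.6 Å⁻¹.

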