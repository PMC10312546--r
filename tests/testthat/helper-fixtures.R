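## Shared fixtures: a glycine tripeptide with its grid and precomputed
## structure-factor cross terms (reused across files to keep the suite fast).

gly3 <- make_gly3()
gly3_spec <- make_grid(gly3)
gly3_vols <- unique_volumes(gly3)
gly3_terms <- local({
  Fv <- sharpen(map_to_structure_factors(in_vacuo_map(gly3, gly3_spec)))
  Fx <- map_to_structure_factors(excluded_volume_map(gly3, gly3_vols, gly3_spec))
  Fs <- map_to_structure_factors(shell_map(gly3, gly3_spec))
  binned_cross_terms(Fv, Fx, Fs)
})

## generic (non-axis-aligned) bond direction for volume oracles; axis-aligned
## bonds are the degenerate case where a whole voxel slab flips at once
skew_dir <- c(0.36, 0.48, 0.80)

two_atom_pair <- function(d, dir = skew_dir, elements = c("C", "C")) {
  p <- d * dir / sqrt(sum(dir^2))
  atom_table(c(0, p[1]), c(0, p[2]), c(0, p[3]), elements)
}

## analytic sphere-minus-cap volume for two overlapping spheres
clipped_sphere_volume <- function(r1, r2, d) {
  t1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h <- r1 - t1
  4 / 3 * pi * r1^3 - ifelse(h > 0, pi * h^2 * (3 * r1 - h) / 3, 0)
}
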