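test_that("isolated atom volume matches the vdW sphere within quadrature error", {
  v16 <- unique_volume(atom_table(0, 0, 0, "C"), 1)$volume
  expect_equal(v16, 20.57953, tolerance = 0.02)
  v48 <- unique_volume(atom_table(0, 0, 0, "C"), 1, fine_grid_n = 48)$volume
  expect_equal(v48, 20.57953, tolerance = 0.005)
  expect_equal(unique_volume(atom_table(0, 0, 0, "C"), 1)$source,
               "explicit-calculation")
})

test_that("two-atom clipping matches the analytic sphere-minus-cap formula", {
  for (d in c(1.2, 1.5, 2.0)) {
    a <- two_atom_pair(d)
    expected <- clipped_sphere_volume(1.7, 1.7, d)
    expect_equal(unique_volume(a, 1)$volume, expected, tolerance = 0.02)
    expect_equal(unique_volume(a, 1, fine_grid_n = 48)$volume, expected,
                 tolerance = 0.005)
  }
  ## unequal radii clip at the radical plane
  a <- two_atom_pair(1.1, elements = c("C", "H"))
  expect_equal(unique_volume(a, 1, fine_grid_n = 48)$volume,
               clipped_sphere_volume(1.7, 1.2, 1.1), tolerance = 0.005)
})

test_that("non-overlapping neighbors do not clip and clipping is monotone", {
  iso <- unique_volume(atom_table(0, 0, 0, "C"), 1)$volume
  far <- two_atom_pair(3.5)     # beyond r1 + r2 = 3.4
  expect_identical(unique_volume(far, 1)$volume, iso)

  ## each added overlapping neighbor can only shrink the volume
  dirs <- list(c(1, 0.2, 0.1), c(-0.3, 1, 0.2), c(0.1, -0.4, 1))
  xyz <- rbind(c(0, 0, 0), t(vapply(dirs, function(u) 1.5 * u / sqrt(sum(u^2)),
                                    numeric(3))))
  prev <- iso
  for (k in 2:4) {
    a <- atom_table(xyz[1:k, 1], xyz[1:k, 2], xyz[1:k, 3], rep("C", k))
    v <- unique_volume(a, 1)$volume
    expect_lte(v, prev + 1e-12)
    prev <- v
  }
})

test_that("identical pairs clip symmetrically and overlaps shrink the total", {
  a <- two_atom_pair(1.5)
  v1 <- unique_volume(a, 1)$volume
  v2 <- unique_volume(a, 2)$volume
  expect_equal(v1, v2, tolerance = 0.01)   # grid quantization only
  expect_lt(v1 + v2, 2 * 20.58)            # strict when spheres overlap

  vols <- unique_volumes(gly3)
  expect_lt(sum(vols$volume),
            sum(4 / 3 * pi * vdw_radius(gly3$element)^3))
  expect_true(all(vols$volume > 0))
})

test_that("degenerate geometries are reported", {
  twin <- atom_table(c(0, 0), c(0, 0), c(0, 0), c("C", "C"))
  expect_warning(unique_volume(twin, 1), "share coordinates")
  ## small atom fully inside a large one
  eng <- atom_table(c(0, 0.3), c(0, 0), c(0, 0), c("H", "FE"))
  expect_warning(v <- unique_volume(eng, 1), "engulfed")
  expect_equal(v$volume, 0)
  expect_error(unique_volume(atom_table(0, 0, 0, "C"), 1, radii = -1),
               "non-positive")
})

test_that("volume dictionary averages per (residue, atom name) key with explicit fallback", {
  ala <- gly3
  ala$residue_name <- "ALA"
  ala$x <- ala$x + 0.05    # slightly different geometry, same atom names
  dict <- build_volume_dictionary(list(gly3, ala))
  expect_s3_class(dict, "volume_dictionary")
  ## same atom name in two residue types -> two distinct entries
  expect_equal(sum(dict$atom_name == "CA"), 2L)
  ## corpus of one model: dictionary means equal per-key explicit means
  d1 <- build_volume_dictionary(list(gly3))
  key <- paste(gly3$residue_name, gly3$atom_name)
  per_key <- tapply(gly3_vols$volume, key, mean)
  expect_equal(d1$volume, as.numeric(per_key[paste(d1$residue_name, d1$atom_name)]),
               tolerance = 1e-12)

  ## lookup hits the dictionary; unknown atoms fall through to explicit
  got <- suppressMessages(volumes_for_model(gly3, dictionary = d1))
  expect_true(all(got$source == "dictionary-lookup"))
  stranger <- rbind(gly3, atom_table(20, 0, 0, "S", "SD", "MET", 9L))
  got2 <- suppressMessages(volumes_for_model(stranger, dictionary = d1))
  expect_equal(sum(got2$source == "explicit-calculation"), 1L)
  expect_equal(got2$volume[nrow(stranger)],
               unique_volume(stranger, nrow(stranger))$volume)

  expect_error(build_volume_dictionary(list()), "empty")

  ## text round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_volume_dictionary(dict, f)
  back <- read_volume_dictionary(f)
  expect_equal(back$volume, dict$volume, tolerance = 1e-6)
})

test_that("volume scale factors multiply selectively and validate", {
  vols <- gly3_vols
  same <- apply_volume_scale_factors(vols, gly3$element, c(H = 1, C = 1, N = 1, O = 1))
  expect_equal(same$volume, vols$volume)
  onlyC <- apply_volume_scale_factors(vols, gly3$element, c(C = 1.1))
  isC <- gly3$element == "C"
  expect_equal(onlyC$volume[isC], vols$volume[isC] * 1.1)
  expect_equal(onlyC$volume[!isC], vols$volume[!isC])
  expect_error(apply_volume_scale_factors(vols, gly3$element, c(C = -1)),
               "non-positive")
  expect_equal(default_scale_factors(), c(H = 1, C = 1, N = 1, O = 1))
})

test_that("scale-factor calibration recovers known factors from noiseless data", {
  truef <- c(H = 1.05, C = 1.10, N = 1.08, O = 1.12)
  sv <- apply_volume_scale_factors(gly3_vols, gly3$element, truef)
  Fv <- sharpen(map_to_structure_factors(in_vacuo_map(gly3, gly3_spec)))
  Fx <- map_to_structure_factors(excluded_volume_map(gly3, sv, gly3_spec))
  Fs <- map_to_structure_factors(shell_map(gly3, gly3_spec))
  prof <- profile_from_terms(binned_cross_terms(Fv, Fx, Fs), 0.334, 1)
  qe <- seq(2 * pi / gly3_spec$side, 0.85 * pi / gly3_spec$voxel, length.out = 300)
  It <- interpolate_profile(prof, qe)$I
  d <- swaxs_profile(qe, It, 0.01 * abs(It))

  f <- suppressWarnings(calibrate_scale_factors(gly3, d, spec = gly3_spec,
                                                base_volumes = gly3_vols))
  expect_equal(unname(f), unname(truef), tolerance = 0.02, ignore_attr = TRUE)
  ## calibration cannot worsen its own objective relative to identity factors
  chi2_identity <- {
    ci <- interpolate_profile(profile_from_terms(gly3_terms, 0.334, 1), qe)
    chi2_profile(d, ci)$chi2
  }
  expect_lte(attr(f, "chi2"), chi2_identity)
  ## identity-factor data recover ~1
  d0 <- swaxs_profile(qe, interpolate_profile(
    profile_from_terms(gly3_terms, 0.334, 1), qe)$I,
    0.01 * abs(It))
  f0 <- suppressWarnings(calibrate_scale_factors(gly3, d0, spec = gly3_spec,
                                                 base_volumes = gly3_vols,
                                                 maxit = 200))
  expect_equal(unname(f0), rep(1, 4), tolerance = 0.02, ignore_attr = TRUE)
})
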