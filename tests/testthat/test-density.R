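test_that("grid builder follows the box and voxel-cap rules", {
  ## Dmax 50 -> side 150, 150 voxels of 1 A
  a <- atom_table(c(0, 50), 0, 0, c("C", "C"))
  sp <- make_grid(a)
  expect_equal(sp$side, 150)
  expect_equal(sp$n, 150L)
  expect_equal(sp$voxel, 1)
  ## Dmax 120 -> 360 A side exceeds 256 voxels -> 256 voxels of 1.40625 A
  b <- atom_table(c(0, 120), 0, 0, c("C", "C"))
  spb <- make_grid(b)
  expect_equal(spb$n, 256L)
  expect_equal(spb$voxel, 1.40625)
  expect_equal(spb$side, 360)
  ## single atom: minimum box
  sp1 <- make_grid(make_single_atom("C"))
  expect_equal(sp1$side, 20)
  ## invariants: side = n * voxel >= 2 Dmax; particle centered
  for (s in list(sp, spb, sp1)) {
    expect_equal(s$side, s$n * s$voxel)
    expect_gte(s$side, 2 * s$dmax)
  }
  ctr <- sp$origin + sp$side / 2
  expect_equal(unname(ctr), c(25, 0, 0))
  ## ~1.5 calculated points per Shannon channel at box_factor 3
  expect_equal((pi / sp$dmax) / (2 * pi / sp$side), 1.5)
})

test_that("in vacuo map conserves electrons to machine precision", {
  for (el in c("H", "C", "O")) {
    a <- make_single_atom(el)
    m <- in_vacuo_map(a, make_grid(a))
    expect_equal(map_integral(m), n_electrons(el), tolerance = 1e-13)
  }
  mg <- in_vacuo_map(gly3, gly3_spec)
  expect_equal(map_integral(mg), sum(n_electrons(gly3$element)),
               tolerance = 1e-13)
  expect_true(all(mg$values >= 0))
  ## occupancy scales deposited electrons
  half <- make_single_atom("C")
  half$occupancy <- 0.5
  expect_equal(map_integral(in_vacuo_map(half, make_grid(half))), 3,
               tolerance = 1e-13)
})

test_that("model B-factors broaden the footprint but preserve electrons", {
  sp <- make_grid(make_single_atom("H"))
  sharp_map <- in_vacuo_map(make_single_atom("H", 0), sp, use_model_b = TRUE)
  broad_map <- in_vacuo_map(make_single_atom("H", 30), sp, use_model_b = TRUE)
  expect_equal(map_integral(sharp_map), 1, tolerance = 1e-13)
  expect_equal(map_integral(broad_map), 1, tolerance = 1e-13)
  expect_lt(max(broad_map$values), max(sharp_map$values))
  expect_gt(sum(broad_map$values > 1e-6), sum(sharp_map$values > 1e-6))
})

test_that("excluded-volume Gaussians integrate to the adjusted volumes", {
  a <- atom_table(0, 0, 0, "C")
  sp <- make_grid(a)
  m <- excluded_volume_map(a, data.frame(volume = 20), sp)
  expect_equal(map_integral(m), 20, tolerance = 0.01)
  ## two distant atoms: integrals add
  a2 <- atom_table(c(0, 12), 0, 0, c("C", "O"))
  m2 <- excluded_volume_map(a2, data.frame(volume = c(20, 15)), make_grid(a2))
  expect_equal(map_integral(m2), 35, tolerance = 0.01)
  ## whole-model integral consistent with the volumes module
  mg <- excluded_volume_map(gly3, gly3_vols, gly3_spec)
  expect_equal(map_integral(mg), sum(gly3_vols$volume), tolerance = 0.01)
  expect_error(excluded_volume_map(a, data.frame(volume = -1), sp),
               "non-positive")
})

test_that("cube-method support is the union of vdW spheres", {
  a <- make_single_atom("C")
  sp <- make_grid(a, voxel_size = 0.25)
  m <- excluded_volume_map_cube(a, sp)
  expect_true(all(m$values %in% c(0, 1)))
  expect_equal(map_integral(m), 20.58, tolerance = 0.02)
  ## overlapping pair: union strictly below the sum of sphere volumes
  pair <- two_atom_pair(1.5)
  mp <- excluded_volume_map_cube(pair, make_grid(pair, voxel_size = 0.25))
  expect_lt(map_integral(mp), 2 * 20.58)
})

test_that("hydration shell peaks one water radius off the surface at the set contrast", {
  a <- make_single_atom("C")
  sp <- make_grid(a, voxel_size = 0.5)
  ms <- shell_map(a, sp)
  sel <- ms$values != 0
  expect_equal(mean(ms$values[sel]), 0.019, tolerance = 1e-12)
  ## no shell density inside the vdW support
  ax <- sp$origin[1] + (seq_len(sp$n) - 0.5) * sp$voxel
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  expect_true(all(ms$values[r <= 1.7] == 0))
  ## contrast maximal near distance water_radius from the surface, decaying both ways
  d <- r - 1.7
  band <- function(lo, hi) mean(ms$values[d > lo & d <= hi])
  expect_gt(band(1.2, 1.6), band(0.1, 0.5))
  expect_gt(band(1.2, 1.6), band(2.8, 3.2))
  ## negative contrast allowed, reported
  expect_message(shell_map(a, sp, mean_contrast = -0.01), "negative")
})

test_that("atoms outside the grid are fatal", {
  a <- make_single_atom("C")
  sp <- make_grid(a)
  far <- atom_table(100, 0, 0, "C")
  expect_error(in_vacuo_map(far, sp), "outside the grid")
})
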