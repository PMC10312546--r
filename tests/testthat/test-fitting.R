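test_that("spline interpolation reproduces nodes and low-degree polynomials", {
  p <- swaxs_profile(seq(0, 2, by = 0.1), (seq(0, 2, by = 0.1))^3 - 2 * seq(0, 2, by = 0.1) + 5)
  qt <- seq(0.05, 1.95, by = 0.07)
  got <- interpolate_profile(p, qt)
  expect_equal(got$I, qt^3 - 2 * qt + 5, tolerance = 1e-10)  # cubic reproduced
  expect_equal(interpolate_profile(p, p$q)$I, p$I)            # nodes exact
  expect_error(interpolate_profile(p, 2.5), "outside")
})

test_that("interpolating a coarse sphere profile matches the analytic curve", {
  ## analytic profile sampled at the calculated-bin spacing of a 120 A box,
  ## splined to intermediate q: sub-half-Nyquist error well below 0.5%
  qc <- seq(0, 1.5, by = 2 * pi / 120)
  p <- swaxs_profile(qc, sphere_intensity(qc, 10))
  qt <- qc[-length(qc)] + diff(qc) / 2
  keep <- qt < 0.7
  got <- interpolate_profile(p, qt[keep])
  expect_equal(got$I, sphere_intensity(qt[keep], 10), tolerance = 0.005)
})

test_that("chi-square contract: scale, offset, and invariances", {
  q <- seq(0.01, 0.5, length.out = 50)
  I <- 100 * exp(-q * 4)
  s <- 0.05 * I
  pe <- swaxs_profile(q, I, s)
  ## identical profiles: c = 1, chi2 = 0
  r <- chi2_profile(pe, swaxs_profile(q, I))
  expect_equal(r$scale_c, 1)
  expect_equal(r$chi2, 0)
  expect_equal(r$offset_b, 0)
  ## pure scale: c recovers the factor, chi2 = 0
  r2 <- chi2_profile(pe, swaxs_profile(q, 2 * I))
  expect_equal(r2$scale_c, 2)
  expect_equal(r2$chi2, 0, tolerance = 1e-20)
  ## printed three-point toy: Icalc = 2.1 * Iexp
  toy_e <- swaxs_profile(1:3, c(10, 5, 2), c(1, 1, 1))
  toy_c <- swaxs_profile(1:3, c(21, 10.5, 4.2))
  r3 <- chi2_profile(toy_e, toy_c)
  expect_equal(r3$scale_c, 2.1)
  expect_equal(r3$chi2, 0, tolerance = 1e-25)
  ## offset applied to the data: c*Iexp + b = Icalc
  r4 <- chi2_profile(pe, swaxs_profile(q, I + 7), fit_offset = TRUE)
  expect_equal(r4$chi2, 0, tolerance = 1e-18)
  expect_equal(r4$offset_b, 7, tolerance = 1e-8)
  ## scale invariance: rescaling data and errors together leaves chi2 unchanged
  noisy <- I * (1 + 0.05 * sin(1:50))
  pn <- swaxs_profile(q, noisy, s)
  pn_scaled <- swaxs_profile(q, 13 * noisy, 13 * s)
  calc <- swaxs_profile(q, I)
  expect_equal(chi2_profile(pn_scaled, calc)$chi2, chi2_profile(pn, calc)$chi2,
               tolerance = 1e-12)
  expect_error(chi2_profile(pe, swaxs_profile(q, rep(0, 50))), "identically zero")
})

test_that("noiseless parameter recovery hits the generating values", {
  d0 <- make_synthetic_data(gly3, rho0 = 0.340, drho = 0.025,
                            noise_fraction = 0, seed = 1,
                            spec = gly3_spec, terms = gly3_terms)
  fit <- fit_parameters(d0, gly3_terms)
  expect_lt(abs(fit$rho0 - 0.340), 0.001)
  expect_lt(abs(fit$drho - 0.025), 0.002)
  expect_lt(fit$chi2, 1e-8)
  expect_true(fit$flags$rho0 && fit$flags$drho)
})

test_that("no-fit mode evaluates the defaults and never beats fitting", {
  d0 <- make_synthetic_data(gly3, rho0 = 0.340, drho = 0.025,
                            noise_fraction = 0, seed = 1,
                            spec = gly3_spec, terms = gly3_terms)
  nofit <- fit_parameters(d0, gly3_terms, fit_rho0 = FALSE, fit_drho = FALSE)
  expect_equal(nofit$rho0, 0.334)
  expect_equal(nofit$drho, 0.019)
  fit <- fit_parameters(d0, gly3_terms)
  expect_gt(nofit$chi2, fit$chi2)
})

test_that("experimental points beyond calculated qmax truncate only on request", {
  d0 <- make_synthetic_data(gly3, noise_fraction = 0.01, seed = 7,
                            spec = gly3_spec, terms = gly3_terms)
  beyond <- swaxs_profile(c(d0$q, max(gly3_terms$q) + 0.5),
                          c(d0$I, 1), c(d0$sigma, 1))
  expect_error(fit_parameters(beyond, gly3_terms), "exceeds calculated qmax")
  fit <- suppressMessages(fit_parameters(beyond, gly3_terms, truncate = TRUE))
  expect_equal(fit$n_points, nrow(d0))
})

test_that("the whole pipeline is deterministic", {
  d1 <- make_synthetic_data(gly3, noise_fraction = 0.01, seed = 42,
                            spec = gly3_spec, terms = gly3_terms)
  d2 <- make_synthetic_data(gly3, noise_fraction = 0.01, seed = 42,
                            spec = gly3_spec, terms = gly3_terms)
  expect_identical(d1$I, d2$I)
  f1 <- fit_parameters(d1, gly3_terms)
  f2 <- fit_parameters(d2, gly3_terms)
  expect_identical(f1$chi2, f2$chi2)
  expect_identical(f1$rho0, f2$rho0)
})

test_that("fit file records scaled data and parameters", {
  d0 <- make_synthetic_data(gly3, noise_fraction = 0.01, seed = 3,
                            spec = gly3_spec, terms = gly3_terms)
  fit <- fit_parameters(d0, gly3_terms)
  f <- withr::local_tempfile(fileext = ".fit")
  write_fit(fit, f)
  lines <- readLines(f)
  expect_match(lines[1], "rho0")
  body <- read.table(f, comment.char = "#")
  expect_equal(ncol(body), 4L)
  expect_equal(body[[1]], d0$q, tolerance = 1e-7)
  expect_equal(body[[2]], fit$scale_c * d0$I + fit$offset_b, tolerance = 1e-6)
})
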