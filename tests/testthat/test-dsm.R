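test_that("detector's-eye view follows back-projection geometry", {
  g <- machine_geometry()
  # symmetric jaw square: DEV side from the similar-triangle magnification
  fld <- field_spec(jaw_square(10))
  dev <- dev_region(fld, g)
  mag <- (g$scd_x / g$sad) * (g$sad - g$ff_dist) / (g$sad - g$scd_x)
  expect_equal(dev$slabs$x_hi - dev$slabs$x_lo, 10 * mag, tolerance = 1e-12)
  expect_equal(poly_area(dev), (10 * mag)^2, tolerance = 1e-12)
  # closed jaws block the view entirely
  expect_equal(poly_area(dev_region(field_spec(jaw_setting(0, 0, -5, 5)), g)),
               0)
  # jaws wide open: the region is bounded only by the primary-collimator cap
  wide <- dev_region(field_spec(jaw_setting(-90, 90, -90, 90)), g,
                     cap_step = 0.01)
  expect_equal(poly_area(wide), pi * g$cap_radius^2, tolerance = 1e-3)
  # MLC leaves narrow the view when included
  mfld <- field_spec(jaw_square(20), mlc_bank_square(6))
  a_with <- poly_area(dev_region(mfld, g, include_mlc = TRUE))
  a_without <- poly_area(dev_region(mfld, g, include_mlc = FALSE))
  expect_lt(a_with, a_without)
})

test_that("extra-focal ratio integrates the Gaussian over the DEV", {
  g <- machine_geometry()
  p <- dsm_params(0.08, 1.3, 0)
  # a practically unbounded view captures the whole Gaussian mass
  wide <- field_spec(jaw_setting(-90, 90, -90, 90))
  expect_equal(f_efs(wide, p, g), p$k_ff, tolerance = 1e-6)
  # half-plane through the axis: half the mass (construct via jaw x1 = 0)
  half <- field_spec(jaw_setting(0, 90, -90, 90))
  expect_equal(f_efs(half, p, g), p$k_ff / 2, tolerance = 1e-6)
  # centered square of side 2 sigma at the source plane vs the grid oracle
  mag <- (g$scd_x / g$sad) * (g$sad - g$ff_dist) / (g$sad - g$scd_x)
  side_iso <- 2 * p$sigma_ff / mag
  sq <- field_spec(jaw_setting(-side_iso / 2, side_iso / 2,
                               -side_iso / 2, side_iso / 2))
  dev <- dev_region(sq, g)
  oracle <- p$k_ff * gaussian_grid_oracle(dev$slabs, p$sigma_ff, cell = 0.02)
  expect_equal(f_efs(sq, p, g), oracle, tolerance = 1e-4)
})

test_that("monitor backscatter is linear in the blocked jaw area", {
  p <- dsm_params(0.05, 1.5, 1e-5)
  expect_equal(f_mbs(jaw_square(40), p), 0)
  expect_equal(f_mbs(jaw_square(10), dsm_params(0.05, 1.5, 0)), 0)
  expect_equal(f_mbs(jaw_square(10), p), 0.015)
})

test_that("dual-source Sc normalizes at the reference field", {
  g <- machine_geometry()
  p <- reference_dsm_params()
  expect_identical(sc_dsm(reference_field(), p, g), 1)
  # degenerate parameters give unity for every field
  p0 <- dsm_params(0, 1, 0)
  for (s in c(4, 10, 25, 40))
    expect_equal(sc_dsm(field_spec(jaw_square(s)), p0, g), 1)
  # non-decreasing in the jaw side for square fields
  sc <- vapply(4:40, function(s)
    sc_dsm(field_spec(jaw_square(s)), p, g), numeric(1))
  expect_true(all(diff(sc) > -1e-12))
})

test_that("dual-source fitting recovers known parameters", {
  g <- machine_geometry()
  truth <- reference_dsm_params()
  design <- campaign_design(jaw_squares = seq(4, 40, by = 2),
                            rect_fixed = 10, rect_varied = seq(4, 40, by = 4),
                            mlc_jaws = integer(0), irregular_jaws = integer(0),
                            noise_sd = 0)
  tab <- simulate_campaign(design, truth = list(dsm = truth, mlc = NULL),
                           geom = g, noise_sd = 0, seed = 11)
  tab$sd <- 0.002 * tab$sc
  fit <- fit_dsm(tab, g)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 400)
  expect_equal(fit$params$k_ff, truth$k_ff, tolerance = 1e-3)
  expect_equal(fit$params$sigma_ff, truth$sigma_ff, tolerance = 1e-3)
  expect_equal(fit$params$k_b, truth$k_b, tolerance = 1e-3 * truth$k_b)
})

test_that("dual-source fitting validates its inputs", {
  g <- machine_geometry()
  one <- data.frame(field_id = "a", jaw_x1 = -5, jaw_x2 = 5, jaw_y1 = -5,
                    jaw_y2 = 5, mlc_spec = "retracted", sc = 1, sd = 0.002)
  expect_error(fit_dsm(one, g), "at least 3")
  norf <- do.call(rbind, lapply(c(4, 6, 8), function(s)
    data.frame(field_id = paste0("j", s), jaw_x1 = -s / 2, jaw_x2 = s / 2,
               jaw_y1 = -s / 2, jaw_y2 = s / 2, mlc_spec = "retracted",
               sc = 1, sd = 0.002)))
  expect_error(fit_dsm(norf, g), "reference")
})
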