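test_that("simple apertures have the expected area and perimeter", {
  sq <- mlc_polygon(mlc_bank_square(10), jaw_square(10), 100)
  expect_equal(poly_area(sq), 100)
  expect_equal(poly_perimeter(sq), 40)
  closed <- mlc_bank(rep(0, 60), rep(0, 60))
  expect_equal(poly_area(mlc_polygon(closed, jaw_square(10), 100)), 0)
  # closed-pair tolerance: a 0.05 cm gap contributes nothing
  tiny <- mlc_bank(rep(-0.025, 60), rep(0.025, 60))
  expect_equal(poly_area(mlc_polygon(tiny, jaw_square(10), 100)), 0)
})

test_that("cross template matches the shoelace oracle", {
  J <- 20
  poly <- mlc_polygon(mlc_bank_template("cross", J), jaw_square(J), 100)
  # leaf-quantized outline: full width |y| <= 3.5, arms of half-width J/6
  w <- J / 6
  outline <- rbind(c(10, -3.5), c(10, 3.5), c(w, 3.5), c(w, 10),
                   c(-w, 10), c(-w, 3.5), c(-10, 3.5), c(-10, -3.5),
                   c(-w, -3.5), c(-w, -10), c(w, -10), c(w, -3.5))
  expect_equal(poly_area(poly), shoelace_area(outline), tolerance = 1e-9)
  m <- rect_union_metrics(poly_to_rects(poly))
  expect_equal(poly_perimeter(poly), m$perimeter, tolerance = 1e-9)
})

test_that("exposed MLC area subtracts the MLC field from the jaw field", {
  jaw <- jaw_square(20)
  retracted <- mlc_polygon(mlc_bank_retracted(20.5), jaw, 100)
  expect_equal(exposed_mlc_area(jaw, retracted), 0)
  same <- mlc_polygon(mlc_bank_square(20), jaw, 100)
  expect_equal(exposed_mlc_area(jaw, same), 0)
  p51 <- mlc_polygon(mlc_bank_square(10), jaw, 51)
  expect_equal(exposed_mlc_area(jaw, p51), (400 - 100) * 0.51^2,
               tolerance = 1e-12)
})

test_that("interface split handles containment, identity, and straddling", {
  g <- machine_geometry()
  jaw <- jaw_square(20)
  ifc <- scatter_interface(g, jaw)
  # MLC square well inside the interface: all perimeter is "in"
  poly <- mlc_polygon(mlc_bank_square(8), jaw, 51)
  m <- split_by_interface(poly, jaw, ifc)
  expect_equal(m$fp_in, poly_perimeter(poly))
  expect_equal(m$fp_out, 0)
  expect_equal(m$rp, rect_perimeter(ifc))
  expect_equal(m$ra_out, rect_area(ifc))
  expect_equal(m$ra_in, 9 * 0.51^2)
  # polygon equal to the interface: boundary counts inward
  iface_poly <- mlc_polygon(NULL, jaw_setting(ifc$x_lo, ifc$x_hi,
                                              ifc$y_lo, ifc$y_hi),
                            51, iso_dist = 51)
  mi <- split_by_interface(iface_poly, jaw, ifc)
  expect_equal(mi$fp_in, rect_perimeter(ifc))
  expect_equal(mi$fp_out, 0)
  expect_equal(mi$ma_in, 0)
  # square straddling one interface edge agrees with the segment-clip oracle
  bank <- mlc_bank_square(10)
  shifted <- mlc_bank(bank$left + 4, bank$right + 4, bank$edges)
  poly2 <- mlc_polygon(shifted, jaw, 51)
  m2 <- split_by_interface(poly2, jaw, ifc)
  o <- segment_clip_oracle(poly2, ifc)
  expect_equal(m2$fp_in, o$fp_in, tolerance = 1e-9)
  expect_equal(m2$fp_out, o$fp_out, tolerance = 1e-9)
  expect_error(split_by_interface(mlc_polygon(bank, jaw, 100), jaw, ifc),
               "same plane")
})

test_that("split metrics conserve totals on random apertures", {
  set.seed(401)
  g <- machine_geometry()
  for (k in 1:60) {
    ap <- random_aperture()
    poly <- mlc_polygon(ap$bank, ap$jaw, 51)
    ifc <- scatter_interface(g, ap$jaw)
    m <- split_by_interface(poly, ap$jaw, ifc)
    per <- poly_perimeter(poly)
    expect_equal(m$fp_in + m$fp_out, per, tolerance = 1e-9 * max(per, 1))
    tot <- exposed_mlc_area(ap$jaw, poly)
    expect_equal(m$ma_in + m$ma_out, tot, tolerance = 1e-9 * max(tot, 1))
    expect_true(all(c(m$fp_in, m$fp_out, m$ma_in, m$ma_out) >= -1e-12))
    # union-sweep oracle for the slab polygon itself
    u <- rect_union_metrics(poly_to_rects(poly))
    expect_equal(poly_area(poly), u$area, tolerance = 1e-9 * max(u$area, 1))
    expect_equal(per, u$perimeter, tolerance = 1e-9 * max(u$perimeter, 1))
  }
})

test_that("projection scales perimeter linearly and area quadratically", {
  bank <- mlc_bank_template("mirrored_e", 20)
  p100 <- mlc_polygon(bank, jaw_square(20), 100)
  p51 <- mlc_polygon(bank, jaw_square(20), 51)
  expect_equal(poly_perimeter(p51), poly_perimeter(p100) * 0.51,
               tolerance = 1e-12)
  expect_equal(poly_area(p51), poly_area(p100) * 0.51^2, tolerance = 1e-12)
})

test_that("fields classify into the three BEV/interface categories", {
  g <- machine_geometry()
  jaw <- jaw_square(20)
  ifc <- scatter_interface(g, jaw)
  expect_equal(classify_category(jaw, NULL, ifc), 1L)
  expect_equal(classify_category(jaw, mlc_bank_retracted(20.5), ifc), 1L)
  # MLC field larger than the interface but inside the BEV
  expect_equal(classify_category(jaw, mlc_bank_square(15), ifc), 2L)
  # MLC field smaller than the interface
  expect_equal(classify_category(jaw, mlc_bank_square(8), ifc), 3L)
  # tips exactly on the jaw edge still count as shaping the field
  expect_equal(classify_category(jaw, mlc_bank_square(20), ifc), 2L)
  # retraction must be strict on both banks
  half <- mlc_bank(rep(-10, 60), rep(25, 60))
  expect_equal(classify_category(jaw, half, ifc), 2L)
})

test_that("field files round-trip leaf positions and shorthands", {
  path <- withr::local_tempfile(fileext = ".yaml")
  fld <- field_spec(jaw_square(15), mlc_bank_template("maze", 15), id = "mz")
  write_field_file(fld, path)
  fld2 <- read_field_file(path)
  expect_equal(fld2$bank$left, fld$bank$left)
  expect_equal(fld2$bank$right, fld$bank$right)
  expect_equal(fld2$id, "mz")
  yaml::write_yaml(list(jaw = list(x1 = -5, x2 = 5, y1 = -5, y2 = 5),
                        mlc = list(mlc_square = 4)), path)
  fld3 <- read_field_file(path)
  expect_equal(poly_area(mlc_polygon(fld3$bank, fld3$jaw, 100)), 16)
  yaml::write_yaml(list(mlc = "retracted"), path)
  expect_error(read_field_file(path), "jaw")
})
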