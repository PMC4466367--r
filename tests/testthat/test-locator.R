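test_that("points outside the annulus or the helix shell never hit", {
  m <- build_conformation("B")
  roi <- m$roi
  h2 <- roi$height_nm / 2
  # ROI axis, inner/outer of the annulus, above/below
  loc <- locate_events(m,
                       x = c(0, 4000, 5200, 5000, 5000),
                       y = c(0, 0, 0, 0, 0),
                       z = c(h2, h2, h2, -1, roi$height_nm + 1))
  expect_true(all(!loc$hit))
  expect_true(all(is.na(loc$fragment)))
  # a point exactly on a nucleosome loop path is inside the bp core
  pt <- target_placement(m, 0, 0, 0, 10, 0, r_frac = 0.5)
  on_path <- target_placement(m, 0, 0, 0, 10, 0)
  # construct the path point by placing at r -> 0 is not allowed by the
  # sector; instead verify that radii below r_min are rejected via a point
  # nudged onto the path from the placement geometry
  frame_pt <- locate_events(m, pt$x_nm, pt$y_nm, pt$z_nm)
  expect_true(frame_pt$hit)
  expect_error(locate_events(m, NaN, 0, 0), "finite")
})

test_that("locator inverts placement over random interior points", {
  set.seed(31)
  for (lbl in c("A", "B", "Z")) {
    m <- build_conformation(lbl)
    n <- 1200
    ad <- random_addresses(m, n)
    ok <- roundtrip_ok(m, ad, boundary_fracs(n), boundary_fracs(n),
                       boundary_fracs(n))
    expect_true(all(ok), label = paste(lbl, "round-trip"))
  }
})

test_that("reference points of extreme addresses round-trip", {
  for (lbl in c("A", "B", "Z")) {
    m <- build_conformation(lbl)
    nbp <- m$params$bp_per_nucleosome
    ad <- expand.grid(fragment = c(0, 899), level = c(0, 499),
                      nucleosome = c(0, 5),
                      bp = c(0, m$per_loop - 1, m$per_loop, nbp - 1),
                      strand = 0:1)
    ok <- roundtrip_ok(m, ad, 0.5, 0.5, 0.5)
    expect_true(all(ok), label = paste(lbl, "extreme addresses"))
  }
})

test_that("the azimuthal seam resolves continuously", {
  m <- build_conformation("B")
  r <- m$roi$central_radius_nm
  eps <- 1e-9
  loc <- locate_events(m,
                       x = c(r, r),
                       y = c(-eps * r, eps * r),
                       z = c(2000, 2000))
  expect_equal(nrow(loc), 2L)  # both sides of the seam resolve w/o error
  # fragment resolution across the seam via boundary-fragment placements
  p0 <- target_placement(m, 0, 10, 0, 5, 0)
  p899 <- target_placement(m, 899, 10, 0, 5, 0)
  l0 <- locate_events(m, p0$x_nm, p0$y_nm, p0$z_nm)
  l899 <- locate_events(m, p899$x_nm, p899$y_nm, p899$z_nm)
  expect_equal(l0$fragment, 0L)
  expect_equal(l899$fragment, 899L)
})

test_that("out-of-range addresses are rejected", {
  m <- build_conformation("A")
  expect_error(target_placement(m, 900, 0, 0, 0, 0), "address")
  expect_error(target_placement(m, 0, 500, 0, 0, 0), "address")
  expect_error(target_placement(m, 0, 0, 6, 0, 0), "address")
  expect_error(target_placement(m, 0, 0, 0, 286, 0), "address")
  expect_error(target_placement(m, 0, 0, 0, 0, 2), "address")
})

test_that("left- and right-handed locators are mirror consistent", {
  # a left-handed helix reflected through a plane containing the fiber
  # axis is a right-handed helix with phase advanced by the loop-closure
  # twist; hit/miss must be preserved point by point
  zdim <- dnabreaksim:::.DNA_TABLE$Z
  left <- conformation_params("Zl", "left", zdim$dna_diameter,
                              zdim$bp_diameter, zdim$bp_axial_step,
                              zdim$bp_per_turn, zdim$helix_pitch,
                              zdim$bp_per_nucleosome, 0,
                              zdim$target_aperture, zdim$target_height,
                              helix_phase = 0)
  m_left <- build_conformation(left, slot_level_offset_deg = 0)
  phase_r <- (m_left$per_loop * m_left$twist_per_bp_deg) %% 360
  right <- conformation_params("Zr", "right", zdim$dna_diameter,
                               zdim$bp_diameter, zdim$bp_axial_step,
                               zdim$bp_per_turn, zdim$helix_pitch,
                               zdim$bp_per_nucleosome, 0,
                               zdim$target_aperture, zdim$target_height,
                               helix_phase = phase_r)
  m_right <- build_conformation(right, slot_level_offset_deg = 0)
  set.seed(5)
  # points concentrated near the chromatin shell so that hits occur
  cfg <- generator_config("uniform", n_events = 4e4, seed = 5)
  es <- sample_uniform(cfg)$events
  l1 <- locate_events(m_left, es$x_nm, es$y_nm, es$z_nm)
  l2 <- locate_events(m_right, es$x_nm, -es$y_nm, es$z_nm)
  expect_gt(sum(l1$hit), 300)             # the comparison is non-vacuous
  expect_equal(l1$hit, l2$hit)
})

test_that("bp separation is defined only within one nucleosome", {
  a <- data.frame(fragment = 1, level = 2, nucleosome = 3, bp = 5, strand = 0)
  b <- data.frame(fragment = 1, level = 2, nucleosome = 3, bp = 12, strand = 1)
  expect_equal(bp_separation(a, a), 0)
  expect_equal(bp_separation(a, b), 7)
  b$nucleosome <- 4
  expect_true(is.na(bp_separation(a, b)))
  b$nucleosome <- 3; b$level <- 3
  expect_true(is.na(bp_separation(a, b)))
})

test_that("event CSV round-trips through the schema", {
  cfg <- generator_config("uniform", n_events = 50, seed = 2)
  es <- sample_uniform(cfg)
  path <- tempfile(fileext = ".csv")
  write_event_csv(es, path)
  back <- read_event_csv(path)
  expect_equal(back$history, es$events$history)
  expect_equal(back$particle, es$events$particle)
  expect_equal(back$x_nm, es$events$x_nm, tolerance = 1e-12)
  expect_equal(back$energy_ev, es$events$energy_ev, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_event_csv(bad), "columns")
})
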