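test_that("sector volume follows the closed form and rejects bad input", {
  # B-DNA sugar-phosphate sector, independent arithmetic
  expect_equal(sector_volume(73, 1.185, 0.5, 0.183),
               (73 / 360) * pi * (1.185^2 - 0.5^2) * 0.183)
  # degenerate full cylinder
  expect_equal(sector_volume(360, 2, 0, 1.5), pi * 4 * 1.5)
  expect_error(sector_volume(0, 1, 0.5, 1), "aperture")
  expect_error(sector_volume(90, 1, 1.2, 1), "r_min")
  expect_error(sector_volume(90, 1, 0.5, -1), "positive")
})

test_that("per-target volumes round to the tabulated values", {
  v <- vapply(c("A", "B", "Z"),
              function(l) build_conformation(l)$target_volume, numeric(1))
  expect_equal(round(unname(v), 2), c(0.12, 0.13, 0.10))
})

test_that("sector volume agrees with a rejection-sampling MC estimate", {
  set.seed(101)
  for (lbl in c("A", "B", "Z")) {
    m <- build_conformation(lbl)
    mc <- mc_sector_volume(m$params$target_aperture, m$r_max, m$r_min,
                           m$params$target_height, n = 3e5)
    expect_lt(abs(m$target_volume - mc$value), 3 * mc$se,
              label = paste(lbl, "analytic vs MC sector volume"))
  }
})

test_that("conformation parameters enforce their geometric invariants", {
  z <- dna_conformation_params("Z")
  expect_identical(z$handedness, "left")
  expect_identical(dna_conformation_params("A")$handedness, "right")
  for (lbl in c("A", "B", "Z")) {
    p <- dna_conformation_params(lbl)
    expect_lt(p$target_height, p$bp_axial_step)
    expect_lt(p$bp_diameter, p$dna_diameter)
  }
  expect_error(conformation_params("X", "right", 2, 1, 0.3, 10, 3, 200,
                                   1, 70, 0.4), "target_height")
  expect_error(conformation_params("X", "right", 2, 2.5, 0.3, 10, 3, 200,
                                   1, 70, 0.2), "bp_diameter")
  expect_error(conformation_params("X", "right", 2, 1, 0.3, 10, 3, 201,
                                   1, 70, 0.2), "even")
})

test_that("structural totals match the tabulated genome content", {
  expect_equal(build_conformation("A")$n_nucleosomes, 900 * 500 * 6)
  expect_equal(build_conformation("A")$n_nucleosomes, 2.7e6)
  totals <- vapply(c("A", "B", "Z"),
                   function(l) build_conformation(l)$total_bp, numeric(1))
  expect_equal(signif(unname(totals), 3), c(7.72e8, 5.35e8, 4.64e8))
  m <- build_conformation("B")
  expect_equal(m$n_targets, 2 * m$total_bp)
  expect_equal(m$total_bp, m$n_nucleosomes * m$params$bp_per_nucleosome)
})

test_that("nucleosome path radius carries the full loop arc length", {
  m <- build_conformation("B")
  expect_equal(m$nucleosome_path_radius, 198 * 0.33 / (4 * pi))
  # two full loops of this radius have arc length bp_per_nucleosome * step
  expect_equal(2 * 2 * pi * m$nucleosome_path_radius,
               m$params$bp_per_nucleosome * m$params$bp_axial_step)
  expect_equal(build_conformation("Z")$twist_per_bp_deg, -30)
  expect_equal(build_conformation("B")$twist_per_bp_deg, 36)
})

test_that("ROI volume and mass follow from independent arithmetic", {
  roi <- roi_params()
  expect_equal(roi_volume(roi), pi * (5015^2 - 4985^2) * 5250)
  expect_equal(roi_volume(roi), pi * 10000 * 30 * 5250) # thin-annulus form
  expect_equal(roi_volume(roi_params(radial_thickness_nm = 0)), 0)
  # 4.948e9 nm^3 of water at 1.06 g/cm^3
  expect_equal(roi_mass(roi), roi_volume(roi) * 1e-21 * 1.06 * 1e-3)
  expect_equal(signif(roi_mass(roi), 3), 5.24e-15)
  expect_equal(roi_mass(roi_params(density_g_cm3 = 0)), 0)
})

test_that("predicted hit probability is the target/ROI volume ratio", {
  for (lbl in c("A", "B", "Z")) {
    m <- build_conformation(lbl)
    expect_equal(predicted_hit_probability(m),
                 2 * m$total_bp * m$target_volume / roi_volume(m$roi))
  }
  # ratio for B close to the 0.029 consistency value
  expect_equal(round(predicted_hit_probability(build_conformation("B")), 3),
               0.029)
})

test_that("geometry report collects one row per conformation", {
  rep <- geometry_report()
  expect_equal(rep$conformation, c("A", "B", "Z"))
  expect_true(all(rep$predicted_hit_probability ==
                    rep$total_target_volume_nm3 / rep$roi_volume_nm3))
})

test_that("targets of one nucleosome are disjoint and stay in the ROI", {
  # sampled interior points of every target of one nucleosome must locate
  # back to their own address (disjointness + containment + inversion)
  set.seed(7)
  for (lbl in c("A", "B", "Z")) {
    m <- build_conformation(lbl)
    nbp <- m$params$bp_per_nucleosome
    per_target <- 25
    ad <- expand.grid(bp = 0:(nbp - 1), strand = 0:1)
    ad <- ad[rep(seq_len(nrow(ad)), each = per_target), ]
    n <- nrow(ad)
    pt <- target_placement(m, 450, 250, 3, ad$bp, ad$strand,
                           r_frac = boundary_fracs(n),
                           ang_frac = boundary_fracs(n),
                           s_frac = boundary_fracs(n))
    expect_true(all(in_roi(m$roi, pt$x_nm, pt$y_nm, pt$z_nm)))
    loc <- locate_events(m, pt$x_nm, pt$y_nm, pt$z_nm)
    expect_true(all(loc$hit))
    expect_true(all(loc$nucleosome == 3 & loc$bp == ad$bp &
                      loc$strand == ad$strand))
  }
})

test_that("twist angle repeats after one full helical turn", {
  # B-DNA has an integer number of bp per turn, so bp i and i+10 share
  # their angular position exactly
  m <- build_conformation("B")
  a1 <- target_placement(m, 0, 0, 0, 20, 0)
  a2 <- target_placement(m, 0, 0, 0, 30, 0)
  # equal twist mod 360: both placements have the same local sector angle,
  # so their radial offsets from the loop plane agree
  f1 <- dnabreaksim:::.address_frame(m, 0, 0, 20, 0)
  f2 <- dnabreaksim:::.address_frame(m, 0, 0, 30, 0)
  expect_equal(dnabreaksim:::.ang_diff(f1$theta, f2$theta), 0)
})

test_that("energy bookkeeping for the 100 Gy protocol is consistent", {
  expect_equal(signif(dose_to_energy_ev(100), 2), 3.3e6)
  expect_equal(dose_to_energy_ev(0), 0)
  # linearity
  expect_equal(dose_to_energy_ev(60) + dose_to_energy_ev(40),
               dose_to_energy_ev(100))
})
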