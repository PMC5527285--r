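test_that("nuclear intensity subtracts the background mode", {
  lab <- matrix(0L, 60, 60); lab[10:25, 10:25] <- 1L; lab[35:50, 35:50] <- 2L
  img <- matrix(2, 60, 60)
  img[lab == 1] <- 10
  img[lab == 2] <- 6
  res <- nuclear_intensity(img, lab)
  expect_equal(res$mean_intensity, c(8, 4))
  expect_equal(res$background[1], 2, tolerance = 0.05)
  raw <- nuclear_intensity(img, lab, subtract_background = FALSE)
  expect_equal(raw$mean_intensity, c(10, 6))
  expect_equal(nrow(nuclear_intensity(img, matrix(0L, 60, 60))), 0)
  expect_error(nuclear_intensity(img, matrix(0L, 10, 10)), "mismatch")
})

test_that("normalization to control is exact and idempotent", {
  expect_equal(normalize_to_control(c(3, 6), c(2, 4)), c(1, 2))
  v <- c(1.2, 0.4, 2.2, 0.9)
  n1 <- normalize_to_control(v, v)
  expect_equal(mean(n1), 1)
  expect_equal(normalize_to_control(n1, n1), n1, tolerance = 1e-12)
  expect_equal(normalize_to_control(0, c(1, 1, 1)), 0)
  expect_error(normalize_to_control(1, numeric(0)), "empty")
  expect_error(normalize_to_control(1, c(-2, 0)), "positive")
})

test_that("focus positivity is strict at more than five foci", {
  sim <- spot_field()
  counts <- rep(c(5L, 6L), 8)
  mk <- simulate_marker_channel(sim$label, pixel_size = 0.2,
                                spot_counts = counts, base_intensity = 5,
                                spot_snr = 12, seed = 31)
  fr <- detect_foci(mk$image, sim$label, pixel_size = 0.2)
  expect_equal(fr$focus_count, counts)
  expect_equal(fr$positive, counts > 5)
  # zero-spot nuclei are negative with count 0
  mk0 <- simulate_marker_channel(sim$label, pixel_size = 0.2,
                                 spot_counts = 0, base_intensity = 5,
                                 seed = 32)
  fr0 <- detect_foci(mk0$image, sim$label, pixel_size = 0.2)
  expect_true(all(fr0$focus_count == 0))
  expect_true(all(!fr0$positive))
})

test_that("exact focus-count recovery across 0-15 spots at snr 8", {
  sim <- spot_field()
  counts <- rep(c(0, 3, 5, 6, 8, 12, 15, 2), 2)
  exact <- c(); posrec <- c()
  for (s in 101:103) {
    mk <- simulate_marker_channel(sim$label, pixel_size = 0.2,
                                  spot_counts = counts, base_intensity = 5,
                                  spot_snr = 8, seed = s)
    fr <- detect_foci(mk$image, sim$label, pixel_size = 0.2)
    exact <- c(exact, fr$focus_count == mk$truth$true_spot_count)
    posrec <- c(posrec, fr$positive == (mk$truth$true_spot_count > 5))
  }
  expect_gte(mean(exact), 0.9)
  expect_gte(mean(posrec), 0.98)
})

test_that("focus counting is invariant to a constant image offset", {
  sim <- spot_field()
  mk <- simulate_marker_channel(sim$label, pixel_size = 0.2,
                                spot_counts = rep(c(2, 7), 8),
                                base_intensity = 5, seed = 41)
  a <- detect_foci(mk$image, sim$label, pixel_size = 0.2)
  b <- detect_foci(mk$image + 37.5, sim$label, pixel_size = 0.2)
  expect_equal(a, b)
  expect_error(detect_foci(mk$image, sim$label, pixel_size = 0.2,
                           params = foci_params(d_min_um = 1, d_max_um = 0.5)),
               "d_min_um")
})

test_that("cytoplasmic aggregates are counted outside the nucleus only", {
  sim <- simulate_nucleus_image(image_spec(
    n_nuclei = 1, width = 256, height = 256,
    phenotype_mix = c(normal = 1), seed = 13))
  nuc <- sim$label == 1
  cells <- cell_masks_from_nuclei(sim$label, radius_px = 14)
  cell <- cells == 1
  cyto_lab <- matrix(0L, 256, 256); cyto_lab[cell & !nuc] <- 1L
  mk <- simulate_marker_channel(cyto_lab, pixel_size = 0.2, spot_counts = 3,
                                spot_diameter_um = 0.5, base_intensity = 1,
                                spot_snr = 12, seed = 51)
  res <- cytoplasmic_aggregates(mk$image, nuc, cell, pixel_size = 0.2)
  expect_equal(res$aggregate_count, 3)
  expect_true(res$positive)
  # aggregates only inside the nucleus: none detected in the cytoplasm
  nuc_lab <- matrix(0L, 256, 256); nuc_lab[nuc] <- 1L
  mkn <- simulate_marker_channel(nuc_lab, pixel_size = 0.2, spot_counts = 3,
                                 spot_diameter_um = 0.5, base_intensity = 1,
                                 spot_snr = 12, seed = 52)
  resn <- cytoplasmic_aggregates(mkn$image, nuc, cell, pixel_size = 0.2)
  expect_equal(resn$aggregate_count, 0)
  # empty cytoplasmic band
  rese <- cytoplasmic_aggregates(mk$image, nuc, nuc, pixel_size = 0.2)
  expect_equal(rese$aggregate_count, 0)
  expect_error(cytoplasmic_aggregates(mk$image, cell, nuc, pixel_size = 0.2),
               "contained")
})

test_that("a 2x group intensity effect is recovered after normalization", {
  sp1 <- image_spec(n_nuclei = 25, width = 640, height = 640,
                    phenotype_mix = c(normal = 1), seed = 11)
  sp2 <- image_spec(n_nuclei = 25, width = 640, height = 640,
                    phenotype_mix = c(normal = 1), seed = 12)
  s1 <- simulate_nucleus_image(sp1)
  s2 <- simulate_nucleus_image(sp2)
  mc <- simulate_marker_channel(s1$label, spot_counts = 0,
                                base_intensity = 5, seed = 21)
  md <- simulate_marker_channel(s2$label, spot_counts = 0,
                                base_intensity = 10, seed = 22)
  ic <- nuclear_intensity(mc$image, s1$label)
  idep <- nuclear_intensity(md$image, s2$label)
  ctrl_norm <- normalize_to_control(ic$mean_intensity, ic$mean_intensity)
  dep_norm <- normalize_to_control(idep$mean_intensity, ic$mean_intensity)
  expect_equal(mean(ctrl_norm), 1)
  expect_equal(mean(dep_norm), 2, tolerance = 0.05)
})
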