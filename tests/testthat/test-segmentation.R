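test_that("segmentation recovers generated nuclei with high overlap", {
  sim <- simulate_nucleus_image(image_spec(
    n_nuclei = 20, width = 640, height = 640,
    phenotype_mix = c(normal = 1), snr = 10, seed = 1))
  seg <- segment_nuclei(sim$image[, , 1], pixel_size = 0.2)
  expect_equal(nrow(seg$records), 20)
  mt <- match_to_truth(seg$label, sim$label)
  ious <- vapply(seq_len(20), function(id) {
    a <- seg$label == id; b <- sim$label == mt[id]
    sum(a & b) / sum(a | b)
  }, numeric(1))
  expect_true(all(ious >= 0.8))
})

test_that("a blank image yields zero objects, not an error", {
  seg <- segment_nuclei(matrix(0, 100, 100), pixel_size = 0.2)
  expect_equal(nrow(seg$records), 0)
  expect_equal(max(seg$label), 0)
  expect_error(segment_nuclei(array(0, c(10, 10, 2)), pixel_size = 0.2),
               "2D")
})

test_that("thin bridges keep fragmented nuclei single 8-connected objects", {
  sim <- simulate_nucleus_image(image_spec(
    n_nuclei = 10, width = 640, height = 640,
    phenotype_mix = c(fragmented = 1), seed = 2))
  # ground-truth masks are single components under 8-connectivity even
  # when the bridge is locally diagonal
  seg <- segment_nuclei(sim$image[, , 1], pixel_size = 0.2)
  mt <- match_to_truth(seg$label, sim$label)
  expect_equal(sort(unique(mt)), 1:10)
  expect_equal(nrow(seg$records), 10)
})

test_that("segmentation is idempotent on its own output mask", {
  sim <- mixed_field()
  seg1 <- segment_nuclei(sim$image[, , 1], pixel_size = 0.2)
  seg2 <- segment_nuclei((seg1$label > 0) + 0, pixel_size = 0.2)
  expect_equal(nrow(seg2$records), nrow(seg1$records))
  iou <- sum(seg1$label > 0 & seg2$label > 0) /
    sum(seg1$label > 0 | seg2$label > 0)
  expect_gt(iou, 0.995)
})

test_that("coverage: full rim = 1, absent envelope = 0, geometry checked", {
  sim <- simulate_nucleus_image(image_spec(
    n_nuclei = 5, width = 512, height = 512,
    phenotype_mix = c(normal = 1), seed = 7))
  cov <- assess_envelope_coverage(sim$label, sim$clean[, , 2], 0.2)
  expect_true(all(cov$envelope_coverage == 1))
  expect_true(all(cov$uncovered_dna_fraction == 0))
  zero <- assess_envelope_coverage(sim$label,
                                   matrix(0, 512, 512), 0.2)
  expect_true(all(zero$envelope_coverage == 0))
  expect_true(all(zero$uncovered_dna_fraction == 1))
  expect_error(assess_envelope_coverage(sim$label, matrix(0, 10, 10), 0.2),
               "mismatch")
})

test_that("coverage is invariant to uniform rescaling of the envelope", {
  sim <- mixed_field()
  seg <- segment_nuclei(sim$image[, , 1], pixel_size = 0.2)
  c1 <- assess_envelope_coverage(seg$label, sim$image[, , 2], 0.2)
  c2 <- assess_envelope_coverage(seg$label, sim$image[, , 2] * 11.3, 0.2)
  expect_equal(c1, c2)
})

test_that("phenotype classification follows the threshold definitions", {
  rec <- data.frame(circularity = c(0.95, 0.40, 0.95, 0.40),
                    envelope_coverage = c(1.0, 1.0, 0.7, 0.7),
                    max_gap_um = c(0, 0, 8, 8))
  cls <- classify_phenotype(rec)
  expect_equal(cls$deformed, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(cls$ruptured, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(cls$phenotype_class,
               c("normal", "deformed", "ruptured", "ruptured"))
  # a short gap (below L_min) does not trigger a rupture call
  short <- classify_phenotype(data.frame(circularity = 0.9,
                                         envelope_coverage = 0.9,
                                         max_gap_um = 0.4))
  expect_false(short$ruptured)
  expect_error(classify_phenotype(data.frame(circularity = 0.9)), "missing")
  expect_error(classify_phenotype(data.frame(circularity = 0.9,
                                             envelope_coverage = NA,
                                             max_gap_um = 1)), "NA")
})

test_that("cohort scoring computes fractions and warns below n = 100", {
  rec <- data.frame(phenotype_class = c(rep("normal", 150),
                                        rep("deformed", 50)))
  cs <- suppressWarnings(score_cohort(rec, "test"))
  expect_equal(cs$fraction_deformed, 0.25)
  expect_equal(cs$fraction_ruptured, 0)
  expect_equal(cs$n_cells, 200)
  expect_warning(score_cohort(rec[1:50, , drop = FALSE]), "100")
  expect_error(score_cohort(rec[0, , drop = FALSE]), "no records")
})

test_that("classification recovers the generator mix on a mixed cohort", {
  sim <- mixed_field()
  seg <- segment_nuclei(sim$image[, , 1], pixel_size = 0.2)
  cov <- assess_envelope_coverage(seg$label, sim$image[, , 2], 0.2)
  rec <- classify_phenotype(merge(seg$records, cov, by = "nucleus_id"))
  cs <- suppressWarnings(score_cohort(rec, "mixed"))
  expect_equal(cs$fraction_ruptured, 0.2, tolerance = 0.25)
  mt <- match_to_truth(seg$label, sim$label)
  truth <- sim$truth$phenotype[mt]
  expect_gt(mean(rec$phenotype_class[truth == "fragmented"] == "ruptured"),
            0.8)
  expect_gt(mean(rec$phenotype_class[truth == "normal"] == "normal"), 0.9)
})
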