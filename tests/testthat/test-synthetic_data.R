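test_that("image spec validates its invariants", {
  expect_error(image_spec(phenotype_mix = c(normal = 0.5, deformed = 0.4)),
               "sum to 1")
  expect_error(image_spec(width = 32), ">= 64")
  expect_error(image_spec(snr = 0), "snr")
  expect_error(image_spec(phenotype_mix = c(weird = 1)), "named")
})

test_that("normal-phenotype fields have near-circular ground truth", {
  sim <- simulate_nucleus_image(image_spec(
    n_nuclei = 20, width = 640, height = 640,
    phenotype_mix = c(normal = 1), seed = 1))
  expect_equal(max(sim$label), 20)
  expect_equal(nrow(sim$truth), 20)
  expect_true(all(sim$truth$circularity >= 0.9))
  expect_true(all(sim$truth$true_uncovered_fraction == 0))
})

test_that("empty field yields empty label mask and ground truth", {
  sim <- simulate_nucleus_image(image_spec(n_nuclei = 0, seed = 1))
  expect_equal(max(sim$label), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(dim(sim$image), c(512, 512, 2))
})

test_that("fragmented nuclei carry an envelope gap over their lobe", {
  sim <- simulate_nucleus_image(image_spec(
    n_nuclei = 12, width = 640, height = 640,
    phenotype_mix = c(fragmented = 1), seed = 2))
  # every object: rim omitted over >= 20% of its boundary
  expect_true(all(sim$truth$true_uncovered_fraction >= 0.2))
  # noise-free envelope channel is dark over the uncovered lobe boundary:
  # measured coverage on clean channels matches 1 - true fraction
  cov <- assess_envelope_coverage(sim$label, sim$clean[, , 2], 0.2)
  expect_true(all(abs(cov$envelope_coverage -
                        (1 - sim$truth$true_uncovered_fraction)) < 0.05))
  # the bridge keeps lobe and body one 8-connected object
  expect_equal(max(sim$label), 12)
})

test_that("generator ground truth agrees with contour_metrics (cross-module)", {
  sim <- mixed_field()
  for (id in sample(seq_len(max(sim$label)), 6)) {
    met <- contour_metrics((sim$label == id) + 0, sim$spec$pixel_size)
    expect_equal(met$circularity, sim$truth$circularity[id],
                 tolerance = 0.02)
  }
})

test_that("image generation is deterministic and density errors are named", {
  s1 <- simulate_nucleus_image(image_spec(n_nuclei = 5, seed = 9))
  s2 <- simulate_nucleus_image(image_spec(n_nuclei = 5, seed = 9))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  expect_error(
    simulate_nucleus_image(image_spec(n_nuclei = 40, width = 128,
                                      height = 128, seed = 1)),
    "density")
})

test_that("trace spec validates and presets match the assay design", {
  expect_error(trace_spec(frame_interval = 0), "frame_interval")
  expect_error(trace_spec(duration = 1, frame_interval = 2), "duration")
  expect_error(trace_spec(event_rate = -1), "event_rate")
  ctrl <- trace_spec_control()
  expect_equal(ctrl$n_cells, 83)
  expect_equal(ctrl$event_rate, 0)
  dep <- trace_spec_depleted()
  expect_equal(dep$n_cells, 292)
  expect_equal(dep$duration, 240)
  expect_equal(dep$frame_interval, 2)
  # expected total events = rate * cells * hours = 56
  expect_equal(dep$event_rate * 292 * 4, 56)
})

test_that("rate-zero traces are stationary around baseline with no events", {
  sim <- simulate_reporter_traces(trace_spec(event_rate = 0, n_cells = 10,
                                             seed = 1))
  expect_equal(nrow(sim$truth), 0)
  r <- sim$traces$nls_nuc / sim$traces$nls_cyt
  expect_equal(mean(r), 3, tolerance = 0.02)
  expect_true(all(abs(r - 3) < 3 * 0.6))  # noise_cv 0.03 on both channels
  expect_equal(length(unique(sim$traces$cell_id)), 10)
})

test_that("reporter amount is conserved exactly before noise", {
  sim <- simulate_reporter_traces(trace_spec(n_cells = 20, event_rate = 0.1,
                                             noise_cv = 0, seed = 5))
  tot_nls <- sim$traces$nls_nuc * sim$volumes["V_n"] +
    sim$traces$nls_cyt * sim$volumes["V_c"]
  tot_nes <- sim$traces$nes_nuc * sim$volumes["V_n"] +
    sim$traces$nes_cyt * sim$volumes["V_c"]
  expect_lt(diff(range(tot_nls)) / mean(tot_nls), 1e-6)
  expect_lt(diff(range(tot_nes)) / mean(tot_nes), 1e-6)
})

test_that("the N/C ratio equilibrates toward 1 during an open window", {
  sim <- simulate_reporter_traces(trace_spec(n_cells = 40, event_rate = 0.1,
                                             noise_cv = 0, seed = 5))
  # cells with exactly one event lasting >= 3 frames
  tab <- table(sim$truth$cell_id)
  for (cid in names(tab)[tab == 1][1:3]) {
    tr <- sim$traces[sim$traces$cell_id == cid, ]
    ev <- sim$truth[sim$truth$cell_id == cid, ]
    sel <- tr$time_min >= ev$open_time & tr$time_min <= ev$recovery_onset
    expect_lte(min(tr$nls_nuc[sel] / tr$nls_cyt[sel]), 1.1)
    # NES mirrors inversely: its nuclear signal rises during the event
    expect_gt(max(tr$nes_nuc[sel]), 1.2 * min(tr$nes_nuc))
  }
})

test_that("injected event counts are Poisson across cells", {
  sim <- simulate_reporter_traces(trace_spec(n_cells = 1000, duration = 240,
                                             event_rate = 0.1, noise_cv = 0,
                                             seed = 77))
  counts <- table(factor(sim$truth$cell_id,
                         levels = unique(sim$traces$cell_id)))
  lam <- 0.1 * 4
  obs <- table(factor(pmin(as.integer(counts), 3), levels = 0:3))
  pr <- c(stats::dpois(0:2, lam), 1 - stats::ppois(2, lam))
  gof <- stats::chisq.test(as.integer(obs), p = pr)
  expect_gt(gof$p.value, 0.01)
})

test_that("over-dense event rates are rejected with a named error", {
  expect_error(simulate_reporter_traces(trace_spec(event_rate = 1)),
               "overlap")
})

test_that("trace generation is deterministic given spec + seed", {
  a <- simulate_reporter_traces(trace_spec(n_cells = 5, event_rate = 0.1,
                                           seed = 12))
  b <- simulate_reporter_traces(trace_spec(n_cells = 5, event_rate = 0.1,
                                           seed = 12))
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)
})

test_that("shape trajectories: dynamics presets separate variance by design", {
  q <- simulate_shape_trajectories(40, 5, "quiescent", seed = 1)
  d <- simulate_shape_trajectories(40, 5, "dynamic", seed = 1)
  expect_equal(nrow(q$trajectories), 40 * 5)
  expect_true(all(table(q$trajectories$cell_id) == 5))
  sq <- cohort_trajectory_stats(q$trajectories)
  sd_ <- cohort_trajectory_stats(d$trajectories)
  expect_gt(mean(sd_$var_circularity), mean(sq$var_circularity))
  expect_gt(mean(sd_$var_perimeter), mean(sq$var_perimeter))
  expect_error(simulate_shape_trajectories(5, 1, "quiescent"), "k_timepoints")
})

test_that("quiescent trajectories with vanishing noise have zero variance", {
  q <- simulate_shape_trajectories(10, 5, "quiescent", seed = 2,
                                   noise_sd = 0)
  st <- cohort_trajectory_stats(q$trajectories)
  expect_true(all(st$var_circularity < 1e-24))
  expect_true(all(st$var_perimeter < 1e-20))
})
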