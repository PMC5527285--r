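make_flat_trace <- function(ratio = 3, n = 30, cell = "c1") {
  data.frame(cell_id = cell, time_min = seq(0, by = 2, length.out = n),
             nls_nuc = rep(60 * ratio / 3, n), nls_cyt = rep(20, n),
             nes_nuc = rep(10, n), nes_cyt = rep(50, n),
             mitosis_flag = FALSE, stringsAsFactors = FALSE)
}

test_that("ratio trace: identity, constant baseline, and validation", {
  tr <- make_flat_trace()
  tr$nls_nuc <- tr$nls_cyt
  rt <- compute_ratio_trace(tr)
  expect_true(all(rt$ratio == 1))
  tr3 <- make_flat_trace(ratio = 3)
  rt3 <- compute_ratio_trace(tr3)
  expect_equal(rt3$baseline, 3)
  expect_false(any(rt3$candidate))
  bad <- make_flat_trace(); bad$nls_cyt <- 0
  expect_error(compute_ratio_trace(bad), "cytoplasmic")
  expect_error(validate_trace(make_flat_trace()[1:3, ]), "5 frames")
  uneven <- make_flat_trace(); uneven$time_min[4] <- 5.3
  expect_error(validate_trace(uneven), "uniform")
})

test_that("a constant-ratio control trace yields no events", {
  expect_equal(nrow(detect_rupture_events(make_flat_trace())), 0)
})

test_that("a single injected event is detected with ~frame-level duration", {
  sim <- simulate_reporter_traces(trace_spec(n_cells = 60, event_rate = 0.1,
                                             noise_cv = 0.02, seed = 21))
  tab <- table(sim$truth$cell_id)
  hits <- 0; checked <- 0
  for (cid in names(tab)[tab == 1]) {
    ev <- sim$truth[sim$truth$cell_id == cid, ]
    if (ev$recovery_onset > 235) next  # truncated by the recording window
    tr <- sim$traces[sim$traces$cell_id == cid, ]
    det <- detect_rupture_events(tr)
    checked <- checked + 1
    if (nrow(det) == 1) {
      hits <- hits + 1
      expect_lt(abs(det$duration_min -
                      (ev$recovery_onset - ev$open_time)), 4.5)
      expect_gt(det$depth, 0.5)
    }
  }
  expect_gt(checked, 3)
  expect_equal(hits, checked)
})

test_that("events inside mitosis-flag windows are discarded", {
  # decoy mitoses open the barrier exactly like ruptures, but are flagged
  sim <- simulate_reporter_traces(trace_spec(n_cells = 30, event_rate = 0,
                                             mitosis_rate = 0.3,
                                             noise_cv = 0.02, seed = 3))
  expect_gt(sum(sim$traces$mitosis_flag), 0)
  expect_equal(nrow(detect_rupture_events(sim$traces)), 0)
  # same dynamics without the flag would be called as events
  unflagged <- sim$traces
  unflagged$mitosis_flag <- FALSE
  expect_gt(nrow(detect_rupture_events(unflagged)), 0)
})

test_that("detector sensitivity and duration bias meet the design targets", {
  sim <- simulate_reporter_traces(trace_spec(n_cells = 600, duration = 240,
                                             event_rate = 0.1,
                                             noise_cv = 0.03, seed = 42))
  ev <- detect_rupture_events(sim$traces)
  tru <- sim$truth
  matched <- 0; errs <- c()
  for (i in seq_len(nrow(tru))) {
    sel <- ev$cell_id == tru$cell_id[i] &
      ev$start_min <= tru$recovery_onset[i] + 4 &
      ev$end_min >= tru$open_time[i] - 4
    if (any(sel)) {
      matched <- matched + 1
      j <- which(sel)[1]
      if (!ev$truncated[j]) {
        errs <- c(errs, ev$duration_min[j] -
                    (tru$recovery_onset[i] - tru$open_time[i]))
      }
    }
  }
  expect_gte(matched / nrow(tru), 0.95)
  expect_lte(abs(stats::median(errs)), 2)  # within one frame
})

test_that("no false positives on rate-zero traces over 600 cell-hours", {
  sim <- simulate_reporter_traces(trace_spec(n_cells = 150, duration = 240,
                                             event_rate = 0,
                                             noise_cv = 0.05, seed = 9))
  ev <- detect_rupture_events(sim$traces)
  expect_lt(nrow(ev) / (150 * 4), 0.01)
})

test_that("detection is ratio-based and monotone in d_min", {
  sim <- simulate_reporter_traces(trace_spec_depleted(seed = 3))
  base <- detect_rupture_events(sim$traces)
  scaled <- sim$traces
  scaled$nls_nuc <- scaled$nls_nuc * 7.3
  scaled$nls_cyt <- scaled$nls_cyt * 7.3
  expect_equal(detect_rupture_events(scaled), base)
  counts <- vapply(c(0.3, 0.4, 0.5, 0.6), function(d) {
    nrow(detect_rupture_events(sim$traces, rupture_params(d_min = d)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cohort summary totals, rates, and truncation handling", {
  tr <- make_flat_trace(n = 121)  # 0..240 min
  ev <- data.frame(cell_id = "c1", start_min = 60, end_min = 70,
                   duration_min = 10, depth = 0.8, crossvalidated = TRUE,
                   truncated = FALSE, stringsAsFactors = FALSE)
  s <- cohort_event_summary(tr, ev)
  expect_equal(s$events_per_cell_hour, 0.25)
  expect_equal(s$mean_duration_min, 10)
  expect_equal(s$n_cells, 1)
  # truncated events count toward totals but not mean duration
  ev2 <- rbind(ev, data.frame(cell_id = "c1", start_min = 230, end_min = 240,
                              duration_min = 10, depth = 0.6,
                              crossvalidated = FALSE, truncated = TRUE))
  s2 <- cohort_event_summary(tr, ev2)
  expect_equal(s2$n_events, 2)
  expect_equal(s2$n_truncated, 1)
  expect_equal(s2$mean_duration_min, 10)
  expect_error(cohort_event_summary(tr[0, ], ev), "empty")
  evbad <- ev; evbad$cell_id <- "ghost"
  expect_error(cohort_event_summary(tr, evbad), "unknown")
})

test_that("NES influx cross-validates genuine exchange events", {
  sim <- simulate_reporter_traces(trace_spec_depleted(seed = 1))
  ev <- detect_rupture_events(sim$traces)
  expect_gt(nrow(ev), 20)
  expect_gt(mean(ev$crossvalidated), 0.9)
})
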