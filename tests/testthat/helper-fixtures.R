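# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# rasterized disk mask, radius r px, in a (2r+28)^2 frame
disk_mask <- function(r = 50, cx = NULL, cy = NULL, n = 2 * r + 28) {
  if (is.null(cx)) cx <- n / 2 + 0.5
  if (is.null(cy)) cy <- n / 2 + 0.5
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  matrix(as.numeric((xy$x - cx)^2 + (xy$y - cy)^2 <= r^2), n, n)
}

# small mixed-phenotype field reused by segmentation/classification tests
mixed_field <- function() {
  fixture("mixed_field", function() {
    simulate_nucleus_image(image_spec(
      n_nuclei = 30, width = 768, height = 768,
      phenotype_mix = c(normal = 0.6, deformed = 0.2, fragmented = 0.2),
      snr = 10, seed = 3))
  })
}

# field of normal nuclei large enough to host up to 15 foci each
spot_field <- function() {
  fixture("spot_field", function() {
    simulate_nucleus_image(image_spec(
      n_nuclei = 16, width = 640, height = 640,
      phenotype_mix = c(normal = 1), seed = 4,
      radius_px_range = c(26, 32)))
  })
}

# depleted-preset cohorts over 10 seeds with detections (acceptance reuse)
depleted_runs <- function() {
  fixture("depleted_runs", function() {
    lapply(1:10, function(s) {
      sim <- simulate_reporter_traces(trace_spec_depleted(seed = s))
      list(truth = sim$truth,
           events = detect_rupture_events(sim$traces))
    })
  })
}

# majority-overlap match of segmented objects to generator labels
match_to_truth <- function(seg_label, true_label) {
  vapply(seq_len(max(seg_label)), function(id) {
    tl <- true_label[seg_label == id]
    tl <- tl[tl > 0]
    if (!length(tl)) NA_integer_ else
      as.integer(names(which.max(table(tl))))
  }, integer(1))
}
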