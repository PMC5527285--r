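#!/usr/bin/env Rscript
# Simulate the study cohorts with known ground truth:
#  - fixed-cell imaging fields: control (mostly normal nuclei) vs
#    myosin-phosphatase-depleted (deformed + fragmented nuclei)
#  - dual-reporter barrier-assay traces: 83 control cells (no events) and
#    292 depleted cells at the calibrated rate (expected 56 events / 4 h)
#  - intravital-style shape trajectories: dynamic vs ROCK-inhibited
# Outputs go to results/data/.

library(nucmorph)

seed <- 1
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

message("-- imaging fields (3 per group, 100 nuclei each) --")
mixes <- list(control = c(normal = 0.9, deformed = 0.07, fragmented = 0.03),
              depleted = c(normal = 0.45, deformed = 0.3, fragmented = 0.25))
for (g in names(mixes)) {
  for (f in 1:3) {
    sim <- simulate_nucleus_image(image_spec(
      n_nuclei = 100, width = 1150, height = 1150, pixel_size = 0.2,
      phenotype_mix = mixes[[g]], snr = 10, seed = seed * 100 + f +
        10 * (g == "depleted")))
    write_multipage_tiff(sim$image,
                         file.path(outdir, sprintf("field_%s_%d.tif", g, f)))
    write_label_tiff(sim$label,
                     file.path(outdir, sprintf("labels_%s_%d.tif", g, f)))
    write.csv(sim$truth,
              file.path(outdir, sprintf("truth_%s_%d.csv", g, f)),
              row.names = FALSE)
  }
  message("  ", g, ": 3 fields written")
}

message("-- barrier-assay traces --")
ctrl <- simulate_reporter_traces(trace_spec_control(seed = seed))
dep <- simulate_reporter_traces(trace_spec_depleted(seed = seed))
write.csv(ctrl$traces, file.path(outdir, "traces_control.csv"),
          row.names = FALSE)
write.csv(dep$traces, file.path(outdir, "traces_depleted.csv"),
          row.names = FALSE)
write.csv(dep$truth, file.path(outdir, "traces_depleted_truth.csv"),
          row.names = FALSE)
message("  control: ", length(unique(ctrl$traces$cell_id)), " cells, ",
        nrow(ctrl$truth), " injected events")
message("  depleted: ", length(unique(dep$traces$cell_id)), " cells, ",
        nrow(dep$truth), " injected events")

message("-- shape trajectories (5 timepoints per nucleus) --")
dyn <- simulate_shape_trajectories(32, 5, "dynamic", seed = seed)
qui <- simulate_shape_trajectories(37, 5, "quiescent", seed = seed + 1)
write.csv(dyn$trajectories, file.path(outdir, "trajectories_control.csv"),
          row.names = FALSE)
write.csv(qui$trajectories, file.path(outdir, "trajectories_rocki.csv"),
          row.names = FALSE)
message("  control (dynamic): 32 cells; ROCK-inhibited (quiescent): 37 cells")
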