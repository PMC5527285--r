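#!/usr/bin/env Rscript
# Per-nucleus trajectory variance of perimeter, circularity and aspect
# ratio (5 traced timepoints per nucleus), compared between the dynamic
# (control tumour) and quiescent (ROCK-inhibited) groups with Welch t
# tests. High variance indicates dynamically deforming nuclei.
# Reads results/data/trajectories_*.csv, writes
# results/trajectory_stats.csv and results/dynamics_tests.csv.

library(nucmorph)

indir <- "results/data"
groups <- list(control = "trajectories_control.csv",
               rock_inhibited = "trajectories_rocki.csv")
stats_list <- list()
for (g in names(groups)) {
  traj <- read.csv(file.path(indir, groups[[g]]))
  st <- cohort_trajectory_stats(traj)
  st$group <- g
  stats_list[[g]] <- st
}
all_stats <- do.call(rbind, stats_list)
write.csv(all_stats, "results/trajectory_stats.csv", row.names = FALSE)

tests <- list()
for (metric in c("var_perimeter", "var_circularity", "var_aspect_ratio")) {
  cmp <- compare_groups(list(stats_list$control[[metric]],
                             stats_list$rock_inhibited[[metric]]),
                        "t_test")
  tests[[metric]] <- data.frame(
    metric = metric,
    mean_control = mean(stats_list$control[[metric]]),
    mean_rock_inhibited = mean(stats_list$rock_inhibited[[metric]]),
    t = cmp$statistic, p_value = cmp$p_value)
  message(sprintf("%s: control %.3g vs ROCK-inhibited %.3g (p = %.2g)",
                  metric, tests[[metric]]$mean_control,
                  tests[[metric]]$mean_rock_inhibited, cmp$p_value))
}
write.csv(do.call(rbind, tests), "results/dynamics_tests.csv",
          row.names = FALSE)
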