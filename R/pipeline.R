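#' Two-group comparison statistics
#'
#' \code{chi_square}: the uncorrected chi-square statistic
#' \eqn{\sum (O-E)^2/E} on an r x c count table with df = (r-1)(c-1); all
#' expected counts must be positive. \code{t_test}: Welch's
#' unequal-variance t by default (the simulated cohorts are unpaired);
#' \code{paired = TRUE} gives the paired t.
#'
#' @param x for \code{chi_square}: a count matrix; for \code{t_test}: a
#'   list of two numeric vectors (each n >= 2).
#' @param test \code{"chi_square"} or \code{"t_test"}.
#' @param paired paired t test instead of Welch.
#' @param alternative passed to \code{t.test} for the t test.
#' @return list of class \code{nucmorph_comparison}: \code{test},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{group_sizes}.
#' @export
compare_groups <- function(x, test = c("chi_square", "t_test"),
                           paired = FALSE, alternative = "two.sided") {
  test <- match.arg(test)
  if (test == "chi_square") {
    if (!is.matrix(x) || any(x < 0)) {
      stop("compare_groups: chi_square needs a non-negative count matrix")
    }
    E <- outer(rowSums(x), colSums(x)) / sum(x)
    if (any(E == 0) || !is.finite(sum(E))) {
      stop("compare_groups: chi_square requires all expected counts > 0")
    }
    stat <- sum((x - E)^2 / E)
    df <- (nrow(x) - 1) * (ncol(x) - 1)
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    out <- list(test = "chi_square", statistic = stat, df = df, p_value = p,
                group_sizes = rowSums(x))
  } else {
    if (!is.list(x) || length(x) != 2) {
      stop("compare_groups: t_test needs a list of two numeric vectors")
    }
    if (any(lengths(x) < 2)) stop("compare_groups: t_test needs n >= 2 per group")
    tt <- stats::t.test(x[[1]], x[[2]], paired = paired, var.equal = FALSE,
                        alternative = alternative)
    out <- list(test = if (paired) "t_test_paired" else "t_test_welch",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, group_sizes = lengths(x))
  }
  class(out) <- "nucmorph_comparison"
  out
}

#' @export
print.nucmorph_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$df, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Pipeline run configuration
#'
#' @param mode \code{"simulate"} (write synthetic inputs), \code{"analyze"}
#'   (read inputs from \code{input_dir}), or \code{"full"} (simulate and
#'   analyze in one run).
#' @param output_dir directory for all outputs (created).
#' @param input_dir directory with inputs for analyze mode.
#' @param seed integer seed for every stochastic stage.
#' @param pixel_size micrometres per pixel.
#' @param image_specs named list of [image_spec()] per cohort.
#' @param trace_specs named list of [trace_spec()] per cohort.
#' @param trajectory_groups named list of argument lists for
#'   [simulate_shape_trajectories()].
#' @param seg,classify,rupture parameter lists for the respective stages.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       output_dir, input_dir = NULL, seed = 1,
                       pixel_size = 0.2,
                       image_specs = NULL, trace_specs = NULL,
                       trajectory_groups = NULL,
                       seg = seg_params(), classify = classify_params(),
                       rupture = rupture_params()) {
  mode <- match.arg(mode)
  if (mode == "analyze") {
    if (is.null(input_dir)) stop("run_config: analyze mode needs input_dir")
    if (!dir.exists(input_dir)) {
      stop("run_config: input path does not exist: ", input_dir)
    }
  }
  if (is.null(image_specs)) {
    image_specs <- list(
      control = image_spec(n_nuclei = 40, width = 768, height = 768,
                           pixel_size = pixel_size,
                           phenotype_mix = c(normal = 0.95, deformed = 0.05,
                                             fragmented = 0),
                           seed = seed),
      depleted = image_spec(n_nuclei = 40, width = 768, height = 768,
                            pixel_size = pixel_size,
                            phenotype_mix = c(normal = 0.4, deformed = 0.3,
                                              fragmented = 0.3),
                            seed = seed + 1))
  }
  if (is.null(trace_specs)) {
    trace_specs <- list(control = trace_spec_control(seed = seed),
                        depleted = trace_spec_depleted(seed = seed))
  }
  if (is.null(trajectory_groups)) {
    trajectory_groups <- list(
      control = list(n_cells = 40, dynamics = "dynamic", seed = seed),
      rock_inhibited = list(n_cells = 40, dynamics = "quiescent",
                            seed = seed + 1))
  }
  structure(list(mode = mode, output_dir = output_dir, input_dir = input_dir,
                 seed = as.integer(seed), pixel_size = pixel_size,
                 image_specs = image_specs, trace_specs = trace_specs,
                 trajectory_groups = trajectory_groups, seg = seg,
                 classify = classify, rupture = rupture),
            class = "run_config")
}

#' Run the staged analysis pipeline
#'
#' Stages: simulate (or load) images, segment + coverage + classification +
#' cohort scoring; simulate (or load) reporter traces, rupture detection +
#' event summary; shape trajectories + per-cell variance statistics; group
#' comparisons (chi-square on phenotype counts, Welch t on circularity
#' variance). Writes per-stage CSV/JSON under \code{output_dir} plus a
#' top-level \code{report.json} with a provenance block (seed, config
#' hash, package version). Each stage logs records in/out.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage logging.
#' @return the report (invisibly), a nested list mirroring report.json.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!quiet) message("[nucmorph] ", sprintf(...))
  report <- list()

  # provenance: hash the serialized config
  cfg_json <- file.path(config$output_dir, "config.json")
  jsonlite::write_json(config_to_list(config), cfg_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  prov <- list(seed = config$seed,
               config_md5 = unname(tools::md5sum(cfg_json)),
               package_version = as.character(utils::packageVersion("nucmorph")),
               variance_divisor = "k-1")

  ## --- images: segmentation + phenotype scoring ---
  cohorts <- list()
  for (gname in names(config$image_specs)) {
    if (config$mode == "analyze") {
      paths <- image_input_paths(config$input_dir, gname)
      img <- list(image = read_multipage_tiff(paths$image), label = NULL)
      dna <- img$image[, , 1]; env <- img$image[, , 2]
    } else {
      sim <- simulate_nucleus_image(config$image_specs[[gname]])
      dna <- sim$image[, , 1]; env <- sim$image[, , 2]
      if (config$mode %in% c("simulate", "full")) {
        write_multipage_tiff(sim$image, file.path(
          config$output_dir, paste0("image_", gname, ".tif")))
        write_label_tiff(sim$label, file.path(
          config$output_dir, paste0("labels_", gname, ".tif")))
        utils::write.csv(sim$truth, file.path(
          config$output_dir, paste0("truth_", gname, ".csv")), row.names = FALSE)
      }
      if (config$mode == "simulate") next
    }
    seg <- segment_nuclei(dna, config$pixel_size, config$seg)
    log_msg("%s: segmented %d nuclei", gname, nrow(seg$records))
    cov <- assess_envelope_coverage(seg$label, env, config$pixel_size)
    rec <- merge(seg$records, cov, by = "nucleus_id")
    rec <- classify_phenotype(rec, config$classify)
    utils::write.csv(rec, file.path(config$output_dir,
                                    paste0("nuclei_", gname, ".csv")),
                     row.names = FALSE)
    cohorts[[gname]] <- list(records = rec,
                             summary = suppressWarnings(
                               score_cohort(rec, gname)))
    log_msg("%s: %.0f%% deformed, %.0f%% ruptured",
            gname, 100 * cohorts[[gname]]$summary$fraction_deformed,
            100 * cohorts[[gname]]$summary$fraction_ruptured)
  }
  if (length(cohorts)) {
    cs <- do.call(rbind, lapply(cohorts, `[[`, "summary"))
    jsonlite::write_json(cs, file.path(config$output_dir, "cohorts.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    report$cohorts <- cs
  }

  ## --- traces: rupture detection ---
  summaries <- list(); all_events <- list()
  for (gname in names(config$trace_specs)) {
    if (config$mode == "analyze") {
      tp <- file.path(config$input_dir, paste0("traces_", gname, ".csv"))
      if (!file.exists(tp)) stop("run_pipeline: missing input path: ", tp)
      traces <- utils::read.csv(tp)
    } else {
      sim <- simulate_reporter_traces(config$trace_specs[[gname]])
      traces <- sim$traces
      utils::write.csv(traces, file.path(config$output_dir,
                                         paste0("traces_", gname, ".csv")),
                       row.names = FALSE)
      if (config$mode == "simulate") next
    }
    ev <- detect_rupture_events(traces, config$rupture)
    all_events[[gname]] <- ev
    utils::write.csv(ev, file.path(config$output_dir,
                                   paste0("events_", gname, ".csv")),
                     row.names = FALSE)
    summaries[[gname]] <- cbind(group = gname,
                                cohort_event_summary(traces, ev))
    log_msg("%s: %d events in %d cells (%s min mean duration)",
            gname, summaries[[gname]]$n_events, summaries[[gname]]$n_cells,
            format(summaries[[gname]]$mean_duration_min, digits = 3))
  }
  if (length(summaries)) {
    es <- do.call(rbind, summaries)
    jsonlite::write_json(es, file.path(config$output_dir, "event_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    report$events <- es
  }
  if (config$mode == "simulate") {
    jsonlite::write_json(list(provenance = prov),
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(provenance = prov)))
  }

  ## --- trajectories: variance statistics ---
  tstats <- list()
  for (gname in names(config$trajectory_groups)) {
    args <- config$trajectory_groups[[gname]]
    sim <- do.call(simulate_shape_trajectories, args)
    st <- cohort_trajectory_stats(sim$trajectories)
    st$group <- gname
    utils::write.csv(st, file.path(config$output_dir,
                                   paste0("trajectory_stats_", gname, ".csv")),
                     row.names = FALSE)
    tstats[[gname]] <- st
    log_msg("%s: mean circularity variance %.4g", gname,
            mean(st$var_circularity))
  }
  report$trajectory_stats <- do.call(rbind, tstats)

  ## --- group comparisons ---
  comparisons <- list()
  if (length(cohorts) >= 2) {
    g <- names(cohorts)[1:2]
    tab <- rbind(
      table(factor(cohorts[[g[1]]]$records$phenotype_class != "normal",
                   levels = c(TRUE, FALSE))),
      table(factor(cohorts[[g[2]]]$records$phenotype_class != "normal",
                   levels = c(TRUE, FALSE))))
    rownames(tab) <- g
    cmp <- compare_groups(unclass(tab), test = "chi_square")
    comparisons$phenotype_chi_square <- cmp[c("test", "statistic", "df",
                                              "p_value")]
  }
  if (length(tstats) >= 2) {
    g <- names(tstats)[1:2]
    cmp <- compare_groups(list(tstats[[g[1]]]$var_circularity,
                               tstats[[g[2]]]$var_circularity),
                          test = "t_test")
    comparisons$circ_variance_t <- cmp[c("test", "statistic", "df", "p_value")]
  }
  report$comparisons <- comparisons
  report$provenance <- prov

  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}

config_to_list <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, config_to_list) else x
}

image_input_paths <- function(input_dir, gname) {
  p <- file.path(input_dir, paste0("image_", gname, ".tif"))
  if (!file.exists(p)) stop("run_pipeline: missing input path: ", p)
  list(image = p)
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' One page per channel, 16-bit. Intensities are floored at 0 (camera-style
#' clipping of negative noise) and normalized to the stack maximum; all
#' analysis operations are invariant to this uniform rescaling (thresholds
#' are data-derived, backgrounds re-estimated).
#'
#' @param arr height x width x channels numeric array (or a matrix).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_multipage_tiff <- function(arr, path) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1))
  arr <- pmax(arr, 0)
  mx <- max(arr)
  if (mx > 0) arr <- arr / mx
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' Write / read an integer label mask as a 16-bit TIFF
#'
#' Labels are stored as value/65535, so up to 65535 objects round-trip
#' exactly.
#'
#' @param label integer label matrix.
#' @param path TIFF file.
#' @return the path (write) or the integer label matrix (read).
#' @export
write_label_tiff <- function(label, path) {
  lab <- as_image_matrix(label)
  if (max(lab) > 65535) stop("write_label_tiff: more than 65535 labels")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  lab <- round(m * 65535)
  storage.mode(lab) <- "integer"
  lab
}

#' Read a multi-page TIFF into an array
#'
#' @param path TIFF file with one page per channel.
#' @return height x width x channels array.
#' @export
read_multipage_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , k] <- p
  }
  arr
}
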