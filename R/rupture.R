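#' Rupture detector parameters
#'
#' All thresholds are relative to the per-cell baseline ratio, so detection
#' is invariant to multiplying both channels by a constant (arbitrary-unit
#' fluorescence).
#'
#' @param d_min event threshold: a candidate frame has ratio below
#'   \code{baseline * (1 - d_min)}.
#' @param d_step "sudden" criterion: the ratio must have dropped by at
#'   least \code{d_step * baseline} within \code{window} frames before the
#'   event start.
#' @param window number of frames for the sudden-drop test.
#' @param recovery_frames m: consecutive significant rises confirming
#'   recovery; the event end is the frame where the confirmed rise run
#'   begins (when the reporter begins to re-accumulate).
#' @param rise_eps minimum rise per frame, as a fraction of baseline, for
#'   an increase to count (guards against noise on the open-state plateau).
#' @param merge_gap_frames events separated by at most this many frames are
#'   merged.
#' @param mitosis_pad_frames events overlapping a mitosis flag window
#'   padded by this many frames are discarded.
#' @param nes_factor cross-validation: NES nuclear signal must rise to at
#'   least this factor times its own baseline inside the event window.
#' @param median_smooth odd window for median pre-smoothing of the channels
#'   (1 disables).
#' @return parameter list.
#' @export
rupture_params <- function(d_min = 0.4, d_step = 0.25, window = 2,
                           recovery_frames = 2, rise_eps = 0.05,
                           merge_gap_frames = 2, mitosis_pad_frames = 2,
                           nes_factor = 1.5, median_smooth = 3) {
  list(d_min = d_min, d_step = d_step, window = window,
       recovery_frames = recovery_frames, rise_eps = rise_eps,
       merge_gap_frames = merge_gap_frames,
       mitosis_pad_frames = mitosis_pad_frames, nes_factor = nes_factor,
       median_smooth = median_smooth)
}

#' Nuclear/cytoplasmic ratio trace with baseline
#'
#' Computes R(t) = nls_nuc / nls_cyt after optional median smoothing of
#' each channel, and a two-pass baseline: candidate event frames (ratio
#' below \code{baseline1 * (1 - d_min)}) are excluded from the second-pass
#' median.
#'
#' @param trace data.frame for one cell with \code{time_min},
#'   \code{nls_nuc}, \code{nls_cyt} (validated by [validate_trace()]).
#' @param params a [rupture_params()] list.
#' @return list: \code{time}, \code{ratio}, \code{baseline},
#'   \code{candidate} (logical).
#' @export
compute_ratio_trace <- function(trace, params = rupture_params()) {
  validate_trace(trace)
  sm <- function(x) if (params$median_smooth > 1) {
    stats::runmed(x, k = params$median_smooth, endrule = "median")
  } else x
  nuc <- sm(trace$nls_nuc)
  cyt <- sm(trace$nls_cyt)
  if (any(cyt <= 0)) {
    stop("compute_ratio_trace: cytoplasmic channel <= 0 after smoothing ",
         "(cell ", trace$cell_id[1], ")")
  }
  ratio <- nuc / cyt
  b1 <- stats::median(ratio)
  candidate <- ratio < b1 * (1 - params$d_min)
  baseline <- stats::median(ratio[!candidate])
  list(time = trace$time_min, ratio = ratio, baseline = baseline,
       candidate = candidate)
}

#' Validate a reporter trace
#'
#' Checks the schema, a strictly increasing uniform time grid, non-negative
#' intensities, and at least 5 frames.
#'
#' @param trace data.frame for one cell.
#' @return invisibly TRUE; errors otherwise.
#' @export
validate_trace <- function(trace) {
  need <- c("time_min", "nls_nuc", "nls_cyt")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop("trace missing columns: ", paste(miss, collapse = ", "))
  if (nrow(trace) < 5) stop("trace needs at least 5 frames")
  dt <- diff(trace$time_min)
  if (any(dt <= 0)) stop("trace time must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * max(dt)) stop("trace time grid must be uniform")
  int_cols <- intersect(c("nls_nuc", "nls_cyt", "nes_nuc", "nes_cyt"),
                        names(trace))
  if (any(unlist(trace[int_cols]) < 0)) stop("trace intensities must be >= 0")
  invisible(TRUE)
}

#' Detect nuclear envelope rupture events in dual-reporter traces
#'
#' An event starts at the first frame where the N/C ratio falls below
#' \code{baseline * (1 - d_min)} after a sudden drop (at least
#' \code{d_step * baseline} within \code{window} frames). It ends when the
#' NLS reporter begins to re-accumulate: the first rising frame after the
#' event minimum, confirmed by \code{recovery_frames} consecutive
#' significant rises. Events overlapping a mitosis-flag window (padded by
#' \code{mitosis_pad_frames}) are discarded; events separated by at most
#' \code{merge_gap_frames} are merged. Events still open at the end of the
#' trace get \code{truncated = TRUE} (end = last frame) and are excluded
#' from mean-duration statistics downstream.
#'
#' @param traces long data.frame of one or more cells (columns
#'   \code{cell_id}, \code{time_min}, \code{nls_nuc}, \code{nls_cyt},
#'   optionally \code{nes_nuc}, \code{mitosis_flag}).
#' @param params a [rupture_params()] list.
#' @return data.frame: \code{cell_id}, \code{start_min}, \code{end_min},
#'   \code{duration_min}, \code{depth} (fractional ratio drop),
#'   \code{crossvalidated}, \code{truncated}. Zero rows when no events.
#' @export
detect_rupture_events <- function(traces, params = rupture_params()) {
  if (!nrow(traces)) return(empty_event_df())
  parts <- split(traces, traces$cell_id)
  out <- lapply(parts, detect_events_one_cell, params = params)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_event_df <- function() {
  data.frame(cell_id = character(0), start_min = numeric(0),
             end_min = numeric(0), duration_min = numeric(0),
             depth = numeric(0), crossvalidated = logical(0),
             truncated = logical(0), stringsAsFactors = FALSE)
}

detect_events_one_cell <- function(trace, params) {
  rt <- compute_ratio_trace(trace, params)
  R <- rt$ratio; B <- rt$baseline; tm <- rt$time
  n <- length(R)
  thr <- B * (1 - params$d_min)
  below <- R < thr
  if (!any(below)) return(empty_event_df())

  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ev <- list()
  for (ri in which(runs$values)) {
    s <- starts[ri]
    # sudden: dropped >= d_step*B within the preceding `window` frames
    js <- max(1, s - params$window):max(1, s - 1)
    if (s == 1 || !any(R[js] - R[s] >= params$d_step * B)) next
    # event minimum over the below-run
    e_run <- ends[ri]
    imin <- s - 1 + which.min(R[s:e_run])
    # recovery: first rising frame after the minimum, confirmed by
    # `recovery_frames` consecutive rises of at least rise_eps * B
    eps <- params$rise_eps * B
    endf <- NA_integer_
    k <- imin + 1
    while (k + params$recovery_frames - 1 <= n) {
      kk <- k:(k + params$recovery_frames - 1)
      if (all(R[kk] - R[kk - 1] > eps)) { endf <- k; break }
      k <- k + 1
    }
    truncated <- is.na(endf)
    if (truncated) endf <- n
    ev[[length(ev) + 1]] <- data.frame(
      s = s, e = endf, imin = imin, truncated = truncated)
  }
  if (!length(ev)) return(empty_event_df())
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$s), , drop = FALSE]

  # merge events separated by <= merge_gap_frames
  merged <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) for (i in 2:nrow(ev)) {
    last <- nrow(merged)
    if (ev$s[i] - merged$e[last] <= params$merge_gap_frames) {
      merged$e[last] <- max(merged$e[last], ev$e[i])
      merged$truncated[last] <- merged$truncated[last] || ev$truncated[i]
      if (R[ev$imin[i]] < R[merged$imin[last]]) merged$imin[last] <- ev$imin[i]
    } else merged <- rbind(merged, ev[i, ])
  }
  ev <- merged

  # mitotic exclusion
  if ("mitosis_flag" %in% names(trace) && any(trace$mitosis_flag)) {
    pad <- params$mitosis_pad_frames
    mit <- which(trace$mitosis_flag)
    keep <- vapply(seq_len(nrow(ev)), function(i) {
      win <- max(1, ev$s[i] - pad):min(n, ev$e[i] + pad)
      !any(win %in% mit)
    }, logical(1))
    ev <- ev[keep, , drop = FALSE]
  }
  if (!nrow(ev)) return(empty_event_df())

  # cross-validation on the NES reporter
  crossval <- rep(NA, nrow(ev))
  if ("nes_nuc" %in% names(trace)) {
    inside <- rep(FALSE, n)
    for (i in seq_len(nrow(ev))) inside[ev$s[i]:ev$e[i]] <- TRUE
    nes_base <- stats::median(trace$nes_nuc[!inside])
    for (i in seq_len(nrow(ev))) {
      crossval[i] <- max(trace$nes_nuc[ev$s[i]:ev$e[i]]) >=
        params$nes_factor * nes_base
    }
  }

  data.frame(
    cell_id = trace$cell_id[1],
    start_min = tm[ev$s], end_min = tm[ev$e],
    duration_min = tm[ev$e] - tm[ev$s],
    depth = pmin(pmax((B - R[ev$imin]) / B, .Machine$double.eps), 1),
    crossvalidated = crossval, truncated = ev$truncated,
    stringsAsFactors = FALSE)
}

#' Cohort-level rupture event summary
#'
#' @param traces long trace data.frame for the whole cohort.
#' @param events event data.frame from [detect_rupture_events()].
#' @return one-row data.frame: \code{n_cells}, \code{observation_time_h}
#'   (per cell), \code{n_events} (all detected, including truncated),
#'   \code{n_truncated}, \code{events_per_cell_hour} and
#'   \code{mean_duration_min} (non-truncated events only; NA when none).
#' @export
cohort_event_summary <- function(traces, events) {
  if (!nrow(traces)) stop("cohort_event_summary: empty trace set")
  cells <- unique(traces$cell_id)
  if (nrow(events) && !all(events$cell_id %in% cells)) {
    stop("cohort_event_summary: events reference unknown cell_id values")
  }
  tr1 <- traces[traces$cell_id == cells[1], ]
  obs_h <- (max(tr1$time_min) - min(tr1$time_min)) / 60
  n_events <- nrow(events)
  complete <- events[!events$truncated, , drop = FALSE]
  data.frame(
    n_cells = length(cells), observation_time_h = obs_h,
    n_events = n_events, n_truncated = n_events - nrow(complete),
    events_per_cell_hour = n_events / (length(cells) * obs_h),
    mean_duration_min = if (nrow(complete)) mean(complete$duration_min) else NA_real_)
}
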