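#' Specification for synthetic dual-reporter traces
#'
#' Describes a cohort of per-cell time series of an NLS-tagged reporter
#' (nuclear in the closed state) and an NES-tagged reporter (cytoplasmic in
#' the closed state), sampled on a uniform grid. Envelope rupture events
#' arrive as a Poisson process; during an event the nucleocytoplasmic
#' barrier is open and reporter concentrations equilibrate (N/C ratio
#' relaxes toward 1 with a 1-min time constant, so the drop completes
#' within one 2-min frame); at the recovery onset the envelope reseals and
#' the reporter re-accumulates toward the closed-state ratio.
#'
#' @param n_cells number of cells.
#' @param duration recording length in minutes.
#' @param frame_interval sampling interval in minutes (default 2, the
#'   acquisition interval of the emulated assay).
#' @param event_rate rupture events per cell-hour.
#' @param open_ratio_baseline closed-state N/C concentration ratio of the
#'   NLS reporter (default 3).
#' @param mean_event_duration mean open-to-reseal time in minutes
#'   (default 15). Durations are Gamma distributed with shape 3 and this
#'   mean, resampled when shorter than 2 frames.
#' @param noise_cv multiplicative measurement noise, coefficient of
#'   variation per sample.
#' @param mitosis_rate mitosis decoys per cell-hour (flagged in the trace;
#'   during the window the barrier also opens, so an unflagged detector
#'   would call a false event).
#' @param seed integer seed.
#' @return object of class \code{trace_spec}.
#' @export
trace_spec <- function(n_cells = 10, duration = 240, frame_interval = 2,
                       event_rate = 0, open_ratio_baseline = 3,
                       mean_event_duration = 15, noise_cv = 0.03,
                       mitosis_rate = 0, seed = 1) {
  if (frame_interval <= 0) stop("trace_spec: frame_interval must be > 0")
  if (duration < frame_interval) stop("trace_spec: duration must be >= frame_interval")
  if (event_rate < 0) stop("trace_spec: event_rate must be >= 0")
  if (mean_event_duration < frame_interval) {
    stop("trace_spec: mean_event_duration must be >= frame_interval")
  }
  if (n_cells < 0) stop("trace_spec: n_cells must be >= 0")
  structure(list(n_cells = as.integer(n_cells), duration = duration,
                 frame_interval = frame_interval, event_rate = event_rate,
                 open_ratio_baseline = open_ratio_baseline,
                 mean_event_duration = mean_event_duration,
                 noise_cv = noise_cv, mitosis_rate = mitosis_rate,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

#' Cohort presets for the nuclear envelope barrier assay
#'
#' \code{trace_spec_control()} is the control cohort: 83 cells, 4 h, no
#' rupture events. \code{trace_spec_depleted()} is the myosin-phosphatase-
#' depleted cohort: 292 cells, 4 h, event rate calibrated so the expected
#' total is 56 events (56 / (292 cells x 4 h) per cell-hour), mean event
#' duration 15 min.
#'
#' @param seed integer seed.
#' @param noise_cv multiplicative noise CV.
#' @rdname trace_presets
#' @export
trace_spec_control <- function(seed = 1, noise_cv = 0.03) {
  trace_spec(n_cells = 83, duration = 240, frame_interval = 2,
             event_rate = 0, noise_cv = noise_cv, seed = seed)
}

#' @rdname trace_presets
#' @export
trace_spec_depleted <- function(seed = 1, noise_cv = 0.03) {
  trace_spec(n_cells = 292, duration = 240, frame_interval = 2,
             event_rate = 56 / (292 * 4), noise_cv = noise_cv, seed = seed)
}

# Compartment model constants. Volumes set the closed-state equilibrium:
# with V_n = 1, V_c = 2 and baseline ratio B, the closed-state nuclear
# amount fraction is B*V_n / (B*V_n + V_c). Total reporter amount is 1
# (conserved exactly; the integration is piecewise-exponential in closed
# form). Intensities are concentrations scaled by 100 a.u.
.trace_const <- list(V_n = 1, V_c = 2, scale = 100,
                     tau_open = 1,    # min; equilibration during rupture
                     tau_reseal = 3,  # min; re-import after resealing
                     mitosis_window = 20)

#' Simulate dual-reporter traces with injected rupture events
#'
#' Integrates a two-compartment exchange model per cell (closed form, exact
#' piecewise exponentials) and samples it every \code{frame_interval}
#' minutes, then applies multiplicative noise. Total reporter amount per
#' cell is conserved before noise. Mitosis decoys (if
#' \code{mitosis_rate > 0}) open the barrier like a rupture but are flagged
#' via \code{mitosis_flag}.
#'
#' @param spec a [trace_spec()].
#' @return list with:
#'   \describe{
#'     \item{traces}{long data.frame: \code{cell_id}, \code{time_min},
#'       \code{nls_nuc}, \code{nls_cyt}, \code{nes_nuc}, \code{nes_cyt},
#'       \code{mitosis_flag}.}
#'     \item{truth}{data.frame of injected events: \code{cell_id},
#'       \code{open_time}, \code{recovery_onset}.}
#'     \item{volumes}{named vector (V_n, V_c) for conservation checks.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
simulate_reporter_traces <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  # analytic overlap check: a draw overlaps an existing busy period with
  # probability ~ 1 - exp(-2 * rate_per_min * mean_duration)
  p_overlap <- 1 - exp(-2 * (spec$event_rate / 60) * spec$mean_event_duration)
  if (p_overlap > 0.05) {
    stop("simulate_reporter_traces: event_rate ", signif(spec$event_rate, 3),
         " events/cell-hour would make >5% of drawn events overlap; reduce it")
  }
  set.seed(spec$seed)
  k <- .trace_const
  B <- spec$open_ratio_baseline
  a_closed <- B * k$V_n / (B * k$V_n + k$V_c)     # NLS closed-state nuclear fraction
  a_open <- k$V_n / (k$V_n + k$V_c)               # free-diffusion equilibrium
  e_closed <- k$V_n / (k$V_n + B * k$V_c)         # NES closed state (excluded)

  tgrid <- seq(0, spec$duration, by = spec$frame_interval)
  traces <- vector("list", spec$n_cells)
  truth <- vector("list", spec$n_cells)
  hours <- spec$duration / 60

  for (ci in seq_len(spec$n_cells)) {
    ev <- draw_events(spec, hours)
    mito <- if (spec$mitosis_rate > 0) {
      nm <- stats::rpois(1, spec$mitosis_rate * hours)
      sort(stats::runif(nm, 0, spec$duration - k$mitosis_window))
    } else numeric(0)
    # open windows: injected events plus mitosis decoys
    open_int <- rbind(ev, if (length(mito)) {
      data.frame(open_time = mito, recovery_onset = mito + k$mitosis_window)
    })
    a_nls <- integrate_compartment(tgrid, open_int, a_closed, a_open,
                                   k$tau_open, k$tau_reseal)
    a_nes <- integrate_compartment(tgrid, open_int, e_closed, a_open,
                                   k$tau_open, k$tau_reseal)
    nls_nuc <- k$scale * a_nls / k$V_n
    nls_cyt <- k$scale * (1 - a_nls) / k$V_c
    nes_nuc <- k$scale * a_nes / k$V_n
    nes_cyt <- k$scale * (1 - a_nes) / k$V_c
    if (spec$noise_cv > 0) {
      nz <- function(x) x * pmax(1 + stats::rnorm(length(x), sd = spec$noise_cv), 0.05)
      nls_nuc <- nz(nls_nuc); nls_cyt <- nz(nls_cyt)
      nes_nuc <- nz(nes_nuc); nes_cyt <- nz(nes_cyt)
    }
    mflag <- rep(FALSE, length(tgrid))
    for (m0 in mito) mflag[tgrid >= m0 & tgrid <= m0 + k$mitosis_window] <- TRUE
    traces[[ci]] <- data.frame(
      cell_id = sprintf("cell_%04d", ci), time_min = tgrid,
      nls_nuc = nls_nuc, nls_cyt = nls_cyt,
      nes_nuc = nes_nuc, nes_cyt = nes_cyt,
      mitosis_flag = mflag, stringsAsFactors = FALSE)
    if (nrow(ev)) {
      truth[[ci]] <- cbind(cell_id = sprintf("cell_%04d", ci), ev,
                           stringsAsFactors = FALSE)
    }
  }
  list(traces = do.call(rbind, traces) %||% empty_trace_df(),
       truth = do.call(rbind, truth) %||%
         data.frame(cell_id = character(0), open_time = numeric(0),
                    recovery_onset = numeric(0)),
       volumes = c(V_n = k$V_n, V_c = k$V_c),
       spec = spec)
}

empty_trace_df <- function() {
  data.frame(cell_id = character(0), time_min = numeric(0),
             nls_nuc = numeric(0), nls_cyt = numeric(0),
             nes_nuc = numeric(0), nes_cyt = numeric(0),
             mitosis_flag = logical(0), stringsAsFactors = FALSE)
}

# Poisson event arrivals with Gamma(shape 3) durations, non-overlapping.
draw_events <- function(spec, hours) {
  n_ev <- stats::rpois(1, spec$event_rate * hours)
  out <- data.frame(open_time = numeric(0), recovery_onset = numeric(0))
  if (n_ev == 0) return(out)
  for (j in seq_len(n_ev)) {
    for (try in 1:50) {
      open <- stats::runif(1, 0, spec$duration - spec$frame_interval)
      dur <- stats::rgamma(1, shape = 3, scale = spec$mean_event_duration / 3)
      while (dur < 2 * spec$frame_interval) {
        dur <- stats::rgamma(1, shape = 3, scale = spec$mean_event_duration / 3)
      }
      reseal <- open + dur
      if (!nrow(out) ||
          all(reseal < out$open_time - 2 * spec$frame_interval |
              open > out$recovery_onset + 2 * spec$frame_interval)) {
        out <- rbind(out, data.frame(open_time = open, recovery_onset = reseal))
        break
      }
    }
  }
  out[order(out$open_time), , drop = FALSE]
}

# Exact piecewise-exponential relaxation of the nuclear amount fraction
# between the open/closed targets. open_int: data.frame(open_time,
# recovery_onset), sorted, non-overlapping (or NULL).
integrate_compartment <- function(tgrid, open_int, a_closed, a_open,
                                  tau_open, tau_reseal) {
  if (is.null(open_int) || !nrow(open_int)) {
    return(rep(a_closed, length(tgrid)))
  }
  open_int <- open_int[order(open_int$open_time), , drop = FALSE]
  # merge overlapping open windows (mitosis decoys may collide with events)
  if (nrow(open_int) > 1) {
    merged <- open_int[1, ]
    for (i in 2:nrow(open_int)) {
      last <- nrow(merged)
      if (open_int$open_time[i] <= merged$recovery_onset[last]) {
        merged$recovery_onset[last] <- max(merged$recovery_onset[last],
                                           open_int$recovery_onset[i])
      } else merged <- rbind(merged, open_int[i, ])
    }
    open_int <- merged
  }
  # breakpoints define piecewise-constant (target, tau) segments
  bp <- c(0, as.vector(t(open_int[, c("open_time", "recovery_onset")])), Inf)
  a0 <- a_closed
  out <- numeric(length(tgrid))
  for (s in seq_len(length(bp) - 1)) {
    t0 <- bp[s]; t1 <- bp[s + 1]
    open_seg <- s %% 2 == 0  # segments alternate closed, open, closed, ...
    target <- if (open_seg) a_open else a_closed
    tau <- if (open_seg) tau_open else tau_reseal
    sel <- tgrid >= t0 & tgrid < t1
    out[sel] <- target + (a0 - target) * exp(-(tgrid[sel] - t0) / tau)
    if (!is.finite(t1)) break
    a0 <- target + (a0 - target) * exp(-(t1 - t0) / tau)
  }
  out
}
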