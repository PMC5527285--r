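#' Simulate per-cell nuclear shape trajectories
#'
#' Emulates nuclei traced over \code{k_timepoints} frames of a time-lapse
#' recording. Each cell has a base ellipse (semi-major axis ~5 um, aspect
#' ratio 1.05-1.5); at each timepoint the semi-axes are perturbed
#' multiplicatively. The \code{quiescent} preset uses small perturbations
#' (sd 0.02), the \code{dynamic} preset large frame-to-frame excursions
#' (sd 0.15), so the per-cell variance of perimeter, circularity and
#' aspect ratio is larger by construction in the dynamic group. The ellipse
#' perimeter uses Ramanujan's approximation.
#'
#' @param n_cells number of cells.
#' @param k_timepoints timepoints per cell, >= 2 (default 5, matching
#'   nuclei traced at five intervals).
#' @param dynamics \code{"quiescent"} or \code{"dynamic"}.
#' @param seed integer seed.
#' @param noise_sd override the preset perturbation sd.
#' @return list with \code{trajectories} (long data.frame: \code{cell_id},
#'   \code{timepoint}, \code{perimeter}, \code{circularity},
#'   \code{aspect_ratio}) and \code{truth} (per-cell generative sd and
#'   dynamics label).
#' @export
simulate_shape_trajectories <- function(n_cells, k_timepoints = 5,
                                        dynamics = c("quiescent", "dynamic"),
                                        seed = 1, noise_sd = NULL) {
  dynamics <- match.arg(dynamics)
  if (k_timepoints < 2) {
    stop("simulate_shape_trajectories: k_timepoints must be >= 2 ",
         "(per-cell variance is undefined otherwise)")
  }
  set.seed(seed)
  sd0 <- noise_sd %||% switch(dynamics, quiescent = 0.02, dynamic = 0.15)
  rows <- vector("list", n_cells)
  truth <- data.frame(cell_id = character(0), dynamics = character(0),
                      noise_sd = numeric(0), base_a = numeric(0),
                      base_b = numeric(0), stringsAsFactors = FALSE)
  for (ci in seq_len(n_cells)) {
    a0 <- stats::runif(1, 4.5, 5.5)
    ar0 <- stats::runif(1, 1.05, 1.5)
    b0 <- a0 / ar0
    ea <- pmax(1 + stats::rnorm(k_timepoints, sd = sd0), 0.3)
    eb <- pmax(1 + stats::rnorm(k_timepoints, sd = sd0), 0.3)
    a <- a0 * ea; b <- b0 * eb
    per <- ellipse_perimeter(a, b)
    area <- pi * a * b
    circ <- as.numeric(circularity(area, per))
    cid <- sprintf("cell_%04d", ci)
    rows[[ci]] <- data.frame(
      cell_id = cid, timepoint = seq_len(k_timepoints),
      perimeter = per, circularity = circ,
      aspect_ratio = pmax(a, b) / pmin(a, b), stringsAsFactors = FALSE)
    truth <- rbind(truth, data.frame(
      cell_id = cid, dynamics = dynamics, noise_sd = sd0,
      base_a = a0, base_b = b0, stringsAsFactors = FALSE))
  }
  list(trajectories = do.call(rbind, rows), truth = truth)
}

# Ramanujan's first approximation to the ellipse perimeter.
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}
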