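#' Circularity of a region from area and perimeter
#'
#' Circularity is defined as \eqn{4\pi \cdot \mathrm{area} / \mathrm{perimeter}^2}.
#' It equals 1 for a perfect disk and decreases with shape irregularity.
#' Values slightly above 1 (digitization overshoot) are clamped to 1; the
#' pre-clamp value is returned in the \code{"preclamp"} attribute.
#'
#' @param area region area (any consistent unit squared), must be > 0.
#' @param perimeter region perimeter (same base unit), must be > 0.
#' @return numeric circularity in [0, 1], with attribute \code{preclamp}.
#' @examples
#' circularity(pi * 4^2, 2 * pi * 4)   # disk -> 1
#' circularity(100, 40)                # square -> pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    stop("circularity: area and perimeter must be finite and positive")
  }
  raw <- 4 * pi * area / perimeter^2
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "preclamp") <- raw
  out
}

#' Shape metrics of a single binary mask
#'
#' Computes area, perimeter, circularity, aspect ratio and centroid of one
#' 8-connected binary region. Area is the pixel count times
#' \code{pixel_size^2}. The perimeter is measured on a sub-pixel contour:
#' the mask is lightly Gaussian-smoothed (sigma 1 px) and traced with
#' marching squares at level 0.5, and the polygon length is summed. Plain
#' boundary-pixel counting would inflate a disk's perimeter by tens of
#' percent and a perfect circle would never reach circularity 1; the
#' sub-pixel contour keeps a rasterized disk at circularity >= 0.98.
#' The aspect ratio is the major/minor axis ratio of the second-moment
#' equivalent ellipse.
#'
#' @param mask logical or 0/1 matrix containing exactly one 8-connected
#'   non-empty region.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @return a one-row data.frame with columns \code{area}, \code{perimeter},
#'   \code{circularity}, \code{circularity_raw} (pre-clamp),
#'   \code{aspect_ratio}, \code{centroid_x}, \code{centroid_y}
#'   (physical units) and \code{area_px}.
#' @export
contour_metrics <- function(mask, pixel_size = 1) {
  m <- as_mask_matrix(mask)
  npix <- sum(m)
  if (npix == 0L) stop("contour_metrics: empty mask")
  if (max(label8(m)) > 1L) {
    stop("contour_metrics: mask has more than one 8-connected component")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("contour_metrics: pixel_size must be a positive scalar")
  }

  per_px <- mask_perimeter_px(m)
  area <- npix * pixel_size^2
  perimeter <- per_px * pixel_size

  # second-moment equivalent ellipse
  idx <- which(m == 1, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  dx <- idx[, 1] - cx; dy <- idx[, 2] - cy
  # + 1/12: variance of the unit-square pixel footprint
  mxx <- mean(dx * dx) + 1 / 12
  myy <- mean(dy * dy) + 1 / 12
  mxy <- mean(dx * dy)
  tr <- mxx + myy
  det <- mxx * myy - mxy * mxy
  disc <- sqrt(max(tr * tr / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, .Machine$double.eps)
  aspect_ratio <- sqrt(l1 / l2)

  circ <- circularity(area, perimeter)
  data.frame(
    area = area,
    perimeter = perimeter,
    circularity = as.numeric(circ),
    circularity_raw = attr(circ, "preclamp"),
    aspect_ratio = aspect_ratio,
    centroid_x = cx * pixel_size,
    centroid_y = cy * pixel_size,
    area_px = npix
  )
}

# Sub-pixel perimeter (in pixels) of a binary matrix: Gaussian-smooth the
# mask, trace level-0.5 contours with marching squares, sum segment lengths.
mask_perimeter_px <- function(m, sigma = 1) {
  # pad so contours near the array edge close properly
  pad <- max(4L, ceiling(3 * sigma))
  mp <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  mp[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  ms <- as.matrix(EBImage::gblur(EBImage::Image(mp), sigma = sigma))
  cl <- grDevices::contourLines(seq_len(nrow(ms)), seq_len(ncol(ms)), ms,
                                levels = 0.5)
  if (length(cl) == 0L) {
    # object thinner than the smoothing kernel: fall back to the raw mask
    cl <- grDevices::contourLines(seq_len(nrow(mp)), seq_len(ncol(mp)), mp,
                                  levels = 0.5)
  }
  if (length(cl) == 0L) return(4)  # single isolated pixel
  sum(vapply(cl, function(cc) {
    x <- cc$x; y <- cc$y
    # contourLines closes loops by repeating the first point; if not, close
    if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
      x <- c(x, x[1]); y <- c(y, y[1])
    }
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1)))
}

#' Per-cell trajectory statistics of shape metrics
#'
#' For one cell traced over k timepoints, returns the arithmetic mean and
#' the sample variance (divisor k - 1) of perimeter, circularity and aspect
#' ratio. A high variance indicates a dynamically deforming nucleus.
#'
#' @param series data.frame with one row per timepoint and columns
#'   \code{perimeter}, \code{circularity}, \code{aspect_ratio}; optionally
#'   \code{cell_id} (must be a single value).
#' @return one-row data.frame: \code{cell_id} (NA if absent), \code{k},
#'   \code{mean_*} and \code{var_*} for the three metrics. The variance
#'   divisor is recorded in the \code{"variance_divisor"} attribute.
#' @export
trajectory_stats <- function(series) {
  need <- c("perimeter", "circularity", "aspect_ratio")
  if (!all(need %in% names(series))) {
    stop("trajectory_stats: series needs columns ",
         paste(need, collapse = ", "))
  }
  k <- nrow(series)
  if (k < 2L) stop("trajectory_stats: need k >= 2 timepoints (variance undefined)")
  cid <- NA_character_
  if ("cell_id" %in% names(series)) {
    u <- unique(series$cell_id)
    if (length(u) != 1L) stop("trajectory_stats: series mixes cell_id values")
    cid <- as.character(u)
  }
  out <- data.frame(
    cell_id = cid, k = k,
    mean_perimeter = mean(series$perimeter),
    var_perimeter = stats::var(series$perimeter),
    mean_circularity = mean(series$circularity),
    var_circularity = stats::var(series$circularity),
    mean_aspect_ratio = mean(series$aspect_ratio),
    var_aspect_ratio = stats::var(series$aspect_ratio),
    stringsAsFactors = FALSE
  )
  attr(out, "variance_divisor") <- "k-1"
  out
}

#' Trajectory statistics for a whole cohort
#'
#' @param trajectories long-format data.frame with columns \code{cell_id},
#'   \code{perimeter}, \code{circularity}, \code{aspect_ratio} (one row per
#'   cell and timepoint).
#' @return data.frame with one row per cell (see [trajectory_stats()]).
#' @export
cohort_trajectory_stats <- function(trajectories) {
  if (!"cell_id" %in% names(trajectories)) {
    stop("cohort_trajectory_stats: need a cell_id column")
  }
  parts <- split(trajectories, trajectories$cell_id)
  out <- do.call(rbind, lapply(parts, trajectory_stats))
  rownames(out) <- NULL
  attr(out, "variance_divisor") <- "k-1"
  out
}
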