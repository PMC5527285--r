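#' Simulate a damage-marker channel with injected foci
#'
#' Renders a marker channel (e.g. gamma-H2AX or 53BP1) over an existing
#' label mask: each nucleus gets a pan-nuclear base intensity plus a known
#' number of Gaussian foci placed well apart inside the nucleus, then
#' Poisson-Gaussian noise (background sd 1). The spot peak amplitude equals
#' \code{spot_snr} background sds above the local base level, so spot
#' detectability is controlled directly.
#'
#' @param label integer label mask of nuclei.
#' @param pixel_size micrometres per pixel.
#' @param spot_counts integer vector of foci per nucleus (recycled).
#' @param spot_diameter_um focus diameter (FWHM-ish, 2.355 sigma) in um.
#' @param base_intensity pan-nuclear base level per nucleus (recycled);
#'   group effects are modelled by scaling this.
#' @param spot_snr spot peak amplitude over background noise sd.
#' @param seed integer seed.
#' @return list with \code{image} (noisy matrix), \code{clean}, and
#'   \code{truth} (\code{object_id}, \code{true_spot_count},
#'   \code{base_intensity}, spot centre coordinates in an attribute).
#' @export
simulate_marker_channel <- function(label, pixel_size = 0.2, spot_counts = 0,
                                    spot_diameter_um = 0.6,
                                    base_intensity = 5, spot_snr = 12,
                                    seed = 1) {
  lab <- as_image_matrix(label)
  set.seed(seed)
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  n <- length(ids)
  counts <- rep_len(spot_counts, max(n, 1L))
  base <- rep_len(base_intensity, max(n, 1L))
  img <- matrix(0, nrow(lab), ncol(lab))
  sigma_px <- (spot_diameter_um / pixel_size) / 2.355
  # "well separated": blobs this far apart stay distinct maxima in LoG
  # scale space over the default diameter window
  min_sep <- max(5.5 * sigma_px, 3)
  centres <- list()
  truth <- data.frame(object_id = integer(0), true_spot_count = integer(0),
                      base_intensity = numeric(0))
  for (k in seq_len(n)) {
    id <- ids[k]
    sel <- lab == id
    img[sel] <- img[sel] + base[k]
    # candidate spot centres: object pixels clear of the boundary by ~2 sigma
    er <- EBImage::imageData(EBImage::erode(
      EBImage::Image((lab == id) + 0),
      EBImage::makeBrush(2 * ceiling(2 * sigma_px) + 1, "disc")))
    cand <- which(er > 0, arr.ind = TRUE)
    if (nrow(cand) == 0) cand <- which(sel, arr.ind = TRUE)
    pts <- matrix(numeric(0), 0, 2)
    if (counts[k] > 0) for (restart in 1:25) {
      pts <- matrix(numeric(0), 0, 2)
      ord <- sample.int(nrow(cand))
      for (ci in ord) {
        p <- cand[ci, ]
        if (!nrow(pts) ||
            min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep) {
          pts <- rbind(pts, p)
          if (nrow(pts) == counts[k]) break
        }
      }
      if (nrow(pts) == counts[k]) break
    }
    if (nrow(pts) < counts[k]) {
      stop("simulate_marker_channel: could not place ", counts[k],
           " foci separated by ", round(min_sep, 1), " px inside object ", id)
    }
    for (j in seq_len(nrow(pts))) {
      img <- add_gaussian_spot(img, pts[j, 1], pts[j, 2], sigma_px, spot_snr)
    }
    centres[[k]] <- pts
    truth <- rbind(truth, data.frame(object_id = id,
                                     true_spot_count = counts[k],
                                     base_intensity = base[k]))
  }
  gain <- 5
  shot <- matrix(stats::rpois(length(img), pmax(img, 0) * gain) / gain,
                 nrow(img), ncol(img))
  noisy <- shot + matrix(stats::rnorm(length(img), sd = 1),
                         nrow(img), ncol(img))
  attr(truth, "spot_centres") <- centres
  list(image = noisy, clean = img, truth = truth)
}

add_gaussian_spot <- function(img, r0, c0, sigma, amp) {
  w <- ceiling(4 * sigma)
  rows <- max(1, r0 - w):min(nrow(img), r0 + w)
  cols <- max(1, c0 - w):min(ncol(img), c0 + w)
  dr <- rows - r0; dc <- cols - c0
  img[rows, cols] <- img[rows, cols] +
    amp * exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
  img
}

#' Cytoplasm labels around nuclei by Voronoi-style region growing
#'
#' Expands each nucleus by \code{radius_px} and assigns the expanded pixels
#' to the nearest nucleus, producing per-cell masks for cytoplasmic
#' measurements (nucleus mask is contained in its cell mask).
#'
#' @param label integer nucleus label mask.
#' @param radius_px cytoplasm width in pixels.
#' @return integer cell label mask (same ids as \code{label}).
#' @export
cell_masks_from_nuclei <- function(label, radius_px = 12) {
  lab <- as_image_matrix(label)
  region <- EBImage::imageData(EBImage::dilate(
    EBImage::Image((lab > 0) + 0),
    EBImage::makeBrush(2 * radius_px + 1, "disc")))
  cells <- EBImage::propagate(EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
                              seeds = EBImage::Image(lab),
                              mask = EBImage::Image(region) > 0)
  out <- EBImage::imageData(cells)
  storage.mode(out) <- "integer"
  out
}
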