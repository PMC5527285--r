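#' Per-nucleus marker intensity, background subtracted
#'
#' Background is the intensity mode of all pixels outside the label mask
#' (robust when a large area fraction is marker-positive). Per-nucleus
#' means are background-subtracted and floored at 0; set
#' \code{subtract_background = FALSE} for raw means.
#'
#' @param marker marker channel (e.g. gamma-H2AX), 2D.
#' @param label integer nucleus label mask, same geometry.
#' @param subtract_background subtract the background mode (default TRUE).
#' @return data.frame: \code{nucleus_id}, \code{mean_intensity},
#'   \code{background} (the estimate used).
#' @export
nuclear_intensity <- function(marker, label, subtract_background = TRUE) {
  img <- as_image_matrix(marker)
  lab <- as_image_matrix(label)
  if (!all(dim(img) == dim(lab))) {
    stop("nuclear_intensity: marker and label geometry mismatch (",
         paste(dim(img), collapse = "x"), " vs ",
         paste(dim(lab), collapse = "x"), ")")
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  if (!length(ids)) {
    return(data.frame(nucleus_id = integer(0), mean_intensity = numeric(0),
                      background = numeric(0)))
  }
  bg <- if (subtract_background) intensity_mode(img[lab == 0]) else 0
  means <- vapply(ids, function(id) mean(img[lab == id]), numeric(1))
  data.frame(nucleus_id = ids,
             mean_intensity = pmax(means - bg, 0),
             background = bg)
}

#' Normalize intensities to a control group
#'
#' Divides each value by the mean of the control values, so the control
#' group has normalized mean exactly 1.
#'
#' @param values numeric vector to normalize.
#' @param control_values numeric control-group vector (non-empty, positive
#'   mean).
#' @return normalized numeric vector.
#' @export
normalize_to_control <- function(values, control_values) {
  if (!length(control_values)) {
    stop("normalize_to_control: control_values is empty")
  }
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) {
    stop("normalize_to_control: control mean must be positive (got ", m, ")")
  }
  values / m
}

#' Focus detection parameters
#'
#' @param d_min_um,d_max_um diameter window of the blobs, in micrometres
#'   (physical units; pixel_size is mandatory in the detection calls).
#' @param n_scales number of log-spaced LoG scales spanning the window.
#' @param k_mad peak threshold: scale-normalized LoG response must exceed
#'   \code{k_mad} times the MAD of the response inside the region.
#' @param positive_min strict focus-count threshold for positivity
#'   (positive when count > positive_min; default 5, i.e. "more than five
#'   foci").
#' @return parameter list.
#' @export
foci_params <- function(d_min_um = 0.3, d_max_um = 1.2, n_scales = 4,
                        k_mad = 6, positive_min = 5) {
  if (d_min_um <= 0 || d_max_um <= d_min_um) {
    stop("foci_params: need 0 < d_min_um < d_max_um")
  }
  list(d_min_um = d_min_um, d_max_um = d_max_um, n_scales = n_scales,
       k_mad = k_mad, positive_min = positive_min)
}

#' Count marker foci per nucleus (Laplacian-of-Gaussian blobs)
#'
#' Scale-normalized LoG filtering over a diameter range, local-maximum
#' peak picking with a prominence threshold relative to the in-region
#' response spread (MAD), restricted to each nucleus mask. The LoG kernel
#' sums to zero, so counting is invariant to adding a constant offset to
#' the image. A cell is focus-positive when its count strictly exceeds
#' \code{positive_min} (default: more than five foci).
#'
#' @param marker marker channel (e.g. 53BP1).
#' @param label integer nucleus label mask.
#' @param pixel_size micrometres per pixel (mandatory: the diameter window
#'   is physical).
#' @param params a [foci_params()] list.
#' @return data.frame: \code{nucleus_id}, \code{focus_count},
#'   \code{positive}.
#' @export
detect_foci <- function(marker, label, pixel_size, params = foci_params()) {
  img <- as_image_matrix(marker)
  lab <- as_image_matrix(label)
  if (!all(dim(img) == dim(lab))) {
    stop("detect_foci: marker and label geometry mismatch")
  }
  if (missing(pixel_size) || pixel_size <= 0) {
    stop("detect_foci: pixel_size (um/px) is required")
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  if (!length(ids)) {
    return(data.frame(nucleus_id = integer(0), focus_count = integer(0),
                      positive = logical(0)))
  }
  # per-nucleus detection on a bounding-box crop; pixels outside the
  # nucleus are filled with the in-nucleus median so the LoG does not
  # respond to the nuclear boundary intensity step
  pad <- ceiling(params$d_max_um / pixel_size) + 2L
  counts <- vapply(ids, function(id) {
    bb <- label_bbox(lab, id, pad = pad)
    sub <- img[bb$r, bb$c]
    obj <- lab[bb$r, bb$c] == id
    sub[!obj] <- stats::median(sub[obj])
    nrow(log_blob_peaks(sub, obj, pixel_size, params))
  }, integer(1))
  data.frame(nucleus_id = ids, focus_count = counts,
             positive = counts > params$positive_min)
}

#' Count cytoplasmic marker aggregates for one cell
#'
#' Blob detection (default diameter window 0.1-1 um) restricted to the
#' cytoplasm, i.e. the cell mask minus the nucleus mask. The nucleus mask
#' must be contained in the cell mask. A cell is aggregate-positive when
#' at least one aggregate is found.
#'
#' @param marker marker channel (e.g. PML).
#' @param nucleus_mask,cell_mask binary masks, nucleus inside cell.
#' @param pixel_size micrometres per pixel.
#' @param params a [foci_params()] list; default window 0.1-1 um.
#' @return one-row data.frame: \code{aggregate_count}, \code{positive}.
#' @export
cytoplasmic_aggregates <- function(marker, nucleus_mask, cell_mask,
                                   pixel_size,
                                   params = foci_params(d_min_um = 0.1,
                                                        d_max_um = 1,
                                                        positive_min = 0)) {
  img <- as_image_matrix(marker)
  nm <- as_mask_matrix(nucleus_mask)
  cm <- as_mask_matrix(cell_mask)
  if (!all(dim(img) == dim(nm)) || !all(dim(img) == dim(cm))) {
    stop("cytoplasmic_aggregates: geometry mismatch")
  }
  if (any(nm > cm)) {
    stop("cytoplasmic_aggregates: nucleus_mask must be contained in cell_mask")
  }
  cyto <- cm == 1 & nm == 0
  if (!any(cyto)) {
    return(data.frame(aggregate_count = 0L, positive = FALSE))
  }
  # fill non-cytoplasm with the cytoplasmic median to suppress boundary
  # step responses (see detect_foci)
  img[!cyto] <- stats::median(img[cyto])
  peaks <- log_blob_peaks(img, cyto, pixel_size, params)
  n <- nrow(peaks)
  data.frame(aggregate_count = n, positive = n >= 1)
}

# Scale-normalized LoG blob detection inside `region` (logical matrix).
# Returns data.frame(r, c, response) of accepted peaks.
log_blob_peaks <- function(img, region, pixel_size, params) {
  sig_range <- c(params$d_min_um, params$d_max_um) / pixel_size / (2 * sqrt(2))
  sigmas <- exp(seq(log(sig_range[1]), log(sig_range[2]),
                    length.out = params$n_scales))
  sigmas <- pmax(sigmas, 0.5)
  ns <- length(sigmas)
  resp <- array(0, dim = c(dim(img), ns))
  knorm <- numeric(ns)
  for (si in seq_len(ns)) {
    f <- log_filter(img, sigmas[si])
    resp[, , si] <- -sigmas[si]^2 * f$response
    knorm[si] <- sigmas[si]^2 * f$kernel_l2
  }
  # pixel noise sd inside the region, from horizontal pairwise differences
  # (robust to a high blob area fraction, insensitive to constant offsets)
  sigma_px_noise <- {
    a <- img[, -ncol(img)]; b <- img[, -1]
    ok <- region[, -ncol(img)] & region[, -1]
    d <- (a[ok] - b[ok]) / sqrt(2)
    stats::mad(d, center = 0)
  }
  # null response sd at scale s is sigma_noise * ||normalized kernel||_2
  thr_s <- params$k_mad * sigma_px_noise * knorm
  thr_s[!is.finite(thr_s) | thr_s <= 0] <- Inf
  # scale-space maxima: spatial 3x3 maximum at its scale, and at least as
  # large as the same pixel at the neighbouring scales (close spots blend
  # on a max-over-scales projection, so maxima are taken per scale)
  pk <- list()
  for (si in seq_len(ns)) {
    m <- resp[, , si]
    locmax <- EBImage::imageData(EBImage::dilate(EBImage::Image(m),
                                                 EBImage::makeBrush(3, "box")))
    ok <- region & m >= locmax - 1e-12 & m > thr_s[si]
    if (si > 1) ok <- ok & m >= resp[, , si - 1]
    if (si < ns) ok <- ok & m >= resp[, , si + 1]
    cand <- which(ok, arr.ind = TRUE)
    if (nrow(cand)) {
      pk[[si]] <- data.frame(r = cand[, 1], c = cand[, 2],
                             response = m[cand], sigma = sigmas[si])
    }
  }
  if (!length(pk)) {
    return(data.frame(r = integer(0), c = integer(0), response = numeric(0),
                      sigma = numeric(0)))
  }
  pk <- do.call(rbind, pk)
  pk <- pk[order(-pk$response), ]
  # greedy scale-aware non-maximum suppression: a weaker peak within
  # 2.5 * max(sigma_i, sigma_j) of a kept peak is suppressed (this removes
  # duplicate detections across scales and the secondary ring maxima that
  # the LoG produces around strong blobs)
  min_sep_floor <- max(params$d_min_um / pixel_size, 2)
  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kr <- pk$r[keep]; kc <- pk$c[keep]; ks <- pk$sigma[keep]
    d <- sqrt((kr - pk$r[i])^2 + (kc - pk$c[i])^2)
    sep <- pmax(2.5 * pmax(ks, pk$sigma[i]), min_sep_floor)
    if (all(d >= sep)) keep[i] <- TRUE
  }
  pk[keep, , drop = FALSE]
}

# Discrete LoG filter response via EBImage::filter2 (zero-sum kernel).
# Returns the response and the kernel L2 norm (for null noise propagation).
log_filter <- function(img, sigma) {
  w <- max(2L, ceiling(3 * sigma))
  x <- (-w):w
  g <- exp(-x^2 / (2 * sigma^2))
  G <- outer(g, g)
  r2 <- outer(x^2, x^2, "+")
  k <- G * (r2 - 2 * sigma^2) / sigma^4
  k <- k - mean(k)  # enforce zero DC response
  list(response = as.matrix(EBImage::filter2(EBImage::Image(img), k,
                                             boundary = "replicate")),
       kernel_l2 = sqrt(sum(k^2)))
}
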