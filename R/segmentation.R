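#' Segmentation parameters
#'
#' @param sigma_px Gaussian smoothing sigma before thresholding.
#' @param threshold_method \code{"otsu"} (data-derived, default) or a fixed
#'   numeric threshold.
#' @param min_area_um2 objects smaller than this are dropped.
#' @param exclude_border drop objects touching the image border (incomplete
#'   shapes corrupt circularity).
#' @return parameter list.
#' @export
seg_params <- function(sigma_px = 1, threshold_method = "otsu",
                       min_area_um2 = 20, exclude_border = TRUE) {
  list(sigma_px = sigma_px, threshold_method = threshold_method,
       min_area_um2 = min_area_um2, exclude_border = exclude_border)
}

#' Segment nuclei from a DNA channel
#'
#' Gaussian smoothing, global threshold (Otsu by default), hole filling,
#' 8-connected component labelling (thin chromatin bridges keep extruded
#' lobes attached to the main body), removal of small and border-touching
#' objects, then per-object shape metrics via [contour_metrics()].
#'
#' @param dna single-channel 2D image (matrix or EBImage Image).
#' @param pixel_size micrometres per pixel.
#' @param params a [seg_params()] list.
#' @return list with \code{label} (integer mask, ids 1..n) and
#'   \code{records} (data.frame: \code{nucleus_id}, shape metrics). A blank
#'   image yields zero records, not an error.
#' @export
segment_nuclei <- function(dna, pixel_size, params = seg_params()) {
  img <- as_image_matrix(dna)
  if (missing(pixel_size) || !is.numeric(pixel_size) || pixel_size <= 0) {
    stop("segment_nuclei: pixel_size (um/px) is required and must be > 0")
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = params$sigma_px))
  thr <- if (identical(params$threshold_method, "otsu")) {
    otsu_threshold(as.vector(sm))
  } else if (is.numeric(params$threshold_method)) {
    params$threshold_method
  } else stop("segment_nuclei: threshold_method must be 'otsu' or numeric")
  bw <- (sm > thr) + 0
  if (sum(bw) == 0) {
    return(list(label = matrix(0L, nrow(img), ncol(img)),
                records = empty_nucleus_records()))
  }
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw)))
  lab <- label8(bw)

  min_px <- params$min_area_um2 / pixel_size^2
  keep <- integer(0)
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_px) next
    if (params$exclude_border &&
        (min(idx) == 1L || max(idx[, 1]) == nrow(lab) ||
         max(idx[, 2]) == ncol(lab))) next
    keep <- c(keep, id)
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  recs <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    sel <- lab == keep[j]
    out[sel] <- j
    bb <- label_bbox(out, j, pad = 2L)
    met <- contour_metrics((out[bb$r, bb$c] == j) + 0, pixel_size)
    met$centroid_x <- met$centroid_x + (bb$r[1] - 1) * pixel_size
    met$centroid_y <- met$centroid_y + (bb$c[1] - 1) * pixel_size
    recs[[j]] <- cbind(nucleus_id = j, met)
  }
  records <- if (length(recs)) do.call(rbind, recs) else empty_nucleus_records()
  list(label = out, records = records)
}

empty_nucleus_records <- function() {
  data.frame(nucleus_id = integer(0), area = numeric(0),
             perimeter = numeric(0), circularity = numeric(0),
             circularity_raw = numeric(0), aspect_ratio = numeric(0),
             centroid_x = numeric(0), centroid_y = numeric(0),
             area_px = numeric(0))
}

#' Envelope-marker coverage of each nucleus boundary
#'
#' Samples the ordered boundary of each nucleus; a boundary pixel counts as
#' covered when the envelope-channel intensity within a rim band
#' (\code{rim_band_px}, Chebyshev radius) exceeds a rim threshold (Otsu on
#' the rim-band pixels of the whole image, so coverage is invariant to
#' uniform intensity rescaling). Also reports the longest contiguous
#' uncovered arc and the fraction of the nucleus area closer to an
#' uncovered boundary arc than to a covered one.
#'
#' @param label integer nucleus label mask.
#' @param envelope envelope-marker channel, same geometry.
#' @param pixel_size micrometres per pixel.
#' @param rim_band_px rim band half-width in pixels.
#' @param rim_threshold fixed threshold overriding the Otsu default.
#' @return data.frame: \code{nucleus_id}, \code{envelope_coverage},
#'   \code{uncovered_dna_fraction}, \code{max_gap_um}.
#' @export
assess_envelope_coverage <- function(label, envelope, pixel_size,
                                     rim_band_px = 3, rim_threshold = NULL) {
  lab <- as_image_matrix(label)
  env <- as_image_matrix(envelope)
  if (!all(dim(lab) == dim(env))) {
    stop("assess_envelope_coverage: label and envelope geometry mismatch (",
         paste(dim(lab), collapse = "x"), " vs ",
         paste(dim(env), collapse = "x"), ")")
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  if (!length(ids)) {
    return(data.frame(nucleus_id = integer(0), envelope_coverage = numeric(0),
                      uncovered_dna_fraction = numeric(0),
                      max_gap_um = numeric(0)))
  }
  box <- EBImage::makeBrush(2 * rim_band_px + 1, "box")
  allmask <- (lab > 0) + 0
  boundary_all <- allmask - EBImage::imageData(
    EBImage::erode(EBImage::Image(allmask), EBImage::makeBrush(3, "box")))
  band <- EBImage::imageData(EBImage::dilate(EBImage::Image(boundary_all), box))
  thr <- rim_threshold %||% otsu_threshold(env[band > 0])
  # max envelope intensity within the rim band of every pixel
  envmax <- EBImage::imageData(EBImage::dilate(EBImage::Image(env), box))

  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    obj <- (lab == id) + 0
    oc <- EBImage::ocontour(EBImage::Image(obj))[[1]]  # ordered, 0-based (x=row-1, y=col-1)
    br <- oc[, 1] + 1L; bc <- oc[, 2] + 1L
    covered <- envmax[cbind(br, bc)] > thr
    coverage <- mean(covered)
    # arc lengths between consecutive contour points (closed)
    nb <- length(br)
    nxt <- c(2:nb, 1)
    step <- sqrt((br[nxt] - br)^2 + (bc[nxt] - bc)^2) * pixel_size
    max_gap <- longest_false_run_length(covered, step)
    unc_frac <- if (coverage >= 1) 0 else if (coverage <= 0) 1 else {
      pix <- which(obj > 0, arr.ind = TRUE)
      dcov <- nearest_dist(pix, cbind(br, bc)[covered, , drop = FALSE])
      dunc <- nearest_dist(pix, cbind(br, bc)[!covered, , drop = FALSE])
      mean(dunc < dcov)
    }
    out[[j]] <- data.frame(nucleus_id = id, envelope_coverage = coverage,
                           uncovered_dna_fraction = unc_frac,
                           max_gap_um = max_gap)
  }
  do.call(rbind, out)
}

# Longest circular run of FALSE, weighted by the step lengths.
longest_false_run_length <- function(flag, step) {
  if (all(flag)) return(0)
  if (!any(flag)) return(sum(step))
  n <- length(flag)
  f2 <- c(flag, flag); s2 <- c(step, step)
  best <- 0; cur <- 0
  for (i in seq_len(2 * n)) {
    if (!f2[i]) { cur <- cur + s2[i]; best <- max(best, cur) } else cur <- 0
  }
  min(best, sum(step))
}

# Min distance from each point in A (n x 2) to the point set B (m x 2).
nearest_dist <- function(A, B) {
  if (nrow(B) == 0) return(rep(Inf, nrow(A)))
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Classification thresholds for nuclear phenotypes
#'
#' @param c_min circularity below which a nucleus is called deformed. The
#'   default 0.65 is an operational calibration on the synthetic generator;
#'   the emulated study scored deformation visually.
#' @param g_min minimum uncovered boundary fraction for a rupture call
#'   (ruptured when coverage < 1 - g_min).
#' @param L_min_um minimum contiguous uncovered arc length in um.
#' @return parameter list.
#' @export
classify_params <- function(c_min = 0.65, g_min = 0.05, L_min_um = 1) {
  list(c_min = c_min, g_min = g_min, L_min_um = L_min_um)
}

#' Classify nuclei as deformed and/or ruptured
#'
#' Deformed: circularity below \code{c_min}. Ruptured: envelope coverage
#' below \code{1 - g_min} with a contiguous uncovered arc of at least
#' \code{L_min_um}. The flags are independent (a ruptured nucleus need not
#' be deformed). \code{phenotype_class} applies the exclusive precedence
#' ruptured > deformed > normal for cohort scoring.
#'
#' @param records data.frame with \code{circularity},
#'   \code{envelope_coverage} and \code{max_gap_um} columns (join of
#'   [segment_nuclei()] records and [assess_envelope_coverage()]).
#' @param thresholds a [classify_params()] list.
#' @return \code{records} with logical columns \code{deformed},
#'   \code{ruptured} and a character \code{phenotype_class}.
#' @export
classify_phenotype <- function(records, thresholds = classify_params()) {
  need <- c("circularity", "envelope_coverage", "max_gap_um")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("classify_phenotype: missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyNA(records[need])) {
    stop("classify_phenotype: metrics or coverage contain NA; populate them first")
  }
  records$deformed <- records$circularity < thresholds$c_min
  records$ruptured <- records$envelope_coverage < (1 - thresholds$g_min) &
    records$max_gap_um >= thresholds$L_min_um
  records$phenotype_class <- ifelse(records$ruptured, "ruptured",
                             ifelse(records$deformed, "deformed", "normal"))
  records
}

#' Cohort summary of phenotype fractions
#'
#' Fractions use the exclusive phenotype class (ruptured > deformed >
#' normal). Cohorts below 100 cells trigger a warning, mirroring the
#' scoring convention of n > 100 cells per condition.
#'
#' @param records classified records from [classify_phenotype()].
#' @param group_label cohort label.
#' @return one-row data.frame: \code{group_label}, \code{n_cells},
#'   \code{fraction_deformed}, \code{fraction_ruptured},
#'   \code{fraction_normal}.
#' @export
score_cohort <- function(records, group_label = "cohort") {
  if (!nrow(records)) stop("score_cohort: no records")
  if (!"phenotype_class" %in% names(records)) {
    stop("score_cohort: records must be classified (run classify_phenotype)")
  }
  n <- nrow(records)
  if (n < 100) {
    warning("score_cohort: cohort '", group_label, "' has only ", n,
            " cells (< 100); fraction estimates will be noisy")
  }
  data.frame(group_label = group_label, n_cells = n,
             fraction_deformed = mean(records$phenotype_class == "deformed"),
             fraction_ruptured = mean(records$phenotype_class == "ruptured"),
             fraction_normal = mean(records$phenotype_class == "normal"),
             stringsAsFactors = FALSE)
}
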