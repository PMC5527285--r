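# Internal helpers shared across modules.

# Coerce an image-like object (matrix, EBImage::Image, logical) to a plain
# 0/1 numeric matrix, erroring on anything but 2D.
as_mask_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.logical(x)) x <- x + 0
  if (!is.matrix(x)) stop("expected a 2D matrix (got ", class(x)[1], ")")
  (x != 0) + 0
}

as_image_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a 2D numeric matrix")
  x
}

# 8-connected labelling. EBImage::bwlabel is 4-connected; thin diagonal
# chromatin bridges must keep extruded lobes attached, so 4-connected labels
# that touch diagonally are merged with a union-find pass.
label8 <- function(mask) {
  m <- as_mask_matrix(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m)))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (s in list(c(1L, 1L), c(1L, -1L))) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - 1L); c1 <- if (dc > 0) seq_len(nc - 1L) else 2L:nc
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + dr, c1 + dc, drop = FALSE]
    sel <- which(a > 0 & b > 0 & a != b)
    for (k in sel) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Otsu threshold on a numeric vector (maximizes between-class variance over
# a 256-bin histogram). Returns the bin upper edge; "covered"/"foreground"
# tests use strict > so an all-zero input yields nothing above threshold.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(Inf)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(findInterval(x, seq(rng[1], rng[2],
        length.out = nbins + 1L), all.inside = TRUE), 1L), nbins), nbins)
  w <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = nbins + 1L)
  mids <- (mids[-1] + mids[-length(mids)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  mids[k]
}

# Mode of a numeric sample via a histogram with Freedman-Diaconis-ish bins.
# Used as the background estimate: robust to large marker-positive fractions.
intensity_mode <- function(x, nbins = NULL) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(0)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  if (is.null(nbins)) nbins <- max(32L, min(512L, round(sqrt(length(x)))))
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(pmin(findInterval(x, br, all.inside = TRUE), nbins), nbins)
  k <- which.max(h)
  (br[k] + br[k + 1L]) / 2
}

# Bounding box (row/col ranges) of a label in a label matrix, padded.
label_bbox <- function(lab, id, pad = 0L) {
  idx <- which(lab == id, arr.ind = TRUE)
  list(
    r = max(1L, min(idx[, 1]) - pad):min(nrow(lab), max(idx[, 1]) + pad),
    c = max(1L, min(idx[, 2]) - pad):min(ncol(lab), max(idx[, 2]) + pad)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
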