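# Preprocessing: raw RGB photograph -> denoised image -> HSV ->
# saturation-thresholded binary mask -> cleaned single-component mask ->
# white-background image. Segmentation exploits the saturation gap between
# the colourful tuber and the near-achromatic background.

#' Median-filter an RGB image
#'
#' Per-channel median filter with an odd square kernel.
#'
#' @param img H x W x 3 RGB array, 0..255.
#' @param kernel odd kernel side length, >= 3.
#' @return filtered image, same shape and depth.
#' @export
median_denoise <- function(img, kernel = 3L) {
  assert_rgb_image(img)
  if (kernel %% 2 != 1 || kernel < 3)
    stop("kernel must be an odd integer >= 3", call. = FALSE)
  half <- (kernel - 1L) %/% 2L
  out <- img
  for (ch in 1:3) {
    out[, , ch] <- if (kernel == 3L) median3x3(img[, , ch]) else
      round(EBImage::medianFilter(img[, , ch] / 255, half) * 255)
  }
  out
}

# exact 3x3 median via a 19-comparison sorting network, vectorised over all
# pixels; borders use edge replication (so constant images stay constant)
median3x3 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  xp <- x[c(1, seq_len(h), h), c(1, seq_len(w), w)]  # replicate-pad
  n <- vector("list", 9)
  k <- 0
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1
    n[[k]] <- xp[dr + seq_len(h), dc + seq_len(w)]
  }
  sw <- function(i, j) {
    lo <- pmin(n[[i]], n[[j]]); hi <- pmax(n[[i]], n[[j]])
    n[[i]] <<- lo; n[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  n[[5]]
}

#' Otsu threshold of a channel by maximum between-class variance
#'
#' Builds a 256-bin histogram over [0, 1] and returns the bin-edge threshold
#' maximising the between-class variance; ties resolve to the lowest.
#'
#' @param x numeric matrix or vector with values in [0, 1].
#' @return scalar threshold in [0, 1].
#' @export
otsu_threshold <- function(x) {
  v <- as.vector(x)
  if (max(v) - min(v) < 1e-12)
    stop("degenerate histogram: channel is constant, cannot auto-threshold",
         call. = FALSE)
  bins <- pmin(floor(v * 256), 255)           # bin k covers [k/256, (k+1)/256)
  counts <- tabulate(bins + 1L, nbins = 256L)
  p <- counts / sum(counts)
  mids <- (0:255 + 0.5) / 256
  omega <- cumsum(p)                          # class 0: bins 0..k
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  k <- which.max(sigma_b[-256])               # threshold strictly inside range
  (k) / 256                                   # upper edge of bin k-1 (0-based)
}

#' Segment the saturation channel into a raw binary mask
#'
#' Foreground pixels are those with saturation strictly above the threshold.
#' With `threshold = "auto"` the threshold is chosen by Otsu's criterion on
#' the 256-bin saturation histogram.
#'
#' @param hsv HSV image list as returned by [rgb_to_hsv()].
#' @param threshold numeric in [0, 1], or "auto".
#' @return logical matrix (raw mask, before cleanup).
#' @export
segment_saturation <- function(hsv, threshold = "auto") {
  s <- hsv$s
  if (identical(threshold, "auto")) threshold <- otsu_threshold(s)
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  s > threshold
}

#' Clean a raw mask: largest component, holes filled
#'
#' Keeps the largest 8-connected foreground component, then fills every
#' interior hole (background regions not 4-connected to the raster border).
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return logical matrix with a single hole-free component.
#' @export
clean_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask))
    stop("segmentation failure: empty mask", call. = FALSE)
  labels <- label_components(mask)
  sizes <- tabulate(labels[labels > 0L])
  keep <- labels == which.max(sizes)
  # border-connected background under 4-connectivity; the rest are holes
  h <- nrow(keep); w <- ncol(keep)
  border <- c(seq_len(h), seq_len(h) + (w - 1L) * h,       # first/last column
              (seq_len(w) - 1L) * h + 1L, (seq_len(w)) * h) # first/last row
  outside <- flood_reach(!keep, unique(border), .nbr4)
  keep | !outside
}

#' Whiten the background of an image
#'
#' Sets every background pixel to pure white (255, 255, 255); foreground
#' pixels are passed through untouched.
#'
#' @param img H x W x 3 RGB array.
#' @param mask logical foreground mask of matching size.
#' @return a `clean_image`: list with `pixels` (RGB array) and `mask`.
#' @export
whiten_background <- function(img, mask) {
  assert_rgb_image(img)
  if (!is.logical(mask) || !all(dim(mask) == dim(img)[1:2]))
    stop("mask must be a logical matrix matching the image size", call. = FALSE)
  px <- img
  bg <- !mask
  for (ch in 1:3) {
    channel <- px[, , ch]
    channel[bg] <- 255
    px[, , ch] <- channel
  }
  structure(list(pixels = px, mask = mask), class = "clean_image")
}

#' Full preprocessing pipeline for one image
#'
#' Median denoise, HSV conversion, saturation segmentation, mask cleanup,
#' background whitening.
#'
#' @param img H x W x 3 RGB array, 0..255.
#' @param kernel median-filter kernel (odd, >= 3).
#' @param threshold saturation threshold in [0, 1], or "auto" (Otsu).
#' @return a `clean_image` (list of `pixels` and `mask`).
#' @export
preprocess_image <- function(img, kernel = 3L, threshold = "auto") {
  den <- median_denoise(img, kernel)
  hsv <- rgb_to_hsv(den)
  raw <- segment_saturation(hsv, threshold)
  whiten_background(den, clean_mask(raw))
}
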