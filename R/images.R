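#' @keywords internal
"_PACKAGE"

# Shared raster primitives. An RGB image is an H x W x 3 numeric array of
# integer values in 0..255 (channel order R, G, B); an HSV image is a list of
# three H x W matrices h in [0,1), s and v in [0,1]; a mask is a logical
# matrix. Rows index image rows (top to bottom), columns index image columns.

#' Validate an 8-bit RGB image array
#'
#' @param img numeric array, H x W x 3, values in 0..255.
#' @return `img`, invisibly, after validation.
#' @keywords internal
assert_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  if (dim(img)[1] < 16L || dim(img)[2] < 16L)
    stop("image must be at least 16 x 16 pixels", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("image values must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

#' Convert an RGB image to HSV channels
#'
#' Standard hexcone transform. Hue is scaled to [0, 1) (0 and 1 identified),
#' saturation and value to [0, 1], matching the convention used throughout
#' the feature pipeline.
#'
#' @param img H x W x 3 RGB array with 8-bit values in 0..255.
#' @return list with matrices `h`, `s`, `v`.
#' @export
rgb_to_hsv <- function(img) {
  assert_rgb_image(img)
  d <- dim(img)[1:2]
  hsv <- grDevices::rgb2hsv(
    r = as.vector(img[, , 1]),
    g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3]),
    maxColorValue = 255
  )
  h <- matrix(hsv[1, ], d[1], d[2])
  h[h >= 1] <- 0  # wrap convention: hue lives in [0, 1)
  list(h = h,
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' Convert HSV channels to an 8-bit RGB image
#'
#' Inverse hexcone transform, vectorised over pixels.
#'
#' @param h,s,v matrices of equal dimension; h in [0,1), s and v in [0,1].
#' @return H x W x 3 array of integers in 0..255.
#' @export
hsv_to_rgb <- function(h, s, v) {
  stopifnot(all(dim(h) == dim(s)), all(dim(h) == dim(v)))
  hh <- as.vector(h) %% 1 * 6
  i <- floor(hh)
  f <- hh - i
  vv <- as.vector(v); ss <- as.vector(s)
  p <- vv * (1 - ss)
  q <- vv * (1 - ss * f)
  t <- vv * (1 - ss * (1 - f))
  r <- g <- b <- numeric(length(vv))
  idx <- i %% 6
  sel <- idx == 0; r[sel] <- vv[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- idx == 1; r[sel] <- q[sel]; g[sel] <- vv[sel]; b[sel] <- p[sel]
  sel <- idx == 2; r[sel] <- p[sel]; g[sel] <- vv[sel]; b[sel] <- t[sel]
  sel <- idx == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- vv[sel]
  sel <- idx == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- vv[sel]
  sel <- idx == 5; r[sel] <- vv[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  out <- array(0, c(dim(h), 3L))
  out[, , 1] <- round(255 * matrix(r, nrow(h)))
  out[, , 2] <- round(255 * matrix(g, nrow(h)))
  out[, , 3] <- round(255 * matrix(b, nrow(h)))
  out
}

#' Read an RGB image from a PNG or JPEG-free PNG file
#'
#' @param path file path to an 8-bit PNG.
#' @return H x W x 3 array of integers in 0..255.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  round(px[, , 1:3, drop = FALSE] * 255)
}

#' Write an RGB image or mask as PNG
#'
#' Masks are written as 0/255 grayscale.
#'
#' @param img H x W x 3 RGB array (0..255) or logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.logical(img)) {
    png::writePNG(img * 1, path)
  } else {
    png::writePNG(img / 255, path)
  }
  invisible(path)
}

# 8-connected (queen) neighbour offsets as (drow, dcol) pairs
.nbr8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
.nbr4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))

# Flood fill from seed linear indices over a logical matrix, returning the
# reachable set as a logical matrix. `offsets` selects the connectivity.
flood_reach <- function(open, seeds, offsets) {
  h <- nrow(open); w <- ncol(open)
  reached <- matrix(FALSE, h, w)
  seeds <- seeds[open[seeds] & !reached[seeds]]
  reached[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    r0 <- (frontier - 1L) %% h + 1L
    c0 <- (frontier - 1L) %/% h + 1L
    nr <- rep(r0, each = nrow(offsets)) + offsets[, 1]
    nc <- rep(c0, each = nrow(offsets)) + offsets[, 2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    idx <- (nc[ok] - 1L) * h + nr[ok]
    idx <- unique(idx[open[idx] & !reached[idx]])
    reached[idx] <- TRUE
    frontier <- idx
  }
  reached
}

#' Label connected components of a binary mask
#'
#' Foreground components use 8-connectivity (the standard dual of the
#' 4-connected background used for hole filling).
#'
#' @param mask logical matrix.
#' @return integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  lab <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- flood_reach(remaining, seed, .nbr8)
    lab <- lab + 1L
    labels[comp] <- lab
    remaining <- remaining & !comp
  }
  labels
}
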