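# The 17-element feature vector: 3 shape descriptors (circularity,
# rectangularity, aspect ratio), 2 colour features (foreground means of the
# HSV hue and saturation channels), and 12 texture statistics (ASM,
# contrast, correlation, entropy from gray-level co-occurrence matrices at
# distances 1, 2, 4 px, each averaged over the four principal angles).

#' Canonical feature names, in table order
#' @return character vector of length 17.
#' @export
feature_names <- function() {
  c("C", "R", "L", "mean_h", "mean_s",
    as.vector(outer(c("ASM", "CON", "COR", "ENT"), c("d1", "d2", "d4"),
                    function(a, b) paste(a, b, sep = "_"))))
}

# Moore-neighbour boundary trace of a single-component, hole-free mask.
# Returns the chain-code perimeter: 1 per axis step, sqrt(2) per diagonal.
chain_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  if (sum(mask) == 1L) return(0)
  # pad so the trace never leaves the raster
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[2:(h + 1L), 2:(w + 1L)] <- mask
  # start: first foreground pixel in column-major order; its west neighbour
  # is guaranteed background
  start <- which(m)[1]
  sr <- (start - 1L) %% (h + 2L) + 1L
  sc <- (start - 1L) %/% (h + 2L) + 1L
  # clockwise Moore neighbourhood starting at west: W, NW, N, NE, E, SE, S, SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  step_len <- ifelse(dr != 0L & dc != 0L, sqrt(2), 1)
  per <- 0
  cr <- sr; cc <- sc
  enter <- 1L  # direction index of the backtrack (west of start is background)
  first_move <- NA_integer_
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (enter + k - 1L) %% 8L + 1L
      nr <- cr + dr[d]; nc <- cc + dc[d]
      if (m[nr, nc]) {
        per <- per + step_len[d]
        # next scan starts from the neighbour we came from (backtrack)
        prev_r <- cr; prev_c <- cc
        cr <- nr; cc <- nc
        # direction from new pixel back toward previous pixel, advanced by one
        back <- which(dr == (prev_r - cr) & dc == (prev_c - cc))
        enter <- back %% 8L + 1L
        if (is.na(first_move)) first_move <- d
        found <- TRUE
        break
      }
    }
    if (!found) return(0)  # isolated pixel
    if (cr == sr && cc == sc) break
  }
  per
}

#' Region properties of a single-component mask
#'
#' Area (pixel count), chain-code perimeter (diagonal steps weighted
#' sqrt(2)), major/minor axis lengths of the moment-equivalent ellipse
#' (4 * sqrt of the eigenvalues of the foreground coordinate covariance,
#' with the standard +1/12 unit-pixel correction), axis-aligned bounding
#' box, and bounding-box area.
#'
#' @param mask logical matrix with exactly one 8-connected component and no
#'   holes.
#' @return list with `A`, `P`, `J`, `I`, `bbox` (row0, col0, height, width;
#'   0-based, half-open) and `A_R`.
#' @export
region_props <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  labels <- label_components(mask)
  if (max(labels) != 1L)
    stop("mask must contain a single connected component", call. = FALSE)
  idx <- which(mask)
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  A <- length(idx)
  # population covariance + 1/12 (second moment of a unit square)
  mr <- mean(rows); mc <- mean(cols)
  crr <- mean((rows - mr)^2) + 1 / 12
  ccc <- mean((cols - mc)^2) + 1 / 12
  crc <- mean((rows - mr) * (cols - mc))
  tr2 <- (crr + ccc) / 2
  det_rt <- sqrt(((crr - ccc) / 2)^2 + crc^2)
  J <- 4 * sqrt(tr2 + det_rt)
  I <- 4 * sqrt(max(tr2 - det_rt, 0))
  bbox <- c(row0 = min(rows) - 1L, col0 = min(cols) - 1L,
            height = diff(range(rows)) + 1L, width = diff(range(cols)) + 1L)
  list(A = A, P = chain_perimeter(mask), J = J, I = I,
       bbox = bbox, A_R = unname(bbox["height"] * bbox["width"]))
}

#' Circularity: 4 pi A / P^2
#'
#' Equals 1 for a continuous disc; decreases for elongated or rough
#' outlines. Not clamped: discrete perimeter estimation can push it
#' slightly above 1.
#'
#' @param props output of [region_props()].
#' @return scalar circularity.
#' @export
circularity <- function(props) {
  if (props$P <= 0) stop("perimeter must be positive", call. = FALSE)
  4 * pi * props$A / props$P^2
}

#' Rectangularity: area over bounding-box area
#' @param props output of [region_props()].
#' @return scalar in (0, 1].
#' @export
rectangularity <- function(props) {
  if (props$A_R <= 0) stop("bounding box must be non-degenerate", call. = FALSE)
  props$A / props$A_R
}

#' Aspect ratio: major over minor axis length
#' @param props output of [region_props()].
#' @return scalar >= 1.
#' @export
aspect_ratio <- function(props) {
  if (props$I <= 0) stop("minor axis must be positive", call. = FALSE)
  props$J / props$I
}

#' Foreground means of the hue and saturation channels
#'
#' Arithmetic means over foreground pixels only, after converting the
#' white-background image to HSV. Hue is averaged arithmetically (matching
#' the reference MATLAB `mean2` semantics); hues near the 0/1 wrap point
#' will average incorrectly, which the default prototypes avoid.
#'
#' @param clean a `clean_image`.
#' @param foreground_only if FALSE, average over the full frame (white
#'   background included), for fidelity experiments.
#' @return named numeric: `mean_h`, `mean_s`.
#' @export
mean_hs <- function(clean, foreground_only = TRUE) {
  stopifnot(inherits(clean, "clean_image"))
  if (!any(clean$mask)) stop("empty mask", call. = FALSE)
  hsv <- rgb_to_hsv(clean$pixels)
  if (foreground_only) {
    c(mean_h = mean(hsv$h[clean$mask]), mean_s = mean(hsv$s[clean$mask]))
  } else {
    c(mean_h = mean(hsv$h), mean_s = mean(hsv$s))
  }
}

#' GLCM configuration
#'
#' @param G number of gray levels (2..256).
#' @param distances pixel offsets at which pairs are counted.
#' @param angles subset of c(0, 45, 90, 135), degrees.
#' @param symmetric count each pair in both directions.
#' @param foreground_only restrict pair counting to foreground pixels.
#' @return a `glcm_config` list.
#' @export
glcm_config <- function(G = 16L, distances = c(1L, 2L, 4L),
                        angles = c(0, 45, 90, 135),
                        symmetric = TRUE, foreground_only = TRUE) {
  stopifnot(G >= 2, G <= 256, all(distances >= 1),
            all(angles %in% c(0, 45, 90, 135)))
  structure(list(G = as.integer(G), distances = as.integer(distances),
                 angles = angles, symmetric = symmetric,
                 foreground_only = foreground_only),
            class = "glcm_config")
}

#' Quantize an image to G gray levels
#'
#' Rec.601 luminance (0.299 R + 0.587 G + 0.114 B), uniformly quantized
#' into G equal-width bins over [0, 255].
#'
#' @param clean a `clean_image` (or raw RGB array).
#' @param G number of gray levels.
#' @return integer matrix of levels 0..G-1.
#' @export
quantize_gray <- function(clean, G = 16L) {
  stopifnot(G >= 2)
  px <- if (inherits(clean, "clean_image")) clean$pixels else clean
  lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  lev <- floor((lum + 1e-9) * G / 256)   # epsilon guards fp sums like 127.999...
  matrix(as.integer(pmin(pmax(lev, 0), G - 1)), nrow(lum), ncol(lum))
}

# displacement (drow, dcol) for distance d at angle theta (degrees),
# following the raster convention (dx, dy) = d (cos theta, -sin theta):
# dcol = dx, drow = dy.
glcm_offset <- function(d, theta) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels at displacement d along angle theta,
#' restricted to positions where both pixels are valid; optionally
#' symmetrised (transpose added); normalised to sum 1. Marginal means and
#' standard deviations are attached for the correlation statistic.
#'
#' @param gray integer matrix of levels 0..G-1.
#' @param valid logical matrix of valid pixels (e.g. the foreground mask),
#'   or NULL for the full frame.
#' @param d pair distance in pixels.
#' @param theta angle in degrees: 0, 45, 90 or 135.
#' @param G number of gray levels.
#' @param symmetric add the transposed counts.
#' @return a `glcm` list: `p` (G x G), `mu_x`, `mu_y`, `sd_x`, `sd_y`,
#'   plus `d`, `theta`.
#' @export
glcm <- function(gray, valid = NULL, d = 1L, theta = 0, G = 16L,
                 symmetric = TRUE) {
  stopifnot(d >= 1)
  h <- nrow(gray); w <- ncol(gray)
  if (is.null(valid)) valid <- matrix(TRUE, h, w)
  off <- glcm_offset(as.integer(d), theta)
  dr <- off[1]; dc <- off[2]
  rlo <- max(1L, 1L - dr); rhi <- min(h, h - dr)
  clo <- max(1L, 1L - dc); chi <- min(w, w - dc)
  if (rlo > rhi || clo > chi)
    stop("no valid pixel pair at this offset", call. = FALSE)
  r1 <- rlo:rhi
  c1 <- clo:chi
  a <- gray[r1, c1, drop = FALSE]
  b <- gray[r1 + dr, c1 + dc, drop = FALSE]
  ok <- valid[r1, c1, drop = FALSE] & valid[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok)) stop("no valid pixel pair at this offset", call. = FALSE)
  counts <- matrix(tabulate(a[ok] * G + b[ok] + 1L, nbins = G * G), G, G,
                   byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  lev <- 0:(G - 1)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  structure(list(p = p,
                 mu_x = mu_x, mu_y = mu_y,
                 sd_x = sqrt(sum((lev - mu_x)^2 * px)),
                 sd_y = sqrt(sum((lev - mu_y)^2 * py)),
                 d = d, theta = theta),
            class = "glcm")
}

#' Haralick statistics of a GLCM
#'
#' ASM = sum p^2; CON = sum (i-j)^2 p; COR = |sum i j p - mu_x mu_y| /
#' (sd_x sd_y), defined as 0 when a marginal is degenerate; ENT =
#' -sum p log2 p over positive entries.
#'
#' @param m a `glcm`.
#' @return named numeric: `ASM`, `CON`, `COR`, `ENT`.
#' @export
glcm_stats <- function(m) {
  stopifnot(inherits(m, "glcm"))
  p <- m$p
  G <- nrow(p)
  lev <- 0:(G - 1)
  i <- matrix(lev, G, G)        # row index
  j <- matrix(lev, G, G, byrow = TRUE)
  asm <- sum(p^2)
  con <- sum((i - j)^2 * p)
  denom <- m$sd_x * m$sd_y
  cor <- if (denom > 0) abs(sum(i * j * p) - m$mu_x * m$mu_y) / denom else 0
  pos <- p[p > 0]
  ent <- -sum(pos * log2(pos))
  c(ASM = asm, CON = con, COR = cor, ENT = ent)
}

#' Angle-averaged texture feature vector
#'
#' For each configured distance, the four Haralick statistics are computed
#' at each configured angle and averaged over angles, giving (by default)
#' 4 statistics x 3 distances = 12 values.
#'
#' @param clean a `clean_image`.
#' @param cfg a `glcm_config`.
#' @return named numeric vector (`ASM_d1`, `CON_d1`, ..., `ENT_d4`).
#' @export
texture_features <- function(clean, cfg = glcm_config()) {
  stopifnot(inherits(clean, "clean_image"), inherits(cfg, "glcm_config"))
  gray <- quantize_gray(clean, cfg$G)
  valid <- if (cfg$foreground_only) clean$mask else NULL
  out <- numeric(0)
  for (d in cfg$distances) {
    stats_mat <- vapply(cfg$angles, function(th)
      glcm_stats(glcm(gray, valid, d = d, theta = th, G = cfg$G,
                      symmetric = cfg$symmetric)),
      numeric(4))
    avg <- rowMeans(stats_mat)
    names(avg) <- paste(c("ASM", "CON", "COR", "ENT"), paste0("d", d), sep = "_")
    out <- c(out, avg)
  }
  out
}

#' Extract the full 17-element feature vector for one image
#'
#' @param clean a `clean_image`.
#' @param cfg a `glcm_config`.
#' @return named numeric vector of length 17 in canonical order.
#' @export
extract_features <- function(clean, cfg = glcm_config()) {
  props <- region_props(clean$mask)
  shape <- c(C = circularity(props), R = rectangularity(props),
             L = aspect_ratio(props))
  v <- c(shape, mean_hs(clean), texture_features(clean, cfg))
  stopifnot(identical(names(v), feature_names()))
  v
}

#' Feature table for a set of synthetic samples
#'
#' Preprocesses each rendered sample and extracts its feature vector.
#'
#' @param samples list of samples from [generate_dataset()].
#' @param cfg a `glcm_config`.
#' @param kernel,threshold preprocessing parameters (see
#'   [preprocess_image()]).
#' @return data.frame: `sample_id`, `origin`, `species`, then the 17
#'   feature columns.
#' @export
feature_table <- function(samples, cfg = glcm_config(), kernel = 3L,
                          threshold = "auto") {
  rows <- lapply(samples, function(s) {
    clean <- preprocess_image(s$image, kernel = kernel, threshold = threshold)
    v <- extract_features(clean, cfg)
    cbind(data.frame(sample_id = s$sample_id, origin = s$origin,
                     species = s$species, stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
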