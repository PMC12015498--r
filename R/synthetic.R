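# Synthetic tuber-image generator. Each sample is a single convex-ish blob
# (ellipse plus a bounded low-order radial perturbation) filled with an HSV
# colour drawn from its class prototype, with the value channel modulated by
# a smoothed Gaussian random field (the "roughness" texture handle), over a
# low-saturation background, plus i.i.d. 8-bit channel noise.

.origin_levels <- c("SC", "GX", "FJ", "JX")
.species_levels <- c("A", "B")

#' Species implied by a geographic origin
#'
#' Origins SC and GX belong to species A (*Alisma plantago-aquatica*);
#' FJ and JX to species B (*Alisma orientale*).
#'
#' @param origin character vector of origin codes.
#' @return character vector of species codes ("A" or "B").
#' @export
origin_species <- function(origin) {
  if (!all(origin %in% .origin_levels))
    stop("unknown origin label; expected one of ", paste(.origin_levels, collapse = ", "),
         call. = FALSE)
  ifelse(origin %in% c("SC", "GX"), "A", "B")
}

#' Construct a class prototype for the synthetic generator
#'
#' A prototype fixes the sampling distributions for one origin class: the
#' blob's major/minor axis ratio, its hue and saturation means (HSV scale,
#' [0,1]), and the surface-roughness texture field (relative amplitude and
#' correlation length in pixels).
#'
#' @param origin one of "SC", "GX", "FJ", "JX".
#' @param axis_ratio_mean,axis_ratio_sd mean (>= 1) and sd of the axis ratio.
#' @param hue_mean,hue_sd mean in [0,1) and sd of the foreground hue.
#' @param sat_mean,sat_sd mean in (0,1] and sd of the foreground saturation.
#' @param roughness_amp relative amplitude (>= 0) of the value-channel
#'   texture field; 0 gives a perfectly flat fill.
#' @param roughness_scale correlation length of the texture field, px (>= 1).
#' @return a `class_prototype` list; `species` is derived from `origin`.
#' @export
class_prototype <- function(origin, axis_ratio_mean, axis_ratio_sd,
                            hue_mean, hue_sd, sat_mean, sat_sd,
                            roughness_amp, roughness_scale) {
  stopifnot(axis_ratio_mean >= 1, axis_ratio_sd >= 0,
            hue_mean >= 0, hue_mean < 1, hue_sd >= 0,
            sat_mean > 0, sat_mean <= 1, sat_sd >= 0,
            roughness_amp >= 0, roughness_scale >= 1)
  structure(list(origin = origin, species = origin_species(origin),
                 axis_ratio_mean = axis_ratio_mean, axis_ratio_sd = axis_ratio_sd,
                 hue_mean = hue_mean, hue_sd = hue_sd,
                 sat_mean = sat_mean, sat_sd = sat_sd,
                 roughness_amp = roughness_amp,
                 roughness_scale = as.integer(roughness_scale)),
            class = "class_prototype")
}

#' Default class prototypes
#'
#' Four separable but single-feature-overlapping classes: species A and B
#' differ mainly in saturation, origins within a species additionally in
#' axis ratio and surface roughness, so that no single feature group fully
#' separates all four origins. The values are free parameters of the
#' generator, not estimates of real tubers.
#'
#' @return named list of four `class_prototype` objects.
#' @export
default_prototypes <- function() {
  list(
    SC = class_prototype("SC", axis_ratio_mean = 1.15, axis_ratio_sd = 0.05,
                         hue_mean = 0.10, hue_sd = 0.010,
                         sat_mean = 0.55, sat_sd = 0.03,
                         roughness_amp = 0.10, roughness_scale = 4),
    GX = class_prototype("GX", axis_ratio_mean = 1.45, axis_ratio_sd = 0.05,
                         hue_mean = 0.13, hue_sd = 0.010,
                         sat_mean = 0.65, sat_sd = 0.03,
                         roughness_amp = 0.20, roughness_scale = 4),
    FJ = class_prototype("FJ", axis_ratio_mean = 1.15, axis_ratio_sd = 0.05,
                         hue_mean = 0.08, hue_sd = 0.010,
                         sat_mean = 0.75, sat_sd = 0.03,
                         roughness_amp = 0.30, roughness_scale = 6),
    JX = class_prototype("JX", axis_ratio_mean = 1.70, axis_ratio_sd = 0.05,
                         hue_mean = 0.11, hue_sd = 0.010,
                         sat_mean = 0.85, sat_sd = 0.03,
                         roughness_amp = 0.40, roughness_scale = 6)
  )
}

#' Configuration for a synthetic dataset
#'
#' Validates the segmentability guarantee (every prototype's saturation must
#' clear the background ceiling by three standard deviations) and that the
#' largest blob fits in the frame with at least a 5 px margin.
#'
#' @param prototypes named list with exactly one `class_prototype` per origin.
#' @param n_per_origin images per origin class.
#' @param image_size c(height, width) in pixels.
#' @param background_sat_max saturation ceiling of the background, in [0,1).
#' @param noise_sd sd of additive i.i.d. channel noise on the 0..255 scale.
#' @param perturb_amp upper bound of each low-order radial perturbation
#'   harmonic (relative); 0 renders exact ellipses.
#' @param seed integer seed; the whole dataset is a pure function of it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(prototypes = default_prototypes(),
                             n_per_origin = 100L,
                             image_size = c(128L, 128L),
                             background_sat_max = 0.08,
                             noise_sd = 2,
                             perturb_amp = 0.04,
                             seed = 1L) {
  stopifnot(n_per_origin >= 1, length(image_size) == 2, all(image_size >= 16),
            background_sat_max >= 0, background_sat_max < 1, noise_sd >= 0,
            perturb_amp >= 0, perturb_amp <= 0.05)
  origins <- vapply(prototypes, `[[`, "", "origin")
  if (!setequal(origins, .origin_levels) || anyDuplicated(origins))
    stop("prototypes must contain exactly one entry per origin (SC, GX, FJ, JX)",
         call. = FALSE)
  names(prototypes) <- origins
  for (p in prototypes) {
    floor_sat <- p$sat_mean - 3 * p$sat_sd
    if (floor_sat <= background_sat_max)
      stop(sprintf(
        "prototype %s: saturation floor %.3f does not exceed background ceiling %.3f",
        p$origin, floor_sat, background_sat_max), call. = FALSE)
  }
  # worst-case semi-major axis must fit with a 5 px margin
  max_ratio <- max(vapply(prototypes, function(p)
    p$axis_ratio_mean + 3 * p$axis_ratio_sd, 0))
  r0 <- 0.28 * min(image_size)
  if (r0 * sqrt(max_ratio) * (1 + 3 * perturb_amp) + 3 + 5 > min(image_size) / 2)
    stop("image_size too small for the largest prototype blob (need >= 5 px margin)",
         call. = FALSE)
  structure(list(prototypes = prototypes[.origin_levels],
                 n_per_origin = as.integer(n_per_origin),
                 image_size = as.integer(image_size),
                 background_sat_max = background_sat_max,
                 noise_sd = noise_sd, perturb_amp = perturb_amp,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# truncated-normal draw by rejection (ranges here are wide, so cheap)
rtrunc_norm <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

# smoothed standard-normal random field, unit variance, correlation length
# `scale` pixels (Gaussian kernel sd = scale)
smooth_field <- function(h, w, scale) {
  z <- matrix(stats::rnorm(h * w), h, w)
  f <- EBImage::gblur(z, sigma = scale)
  sdv <- stats::sd(as.vector(f))
  if (sdv == 0) return(matrix(0, h, w))
  f / sdv
}

#' Render one synthetic tuber sample
#'
#' Draws the sample's axis ratio, hue and saturation from the prototype's
#' truncated normal distributions, rasterises a randomly rotated ellipse
#' with a bounded low-order radial perturbation (so the region stays simply
#' connected), fills it with the sampled colour modulated by a smooth random
#' value-channel field, composites it over a low-saturation background and
#' adds channel noise. Consumes the current RNG stream; callers seed it.
#'
#' @param prototype a `class_prototype`.
#' @param config a `synthetic_config`.
#' @param sample_id identifier string stored with the sample.
#' @return list with `image` (H x W x 3, 0..255), `truth_mask` (logical),
#'   `origin`, `species`, `sample_id`.
#' @export
render_sample <- function(prototype, config, sample_id = "s1") {
  h <- config$image_size[1]; w <- config$image_size[2]
  L <- rtrunc_norm(prototype$axis_ratio_mean, prototype$axis_ratio_sd, lower = 1)
  hue <- rtrunc_norm(prototype$hue_mean, prototype$hue_sd) %% 1
  sat <- rtrunc_norm(prototype$sat_mean, prototype$sat_sd,
                     lower = config$background_sat_max + 1e-3, upper = 1)
  val <- stats::runif(1, 0.60, 0.80)

  r0 <- 0.28 * min(h, w)
  a <- r0 * sqrt(L); b <- r0 / sqrt(L)
  phi0 <- stats::runif(1, 0, pi)
  cy <- h / 2 + stats::runif(1, -3, 3)
  cx <- w / 2 + stats::runif(1, -3, 3)
  # low-order radial perturbation, total relative amplitude <= 0.12
  ks <- 2:4
  eps <- stats::runif(3, 0, config$perturb_amp)
  psi <- stats::runif(3, 0, 2 * pi)

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  theta <- atan2(dy, dx)
  # ellipse radius at polar angle, after rotating by phi0
  tr <- theta - phi0
  r_ell <- a * b / sqrt((b * cos(tr))^2 + (a * sin(tr))^2)
  pert <- 1 + eps[1] * cos(ks[1] * theta + psi[1]) +
              eps[2] * cos(ks[2] * theta + psi[2]) +
              eps[3] * cos(ks[3] * theta + psi[3])
  mask <- sqrt(dx^2 + dy^2) <= r_ell * pert

  # background: near-white, saturation below the configured ceiling
  bg_h <- stats::runif(1) %% 1
  bg_s <- stats::runif(1, 0, 0.6 * config$background_sat_max)
  bg_v <- stats::runif(1, 0.92, 0.98)
  hm <- matrix(bg_h, h, w); sm <- matrix(bg_s, h, w); vm <- matrix(bg_v, h, w)

  vfg <- matrix(val, h, w)
  if (prototype$roughness_amp > 0) {
    field <- smooth_field(h, w, prototype$roughness_scale)
    vfg <- pmin(pmax(val * (1 + prototype$roughness_amp * field), 0.05), 1)
  }
  hm[mask] <- hue; sm[mask] <- sat; vm[mask] <- vfg[mask]

  img <- hsv_to_rgb(hm, sm, vm)
  if (config$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, config$noise_sd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
  }
  list(image = img, truth_mask = mask,
       origin = prototype$origin, species = prototype$species,
       sample_id = sample_id)
}

#' Generate a labelled synthetic dataset
#'
#' Produces `4 * n_per_origin` samples, balanced per origin, fully
#' reproducible from `config$seed`. If `dir` is given, images and masks are
#' written as PNG together with a `manifest.csv`
#' (`sample_id,file,origin,species`).
#'
#' @param config a `synthetic_config`.
#' @param dir optional output directory for PNGs and the manifest.
#' @return list with `samples` (list of rendered samples) and `manifest`
#'   (data.frame).
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  samples <- vector("list", 4L * config$n_per_origin)
  rows <- vector("list", length(samples))
  k <- 0L
  for (origin in .origin_levels) {
    proto <- config$prototypes[[origin]]
    for (i in seq_len(config$n_per_origin)) {
      k <- k + 1L
      id <- sprintf("%s_%03d", origin, i)
      samples[[k]] <- render_sample(proto, config, sample_id = id)
      rows[[k]] <- data.frame(sample_id = id,
                              file = paste0(id, ".png"),
                              origin = origin,
                              species = proto$species,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir, call. = FALSE)
    for (s in samples) {
      write_image(s$image, file.path(dir, paste0(s$sample_id, ".png")))
      write_image(s$truth_mask, file.path(dir, paste0(s$sample_id, "_mask.png")))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}
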