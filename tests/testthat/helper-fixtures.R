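# Shared fixtures, built in code and memoised per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# filled digital disc of radius r centred in a (2r+20)^2 frame
disc_mask <- function(r) {
  n <- 2L * r + 20L
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rows - ctr)^2 + (cols - ctr)^2 <= r^2
}

# axis-aligned filled rectangle mask inside a larger frame
rect_mask <- function(h, w, frame = c(h + 20L, w + 20L)) {
  m <- matrix(FALSE, frame[1], frame[2])
  m[11:(10 + h), 11:(10 + w)] <- TRUE
  m
}

# uniform-colour clean image from an RGB triple and a mask
flat_clean <- function(rgb, mask) {
  px <- array(255, c(dim(mask), 3L))
  for (ch in 1:3) {
    channel <- px[, , ch]
    channel[mask] <- rgb[ch]
    px[, , ch] <- channel
  }
  structure(list(pixels = px, mask = mask), class = "clean_image")
}

# small rendered dataset (n per origin), memoised by (n, seed)
small_dataset <- function(n = 2L, seed = 7L) {
  memo(sprintf("ds_%d_%d", n, seed),
       generate_dataset(synthetic_config(n_per_origin = n, seed = seed)))
}

# features of a 12-sample rendered dataset (memoised)
small_feature_table <- function() {
  memo("small_ft", feature_table(small_dataset(n = 3L, seed = 21L)$samples))
}

# feature table of the default 400-image study set (memoised; ~20 s once)
study_features <- function(seed = 11L) {
  memo(sprintf("feat400_%d", seed), {
    ds <- generate_dataset(synthetic_config(seed = seed))
    feature_table(ds$samples)
  })
}

# prototypes collapsed to a single common distribution (all classes alike)
null_prototypes <- function() {
  base <- default_prototypes()$SC
  out <- lapply(c("SC", "GX", "FJ", "JX"), function(o) {
    p <- base
    p$origin <- o
    p$species <- origin_species(o)
    p
  })
  names(out) <- c("SC", "GX", "FJ", "JX")
  out
}

# brute-force GLCM oracle: double loop over every pixel pair at the offset
brute_glcm <- function(gray, valid, d, theta, G, symmetric) {
  off <- switch(as.character(theta),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d))
  counts <- matrix(0, G, G)
  for (r in seq_len(nrow(gray))) for (cc in seq_len(ncol(gray))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(gray) && c2 >= 1 && c2 <= ncol(gray) &&
        valid[r, cc] && valid[r2, c2]) {
      i <- gray[r, cc] + 1L; j <- gray[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  counts / sum(counts)
}

# two well-separated Gaussian clouds; linearly separable 2-class toy table
toy_clouds <- function(n = 40L, seed = 3L, gap = 8) {
  set.seed(seed)
  half <- n %/% 2L
  x1 <- matrix(rnorm(half * 2), half, 2)
  x2 <- matrix(rnorm((n - half) * 2), n - half, 2) + gap
  df <- as.data.frame(rbind(x1, x2))
  # reuse two canonical feature names so fusion selection applies
  names(df) <- c("C", "R")
  df$L <- 0.5 * (df$C + df$R)       # third shape column keeps group S complete
  df$species <- rep(c("A", "B"), c(half, n - half))
  df$origin <- rep(c("SC", "FJ"), c(half, n - half))
  df
}
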