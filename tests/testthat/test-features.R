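test_that("region properties match closed forms on canonical shapes", {
  r <- rect_mask(10, 20)
  pr <- region_props(r)
  expect_equal(pr$A, 200)
  expect_equal(pr$A_R, 200)
  expect_equal(aspect_ratio(pr), 2.0, tolerance = 0.01)
  expect_equal(rectangularity(pr), 1.0)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  pr1 <- region_props(single)
  expect_equal(pr1$A, 1)
  expect_equal(unname(pr1$bbox[c("height", "width")]), c(1, 1))

  d <- disc_mask(50)
  prd <- region_props(d)
  expect_equal(prd$A, pi * 50^2, tolerance = 0.02)
  expect_equal(prd$P, 2 * pi * 50, tolerance = 0.05)
  expect_equal(circularity(prd), 1.0, tolerance = 0.1)
  expect_equal(rectangularity(prd), pi / 4, tolerance = 0.02 / (pi / 4))
  expect_equal(aspect_ratio(prd), 1.0, tolerance = 0.01)

  expect_error(region_props(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 10, 10); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(region_props(two), "single connected component")
})

test_that("circularity of a rectangle matches the continuous formula", {
  # continuous 10 x 20 rectangle: A = 200, P = 60 -> C = 800 pi / 3600
  expect_equal(4 * pi * 200 / 60^2, 0.698, tolerance = 1e-3)
  # L-shape filling 3 of 4 bounding-box quadrants
  L <- matrix(FALSE, 24, 24)
  L[3:22, 3:12] <- TRUE; L[13:22, 13:22] <- TRUE
  expect_equal(rectangularity(region_props(L)), 0.75)
})

test_that("shape features are invariant to translation and 90-degree rotation", {
  d <- disc_mask(12)
  base <- region_props(rect_mask(8, 14))
  shifted <- region_props(rect_mask(8, 14, frame = c(60, 80)))
  expect_equal(circularity(base), circularity(shifted))
  expect_equal(aspect_ratio(base), aspect_ratio(shifted))
  expect_equal(rectangularity(base), rectangularity(shifted))

  m <- rect_mask(8, 14)
  rot <- t(m)[ncol(m):1, ]              # 90-degree rotation
  expect_equal(aspect_ratio(region_props(rot)), aspect_ratio(base))
  expect_equal(rectangularity(region_props(rot)), rectangularity(base))

  # circularity stable across scales within discretisation tolerance
  cs <- vapply(c(25, 50, 100), function(r) circularity(region_props(disc_mask(r))),
               numeric(1))
  expect_true(all(abs(cs - mean(cs)) / mean(cs) < 0.05))
})

test_that("colour means are foreground-only arithmetic means", {
  mask <- matrix(FALSE, 16, 16); mask[5:12, 5:12] <- TRUE
  red <- flat_clean(c(255, 0, 0), mask)
  expect_equal(unname(mean_hs(red)), c(0, 1))

  # half (255,102,102): h = 0, s = 0.6; half (102,255,102): h = 1/3, s = 0.6
  half <- mask & (col(mask) <= 8)
  px <- flat_clean(c(255, 102, 102), mask)$pixels
  for (ch in 1:3) {
    channel <- px[, , ch]
    channel[mask & !half] <- c(102, 255, 102)[ch]
    px[, , ch] <- channel
  }
  clean <- structure(list(pixels = px, mask = mask), class = "clean_image")
  hs <- mean_hs(clean)
  expect_equal(unname(hs["mean_h"]), 1 / 6)
  expect_equal(unname(hs["mean_s"]), 0.6)

  # invariant to the amount of white padding
  pad <- array(255, c(40, 40, 3))
  pad[1:16, 1:16, ] <- px
  mask_pad <- matrix(FALSE, 40, 40); mask_pad[1:16, 1:16] <- mask
  clean_pad <- structure(list(pixels = pad, mask = mask_pad),
                         class = "clean_image")
  expect_equal(mean_hs(clean_pad), hs)
  expect_error(mean_hs(flat_clean(c(1, 2, 3), matrix(FALSE, 16, 16))), "empty")
})

test_that("gray quantisation uses equal-width bins over 0..255", {
  mk <- function(v) flat_clean(c(v, v, v), matrix(TRUE, 16, 16))
  expect_equal(quantize_gray(mk(255), 16)[1, 1], 15L)
  expect_equal(quantize_gray(mk(0), 16)[1, 1], 0L)
  expect_equal(quantize_gray(mk(128), 16)[1, 1], 8L)
})

test_that("GLCM matches hand enumeration and the pair-count oracle", {
  g <- matrix(c(0L, 0L, 1L, 1L), 2, 2)   # [[0,1],[0,1]] as rows
  m <- glcm(g, NULL, d = 1, theta = 0, G = 2, symmetric = FALSE)
  expect_equal(m$p, matrix(c(0, 0, 1, 0), 2, 2))  # p(0,1) = 1

  const <- matrix(3L, 4, 4)
  mc <- glcm(const, NULL, d = 1, theta = 0, G = 8, symmetric = TRUE)
  expect_equal(mc$p[4, 4], 1)

  set.seed(10)
  for (rep in 1:100) {
    h <- sample(4:16, 1); w <- sample(4:16, 1); G <- sample(2:8, 1)
    gray <- matrix(sample(0:(G - 1), h * w, TRUE), h, w)
    valid <- matrix(runif(h * w) > 0.2, h, w)
    d <- sample(1:2, 1); th <- sample(c(0, 45, 90, 135), 1)
    sym <- sample(c(TRUE, FALSE), 1)
    oracle <- try(brute_glcm(gray, valid, d, th, G, sym), silent = TRUE)
    got <- try(glcm(gray, valid, d = d, theta = th, G = G, symmetric = sym),
               silent = TRUE)
    if (inherits(oracle, "try-error") || any(is.na(oracle))) {
      expect_s3_class(got, "try-error")
    } else {
      expect_equal(got$p, oracle)
      expect_equal(sum(got$p), 1, tolerance = 1e-9)
      if (sym) expect_equal(got$p, t(got$p))
    }
  }
})

test_that("Haralick statistics follow their closed forms", {
  const <- matrix(0L, 4, 4)
  st <- glcm_stats(glcm(const, NULL, d = 1, theta = 0, G = 4))
  expect_equal(unname(st), c(1, 0, 0, 0))  # ASM=1, CON=0, COR=0 (degenerate), ENT=0

  g <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  st2 <- glcm_stats(glcm(g, NULL, d = 1, theta = 0, G = 2, symmetric = FALSE))
  expect_equal(unname(st2[c("ASM", "CON", "ENT")]), c(1, 1, 0))

  # uniform GLCM over G^2 = 16 cells
  G <- 4L
  p <- matrix(1 / 16, G, G)
  lev <- 0:3
  m <- structure(list(p = p, mu_x = 1.5, mu_y = 1.5,
                      sd_x = sqrt(sum((lev - 1.5)^2) / 4),
                      sd_y = sqrt(sum((lev - 1.5)^2) / 4),
                      d = 1, theta = 0), class = "glcm")
  stu <- glcm_stats(m)
  expect_equal(unname(stu["ASM"]), 1 / 16)
  expect_equal(unname(stu["ENT"]), 4)
  expect_equal(unname(stu["COR"]), 0)     # independent marginals

  # ENT = 0 iff single nonzero cell, likewise ASM = 1
  expect_true(st2["ENT"] == 0 && st2["ASM"] == 1)
  expect_true(stu["ENT"] > 0 && stu["ASM"] < 1)
})

test_that("texture vector is flat for constant blobs, rough for textured ones", {
  mask <- disc_mask(10)[1:32, 1:32]
  flat <- flat_clean(c(180, 120, 60), mask)
  tx <- texture_features(flat)
  expect_equal(unname(tx[c("ASM_d1", "ASM_d2", "ASM_d4")]), rep(1, 3))
  expect_equal(unname(tx[c("CON_d1", "CON_d2", "CON_d4")]), rep(0, 3))

  # contrast at d=1 increases with roughness amplitude (20 seed pairs)
  proto_lo <- default_prototypes()$SC; proto_lo$roughness_amp <- 0.05
  proto_hi <- default_prototypes()$SC; proto_hi$roughness_amp <- 0.5
  cfg <- synthetic_config(n_per_origin = 1, seed = 1)
  con <- vapply(1:20, function(seed) {
    set.seed(seed); lo <- render_sample(proto_lo, cfg, "lo")
    set.seed(seed); hi <- render_sample(proto_hi, cfg, "hi")
    cl <- function(s) structure(list(pixels = s$image, mask = s$truth_mask),
                                class = "clean_image")
    c(texture_features(cl(lo))["CON_d1"], texture_features(cl(hi))["CON_d1"])
  }, numeric(2))
  expect_gt(mean(con[2, ]), mean(con[1, ]))
  expect_true(all(con[2, ] > con[1, ]))
})

test_that("angle-averaged texture statistics are invariant to 90-degree rotation", {
  ds <- small_dataset(n = 1L, seed = 13L)
  s <- ds$samples[[1]]
  clean <- structure(list(pixels = s$image, mask = s$truth_mask),
                     class = "clean_image")
  rot90 <- function(m) t(m)[ncol(m):1, ]
  px_rot <- array(0, c(dim(s$image)[2], dim(s$image)[1], 3))
  for (ch in 1:3) px_rot[, , ch] <- rot90(s$image[, , ch])
  clean_rot <- structure(list(pixels = px_rot, mask = rot90(s$truth_mask)),
                         class = "clean_image")
  expect_equal(texture_features(clean), texture_features(clean_rot),
               tolerance = 1e-6)
})

test_that("the assembled feature vector has the canonical 17 entries", {
  ds <- small_dataset(n = 1L, seed = 13L)
  clean <- preprocess_image(ds$samples[[1]]$image)
  v1 <- extract_features(clean)
  v2 <- extract_features(clean)
  expect_length(v1, 17L)
  expect_identical(names(v1), feature_names())
  expect_identical(v1, v2)

  ft <- feature_table(ds$samples)
  expect_equal(ncol(ft), 3 + 17)
  expect_equal(nrow(ft), 4)
})
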