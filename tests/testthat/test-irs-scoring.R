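test_that("tissue_mask recovers a dark disk on a white background", {
  sim <- generate_core_image(
    fraction = 0, hematoxylin_amplitude = 0.6,
    noise_sd = 0.05, size = 96, seed = 21
  )
  mask <- tissue_mask(sim$image)
  expected_area <- sum(
    (matrix(1:96, 96, 96) - 48.5)^2 +
      (t(matrix(1:96, 96, 96)) - 48.5)^2 <= (0.42 * 96)^2
  )
  expect_lt(abs(sum(mask) - expected_area) / expected_area, 0.02)
  # tissue excludes the pure-white background
  lum <- luminance_8bit(sim$image)
  expect_true(all(lum[mask] < 255))

  expect_error(tissue_mask(array(255, c(64, 64, 3))), "bimodality")
})

test_that("dab_mask is the thresholded DAB image inside tissue", {
  sim <- generate_core_image(fraction = 0.3, size = 96, seed = 8)
  tissue <- tissue_mask(sim$image)
  conc <- deconvolve(rgb_to_od(sim$image))
  dabg <- concentration_to_gray8(conc, "dab")
  dm <- dab_mask(dabg, tissue)
  expect_true(all(tissue[dm])) # subset of tissue
  frac <- sum(dm) / sum(tissue)
  expect_lt(abs(frac - sim$truth$realized_dab_fraction), 0.03)

  expect_error(dab_mask(matrix(255L, 96, 96), tissue), "degenerate")
})

test_that("area_pct is the DAB share of the tissue area", {
  tissue <- matrix(TRUE, 4, 4)
  expect_equal(area_pct(tissue, tissue), 100)
  expect_equal(area_pct(matrix(FALSE, 4, 4), tissue), 0)
  half <- matrix(rep(c(TRUE, FALSE), 8), 4, 4)
  expect_equal(area_pct(half, tissue), 50)
  expect_error(area_pct(half, matrix(FALSE, 4, 4)), "empty region")
})

test_that("dab_wt_pct equals the per-pixel mean inverted intensity", {
  all_white <- histogram_256(matrix(255L, 4, 4))
  expect_equal(dab_wt_pct(all_white), 0)
  all_black <- histogram_256(matrix(0L, 4, 4))
  expect_equal(dab_wt_pct(all_black), 100)
  half <- histogram_256(matrix(c(0L, 255L), 4, 4))
  expect_equal(dab_wt_pct(half), 50)

  set.seed(17)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    expect_equal(
      dab_wt_pct(histogram_256(img)),
      oracle_dabwt_per_pixel(as.vector(img)),
      tolerance = 1e-9
    )
  }
})

test_that("score_core recovers simulator ground truth and its invariants", {
  sim <- generate_core_image(
    fraction = 0.30, dab_amplitude = 1.0,
    noise_sd = 0.05, size = 96, seed = 33
  )
  sc <- score_core(sim$image, core_id = "truth30")
  expect_lt(abs(sc$area_pct - 30), 3)
  expect_true(sc$area_pct >= 0 && sc$area_pct <= 100)
  expect_true(sc$dabwt_pct >= 0 && sc$dabwt_pct <= 100)
  expect_true(sc$irs >= 0 && sc$irs <= 10000)
  expect_equal(sc$irs, sc$area_pct * sc$dabwt_pct, tolerance = 1e-9)

  # IRS agrees with a brute-force per-pixel computation on the same masks
  tissue <- tissue_mask(sim$image)
  dabg <- concentration_to_gray8(deconvolve(rgb_to_od(sim$image)), "dab")
  dm <- dab_mask(dabg, tissue)
  brute_irs <- (100 * sum(dm) / sum(tissue)) *
    oracle_dabwt_per_pixel(dabg[dm])
  expect_equal(sc$irs, brute_irs, tolerance = 1e-6)
})

test_that("scoring is invariant to a 90-degree rotation of the core", {
  sim <- generate_core_image(fraction = 0.2, size = 96, seed = 55)
  rot <- array(0L, dim = dim(sim$image))
  for (ch in 1:3) rot[, , ch] <- t(sim$image[96:1, , ch])
  a <- score_core(sim$image, "orig")
  b <- score_core(rot, "rot")
  expect_equal(a$area_pct, b$area_pct)
  expect_equal(a$dabwt_pct, b$dabwt_pct)
  expect_equal(a$irs, b$irs)
})

test_that("a core with no DAB scores a biological zero", {
  sim <- generate_core_image(fraction = 0, size = 96, seed = 3, noise_sd = 0)
  sc <- score_core(sim$image, "blank")
  expect_equal(sc$area_pct, 0)
  expect_equal(sc$dabwt_pct, 0)
  expect_equal(sc$irs, 0)
})

test_that("mean scored area and intensity are monotone in the truth", {
  # averaged over seeds: area_pct non-decreasing in the true fraction
  fractions <- c(0.1, 0.3, 0.5)
  mean_area <- sapply(fractions, function(f) {
    mean(sapply(1:8, function(s) {
      sim <- generate_core_image(f, size = 96, seed = 400 + 17 * s)
      score_core(sim$image)$area_pct
    }))
  })
  expect_true(all(diff(mean_area) > 0))

  # dabwt_pct non-decreasing in the DAB amplitude at fixed fraction
  amps <- c(0.5, 1.0, 1.5)
  mean_wt <- sapply(amps, function(a) {
    mean(sapply(1:8, function(s) {
      sim <- generate_core_image(0.3,
        dab_amplitude = a, size = 96,
        seed = 700 + 13 * s
      )
      score_core(sim$image)$dabwt_pct
    }))
  })
  expect_true(all(diff(mean_wt) > 0))
})

test_that("score_batch records per-core failures without aborting", {
  dir <- withr::local_tempdir()
  ids <- c("a1", "a2")
  for (i in 1:2) {
    sim <- generate_core_image(0.2, size = 96, seed = 60 + i)
    write_rgb_image(sim$image, file.path(dir, paste0(ids[i], ".png")))
  }
  meta <- data.frame(
    core_id = c(ids, "ghost"),
    file = c("a1.png", "a2.png", "missing.png"),
    marker = "INHBB", gleason_group = c("3", "4", "4"),
    stringsAsFactors = FALSE
  )
  scores <- score_batch(meta, dir)
  expect_equal(nrow(scores), 3)
  expect_equal(sum(scores$status == "ok"), 2)
  expect_match(scores$status[scores$core_id == "ghost"], "failed")

  # empty batch and rerun determinism
  expect_equal(nrow(score_batch(meta[0, ], dir)), 0)
  expect_identical(scores, score_batch(meta, dir))

  expect_error(score_batch(meta[, -2], dir), "missing required column")
})
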