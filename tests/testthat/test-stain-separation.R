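test_that("rgb_to_od evaluates the Beer-Lambert formula with the dark clamp", {
  white <- rgb_to_od(array(255, c(1, 1, 3)))
  expect_equal(as.vector(white), c(0, 0, 0))

  mid <- rgb_to_od(array(128, c(1, 1, 3)))
  expect_equal(as.vector(mid), rep(log10(255 / 128), 3), tolerance = 1e-12)

  black <- rgb_to_od(array(0, c(1, 1, 3)))
  expect_equal(as.vector(black), rep(log10(255), 3), tolerance = 1e-12)

  expect_error(rgb_to_od(array(1, c(1, 1, 3)), i0 = 0), "i0")
  expect_error(rgb_to_od(array(300, c(1, 1, 3))), "\\[0, 255\\]")
})

test_that("od_to_rgb inverts rgb_to_od within one gray level", {
  expect_identical(
    as.vector(od_to_rgb(array(0, c(1, 1, 3)))),
    c(255L, 255L, 255L)
  )
  expect_identical(
    as.vector(od_to_rgb(array(log10(255 / 128), c(1, 1, 3)))),
    c(128L, 128L, 128L)
  )
  expect_error(od_to_rgb(array(-0.1, c(1, 1, 3))), "non-negative")

  set.seed(41)
  img <- random_rgb_image()
  back <- od_to_rgb(rgb_to_od(img))
  expect_true(max(abs(back - pmax(img, 1))) <= 1)
})

test_that("H-DAB stain matrix has unit rows and a clean inverse", {
  m <- hdab_stain_matrix()
  expect_equal(sqrt(rowSums(m^2)), c(
    hematoxylin = 1, dab = 1,
    residual = 1
  ), tolerance = 1e-9)
  expect_equal(m %*% solve(m), diag(3),
    ignore_attr = TRUE,
    tolerance = 1e-9
  )

  # a pure-hematoxylin pixel carries no DAB signal after separation
  od <- matrix(0.8 * m["hematoxylin", ], nrow = 1)
  conc <- deconvolve(od, m)
  expect_equal(conc[1, "dab"], c(dab = 0), tolerance = 1e-6)
  expect_equal(conc[1, "hematoxylin"], c(hematoxylin = 0.8),
    tolerance = 1e-6
  )
})

test_that("deconvolve is the exact linear inverse of stain mixing", {
  m <- hdab_stain_matrix()
  expect_equal(
    as.vector(deconvolve(matrix(0, 4, 3), m)),
    rep(0, 12)
  )
  od_dab <- matrix(1.3 * m["dab", ], nrow = 1)
  expect_equal(as.vector(deconvolve(od_dab, m)), c(0, 1.3, 0),
    tolerance = 1e-9
  )

  # linearity and unquantized round trip on random concentration fields
  set.seed(13)
  conc <- matrix(runif(300, 0, 2), ncol = 3)
  od <- conc %*% m
  expect_equal(as.vector(deconvolve(od, m)), as.vector(conc),
    tolerance = 1e-6
  )
  od2 <- matrix(runif(300, 0, 1), ncol = 3)
  lhs <- deconvolve(2 * od + 0.5 * od2, m)
  rhs <- 2 * deconvolve(od, m) + 0.5 * deconvolve(od2, m)
  expect_equal(as.vector(lhs), as.vector(rhs), tolerance = 1e-9)

  expect_error(deconvolve(od, matrix(1, 3, 3)), "unit")
})

test_that("quantized round trip stays within the 8-bit error budget", {
  # generator-like mixed field: hematoxylin everywhere, DAB on part of it
  set.seed(5)
  m <- hdab_stain_matrix()
  ch <- runif(500, 0, 0.8)
  cd <- ifelse(runif(500) < 0.5, runif(500, 0, 1.2), 0)
  conc <- cbind(ch, cd, 0)
  img <- od_to_rgb(conc %*% m)
  rec <- deconvolve(rgb_to_od(img), m)
  expect_lt(max(abs(rec[, 1:2] - conc[, 1:2])), 0.02)
})

test_that("concentration_to_gray8 maps amounts to inverted intensity", {
  conc <- array(0, c(1, 4, 3),
    dimnames = list(NULL, NULL, c("hematoxylin", "dab", "residual"))
  )
  conc[1, , 2] <- c(0, 1, 3.5, -0.4)
  g <- concentration_to_gray8(conc, "dab")
  expect_identical(as.vector(g), c(255L, 26L, 0L, 255L))
  expect_error(concentration_to_gray8(conc, "eosin"), "unknown stain")

  # monotone non-increasing in the amount
  cc <- seq(0, 3, length.out = 64)
  conc2 <- array(0, c(1, 64, 3),
    dimnames = list(NULL, NULL, c("hematoxylin", "dab", "residual"))
  )
  conc2[1, , 2] <- cc
  g2 <- as.vector(concentration_to_gray8(conc2, "dab"))
  expect_true(all(diff(g2) <= 0))
})
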