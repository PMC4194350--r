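# Per-deposit graphical variables: perimeter, circularity, ROD flag,
# colour models, IOD, deposit assembly.

test_that("contour perimeter follows the chain-code convention", {
  sq <- labelComponents(matrix(1L, 10, 10))[[1]]
  expect_equal(tracePerimeter(sq), 36)      # 4 * (10 - 1)
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_equal(tracePerimeter(labelComponents(one)[[1]]), 0)
  two <- matrix(0L, 6, 6); two[3, 3] <- 1L; two[4, 4] <- 1L
  expect_equal(tracePerimeter(labelComponents(two)[[1]]), 0)  # < 3 border pts
  ln <- matrix(0L, 10, 5); ln[3:8, 3] <- 1L                   # 1x6 line
  expect_equal(tracePerimeter(labelComponents(ln)[[1]]), 10)  # out and back
  lshape <- matrix(0L, 6, 6); lshape[2, 2:3] <- 1L; lshape[3, 3] <- 1L
  expect_equal(tracePerimeter(labelComponents(lshape)[[1]]),
               2 + sqrt(2))  # right triangle of pixel centres
  expect_error(tracePerimeter(list(pixels = NULL)), "empty")
})

test_that("disc perimeter is close to the analytic circumference", {
  cc <- labelComponents(discMask(20))[[1]]
  p <- tracePerimeter(cc)
  expect_lt(abs(p - 2 * pi * 20) / (2 * pi * 20), 0.05)
})

test_that("circularity formula, clamp and degenerate conventions", {
  r <- 13.7
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)       # ideal circle
  s <- 9.2
  expect_equal(circularity(s^2, 4 * s), pi / 4)            # ideal square
  expect_equal(circularity(9, 8), 1)                       # 3x3 px: clamped
  expect_equal(circularity(10, 0), 1)                      # degenerate
  expect_error(circularity(0, 10), "positive")
})

test_that("rasterised circularity separates shapes as expected", {
  # discs plateau high (though below 1: chain-code perimeter bias), squares
  # approach pi/4 from above, elongation decreases circularity monotonically
  discC <- vapply(c(10, 20, 40), function(r)
    circularity(sum(discMask(r)), tracePerimeter(labelComponents(discMask(r))[[1]])),
    1.0)
  expect_true(all(discC > 0.85))
  sqC <- vapply(c(10, 30, 90), function(n) {
    cc <- labelComponents(matrix(1L, n, n))[[1]]
    circularity(n^2, tracePerimeter(cc))
  }, 1.0)
  expect_true(all(diff(sqC) < 0))
  expect_true(all(sqC > pi / 4))
  expect_lt(sqC[3], pi / 4 + 0.02)
  rectC <- vapply(c(1, 2, 4, 8), function(ar) {
    m <- matrix(1L, 12 * ar, 12)
    circularity(sum(m), tracePerimeter(labelComponents(m)[[1]]))
  }, 1.0)
  expect_true(all(diff(rectC) < 0))
})

test_that("ROD classification is a strict-cutoff rule on circularity", {
  expect_false(classifyRod(0.9, 0.5))
  expect_true(classifyRod(0.2, 0.5))
  expect_false(classifyRod(0.5, 0.5))   # tie -> non-ROD
  expect_error(classifyRod(1.2, 0.5), "\\[0,1\\]")
})

test_that("mean RGB is the channel-wise mean over the pixel set", {
  m <- matrix(0L, 6, 6); m[2:3, 2:3] <- 1L
  cc <- labelComponents(m)[[1]]
  img <- array(0, dim = c(6, 6, 3)); img[, , 1] <- 1  # pure red
  expect_equal(unname(meanRgb(cc, img)), c(1, 0, 0))
  img2 <- array(0.9, dim = c(6, 6, 3))
  img2[2, 2, ] <- 0; img2[3, 3, ] <- 0  # 2 black px of 4
  img2[2, 3, ] <- 1; img2[3, 2, ] <- 1  # 2 white px
  expect_equal(unname(meanRgb(cc, img2)), c(0.5, 0.5, 0.5))
})

test_that("RGB<->HSL agrees with the named-colour reference and round-trips", {
  got <- rgbToHsl(hslProbe$r, hslProbe$g, hslProbe$b)
  expect_true(all(abs(got[, "h"] - hslProbe$h) <= 1))
  expect_equal(got[, "s"], hslProbe$s, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(got[, "l"], hslProbe$l, tolerance = 1e-6, ignore_attr = TRUE)
  # round trip on random chromatic colours
  set.seed(11)
  h <- runif(40, 0, 360); s <- runif(40, 0.05, 1); l <- runif(40, 0.05, 0.95)
  rgb <- hslToRgb(h, s, l)
  back <- rgbToHsl(rgb[, "r"], rgb[, "g"], rgb[, "b"])
  expect_equal(back[, "h"], h, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back[, "s"], s, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back[, "l"], l, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(rgbToHsl(1.2, 0, 0), "\\[0,1\\]")
})

test_that("IOD is linear in area and decreasing in lightness", {
  expect_equal(iod(100, 1), 0)
  expect_equal(iod(100, 0), 100)
  expect_equal(iod(200, 0.4), 120)
  expect_equal(iod(2 * 350, 0.3), 2 * iod(350, 0.3))
  ls <- seq(0, 1, by = 0.1)
  expect_true(all(diff(iod(100, ls)) < 0))
  expect_error(iod(-1, 0.5), ">= 0")
})

test_that("deposit assembly populates every variable consistently", {
  m <- discMask(6, pad = 4L)
  cc <- labelComponents(m)[[1]]
  img <- array(0.5, dim = c(dim(m), 3))   # uniform mid-grey disc
  d <- buildDeposit(cc, img, "p1", 1L)
  expect_equal(d$mean_s, 0)
  expect_equal(d$mean_h, 0L)
  expect_equal(d$iod, d$area * 0.5)
  expect_equal(d$area, nrow(cc$pixels))
  expect_true(d$include)
  # elongated capsule classifies as ROD
  cap <- matrix(0L, 60, 14); cap[3:57, 5:9] <- 1L
  ccc <- labelComponents(cap)[[1]]
  dc <- buildDeposit(ccc, array(0.3, dim = c(60, 14, 3)), "p1", 2L)
  expect_true(dc$is_rod)
  expect_lt(dc$circularity, 0.5)
})

test_that("deposit invariants hold on synthetic plate output", {
  pl <- generatePlate(testSpec(seed = 9))
  pa <- analyzePlate(pl$image, detectionParams(), "inv", nFlies = 6)
  d <- deposits(pa)
  expect_gt(nrow(d), 0)
  expect_true(all(d$circularity >= 0 & d$circularity <= 1))
  expect_true(all(d$mean_h >= 0L & d$mean_h <= 359L))
  expect_equal(d$iod, d$area * (1 - d$mean_l))
  expect_equal(d$area, vapply(pixelSets(pa), nrow, 1L))
  expect_equal(d$deposit_id, seq_len(nrow(d)))
  # centroids inside bounding boxes
  for (i in seq_len(nrow(d))) {
    px <- pixelSets(pa)[[i]]
    expect_true(d$x[i] >= min(px[, 1]) && d$x[i] <= max(px[, 1]))
  }
})
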