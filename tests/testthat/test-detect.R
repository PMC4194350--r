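# Segmentation pipeline: greyscale, adaptive threshold, labelling,
# hole filling, size filtering, composition.

test_that("greyscale conversion is the weighted channel sum", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(toGreyscale(px(1, 1, 1))[1, 1], 1)
  expect_equal(toGreyscale(px(0, 0, 0))[1, 1], 0)
  expect_equal(toGreyscale(px(1, 0, 0))[1, 1], 0.299)
  expect_equal(toGreyscale(px(0.2, 0.4, 0.6), c(1, 0, 0))[1, 1], 0.2)
  expect_error(toGreyscale(px(1, 1, 1), c(0.5, 0.4, 0.2)), "sum")
})

test_that("uniform images and oversized offsets produce no foreground", {
  g <- matrix(0.7, 30, 30)
  expect_equal(sum(adaptiveThreshold(g, 15, 0.05)), 0)
  gg <- matrix(runif(900), 30, 30)
  expect_equal(sum(adaptiveThreshold(gg, 15, 1.0)), 0)
  expect_error(adaptiveThreshold(g, 31, -0.1), "offset")
  expect_error(adaptiveThreshold(g, 16, 0.1), "odd")
  expect_error(adaptiveThreshold(g, 51, 0.1), "larger")
})

test_that("adaptive threshold matches the brute-force sliding-window rule", {
  set.seed(41)
  # dark disc on light background
  g1 <- ifelse(discMask(5, pad = 11) == 1L, 0.2, 0.9)
  # smooth gradient background with two dark squares
  g2 <- outer(seq(0.7, 0.95, length.out = 40), seq(0, 0.05, length.out = 40), `+`)
  g2[5:9, 5:9] <- 0.3; g2[25:30, 28:33] <- 0.25
  # pure noise
  g3 <- matrix(runif(48 * 64), 48, 64)
  cases <- list(list(g1, 31L, 0.1), list(g2, 15L, 0.06),
                list(g3, 9L, 0.02), list(g3, 63L, 0.2))
  for (cs in cases) {
    expect_identical(adaptiveThreshold(cs[[1]], cs[[2]], cs[[3]]),
                     bruteLocalMeanThreshold(cs[[1]], cs[[2]], cs[[3]]))
  }
})

test_that("labelling follows 8-connectivity and raster order", {
  m <- matrix(0L, 10, 10)
  m[2:3, 2:3] <- 1L     # square at top-left
  m[7:8, 7:8] <- 1L     # square lower-right
  cc <- labelComponents(m)
  expect_length(cc, 2)
  expect_equal(cc[[1]]$bbox, c(1, 1, 2, 2))  # first in raster order
  one <- matrix(0L, 4, 4); one[2, 2] <- 1L
  cc1 <- labelComponents(one)
  expect_length(cc1, 1)
  expect_equal(nrow(cc1[[1]]$pixels), 1)
  diag2 <- matrix(0L, 5, 5); diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_length(labelComponents(diag2), 1)          # diagonal touch merges
  expect_length(labelComponents(diag2, connectivity = 4L), 2)
  expect_length(labelComponents(matrix(0L, 5, 5)), 0)
})

test_that("labelling agrees with a union-find oracle on random masks", {
  set.seed(42)
  for (trial in 1:8) {
    m <- randomMask(25, 25, pFg = runif(1, 0.2, 0.6))
    cc <- labelComponents(m)
    oracle <- unionFindLabel(m)
    lab <- matrix(0L, nrow(m), ncol(m))
    for (comp in cc) lab[comp$pixels + 1L] <- comp$label
    expect_identical(lab, oracle)
    # partition property: components cover exactly the foreground
    expect_equal(sum(vapply(cc, function(x) nrow(x$pixels), 1L)), sum(m))
  }
})

test_that("hole filling closes enclosed cavities only, idempotently", {
  ring <- matrix(0L, 11, 11)
  ring[3:9, 3] <- 1L; ring[3:9, 9] <- 1L; ring[3, 3:9] <- 1L; ring[9, 3:9] <- 1L
  cc <- labelComponents(ring)[[1]]
  filled <- fillHoles(cc)
  expect_equal(nrow(filled$pixels), 49)  # 7x7 solid block
  expect_equal(nrow(fillHoles(filled)$pixels), 49)  # idempotent
  # C-shape: cavity open to the border stays open
  cshape <- matrix(0L, 11, 11)
  cshape[3:9, 3] <- 1L; cshape[3, 3:9] <- 1L; cshape[9, 3:9] <- 1L
  cc2 <- labelComponents(cshape)[[1]]
  expect_equal(nrow(fillHoles(cc2)$pixels), nrow(cc2$pixels))
  # solid disc unchanged
  cc3 <- labelComponents(discMask(6))[[1]]
  expect_equal(fillHoles(cc3)$pixels, cc3$pixels)
})

test_that("hole filling agrees with a flood-fill-from-border oracle", {
  set.seed(7)
  for (trial in 1:6) {
    m <- randomMask(18, 18, 0.55)
    for (cc in labelComponents(m)) {
      got <- fillHoles(cc)$pixels
      want <- floodFillHoles(cc$pixels, cc$bbox)
      expect_equal(got[order(got[, 2], got[, 1]), , drop = FALSE],
                   want[order(want[, 2], want[, 1]), , drop = FALSE],
                   ignore_attr = TRUE)
      # never removes pixels
      expect_true(nrow(got) >= nrow(cc$pixels))
    }
  }
})

test_that("size filter keeps inclusive bounds and preserves order", {
  mk <- function(n) list(label = n, pixels = cbind(x = seq_len(n), y = rep(0L, n)),
                         bbox = c(1, 0, n, 0))
  comps <- list(mk(2), mk(50), mk(10000))
  kept <- filterBySize(comps, 5, 5000)
  expect_length(kept, 1)
  expect_equal(nrow(kept[[1]]$pixels), 50)
  expect_length(filterBySize(comps, 0, Inf), 3)        # identity
  expect_length(filterBySize(list(mk(5)), 5, 10), 1)   # boundary inclusive
  expect_length(filterBySize(list(mk(10)), 5, 10), 1)
  expect_error(filterBySize(comps, 10, 10), "minArea")
})

test_that("detection composes the stages and finds separated spots", {
  blank <- array(0.85, dim = c(120, 120, 3))
  expect_length(detectSpots(blank, detectionParams(window = 31L)), 0)
  pl <- generatePlate(testSpec(seed = 2))
  cc <- detectSpots(pl$image, detectionParams())
  expect_length(cc, nrow(pl$truth))
})

test_that("detection is invariant to a global intensity offset", {
  pl <- generatePlate(testSpec(seed = 3))
  a <- EBImage::imageData(pl$image)
  stopifnot(max(a) + 0.05 <= 1)  # no clipping, shift is exactly global
  shifted <- a + 0.05
  p <- detectionParams()
  ccA <- detectSpots(a, p)
  ccB <- detectSpots(shifted, p)
  expect_equal(length(ccA), length(ccB))
  for (i in seq_along(ccA)) expect_equal(ccA[[i]]$pixels, ccB[[i]]$pixels)
})

test_that("dpi rescaling of default size bounds warns and scales", {
  expect_warning(p <- detectionParams(dpi = 600), "rescaled")
  expect_equal(p@minArea, 40 / 4)
  expect_equal(p@maxArea, 50000 / 4)
  expect_silent(p2 <- detectionParams(dpi = 600, minArea = 40, maxArea = 50000))
  expect_equal(p2@minArea, 40)
})
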