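# Deposit segmentation: greyscale -> adaptive threshold -> 8-connected
# labelling -> hole filling -> size filter. Images follow the EBImage
# convention: arrays indexed [x, y(, channel)], x rightward and y downward
# from the top left; exported pixel coordinates are 0-based.

# Coerce an EBImage Image or plain array to a width x height x 3 array in
# [0,1]. Greyscale inputs are promoted, alpha channels dropped.
asRgbArray <- function(image) {
  a <- if (is(image, "Image")) EBImage::imageData(image) else image
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (length(dim(a)) != 3L)
    stop("image must be a matrix or a width x height x channel array")
  if (dim(a)[3] == 1L) a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] != 3L) stop("image must have 1, 3 or 4 channels")
  if (min(a) < 0 || max(a) > 1)
    stop("channel values must lie in [0,1]")
  a
}

#' Convert an RGB plate image to greyscale
#'
#' Weighted channel sum, by default the standard luma weights
#' (0.299, 0.587, 0.114).
#'
#' @param image an [EBImage::Image] in colour mode, or a width x height x 3
#'   array with channel values in \[0,1\].
#' @param weights three non-negative weights summing to 1.
#' @return A width x height numeric matrix of intensities in \[0,1\].
#' @examples
#' img <- array(c(1, 0, 0), dim = c(1, 1, 3))  # pure red pixel
#' toGreyscale(img)  # 0.299
#' @export
toGreyscale <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (length(weights) != 3L || any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be 3 non-negative values summing to 1")
  a <- asRgbArray(image)
  g <- weights[1] * a[, , 1L] + weights[2] * a[, , 2L] + weights[3] * a[, , 3L]
  matrix(g, dim(a)[1L], dim(a)[2L])  # keep matrix shape for 1-px extents
}

# Index vector implementing (tiled) symmetric reflection padding of an axis
# of length n by p on each side.
reflectIndex <- function(n, p) {
  if (n == 1L) return(rep(1L, 1L + 2L * p))
  base <- c(seq_len(n), rev(seq_len(n)))
  pos <- (1L - p):(n + p)
  base[((pos - 1L) %% (2L * n)) + 1L]
}

#' Adaptive (local-mean) thresholding
#'
#' Binarises a greyscale plate image against the arithmetic mean of a
#' square window centred on each pixel: a pixel is foreground (1) iff its
#' intensity is strictly below the local mean minus `offset`. The local
#' statistic compensates for smooth background gradients that defeat a
#' global threshold; image borders are handled by reflected padding, so a
#' uniform image never produces foreground. The local mean is computed
#' exactly via a summed-area table.
#'
#' @param grey numeric intensity matrix in \[0,1\] (see [toGreyscale()]).
#' @param window odd window side >= 3, in pixels.
#' @param offset non-negative intensity offset.
#' @return An integer 0/1 matrix with the dimensions of `grey`.
#' @examples
#' g <- matrix(0.9, 40, 40); g[18:22, 18:22] <- 0.2
#' sum(adaptiveThreshold(g, window = 15, offset = 0.1))  # the dark square
#' @export
adaptiveThreshold <- function(grey, window = 51L, offset = 0.06) {
  if (!is.matrix(grey)) stop("grey must be a matrix")
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  if (offset < 0) stop("offset must be >= 0")
  nx <- nrow(grey); ny <- ncol(grey)
  if (window > nx && window > ny)
    stop("window (", window, ") larger than both image dimensions")
  p <- (window - 1L) %/% 2L
  gp <- grey[reflectIndex(nx, p), reflectIndex(ny, p), drop = FALSE]
  # summed-area table with a leading zero row/column
  S <- matrix(0, nrow(gp) + 1L, ncol(gp) + 1L)
  S[-1L, -1L] <- apply(apply(gp, 2L, cumsum), 1L, cumsum) |> t()
  i <- seq_len(nx); j <- seq_len(ny)
  localSum <- S[i + window, j + window, drop = FALSE] -
    S[i, j + window, drop = FALSE] - S[i + window, j, drop = FALSE] +
    S[i, j, drop = FALSE]
  mask <- (grey < localSum / (window * window) - offset)
  storage.mode(mask) <- "integer"
  mask
}

#' Label connected foreground regions
#'
#' Confluent regions of foreground pixels become candidate deposits.
#' Under the default 8-connectivity, pixels touching only diagonally belong
#' to the same component. Labels run 1..n in raster order (top-left origin,
#' rows first) of each component's first pixel.
#'
#' @param map integer 0/1 matrix from [adaptiveThreshold()].
#' @param connectivity 8 (default) or 4.
#' @return A list of components; each is a list with `label`, `pixels` (a
#'   2-column integer matrix of 0-based x, y in raster order) and `bbox`
#'   (`c(xmin, ymin, xmax, ymax)`, 0-based inclusive).
#' @examples
#' m <- matrix(0L, 8, 8); m[2, 2] <- 1L; m[3, 3] <- 1L; m[7, 7] <- 1L
#' length(labelComponents(m))  # 2: the diagonal pair merges
#' @export
labelComponents <- function(map, connectivity = 8L) {
  if (!is.matrix(map)) stop("map must be a matrix")
  if (!all(map %in% c(0L, 1L))) stop("map must be binary (0/1)")
  storage.mode(map) <- "integer"
  lab <- .cc_label(map, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) return(list())
  fg <- which(lab > 0L)                       # column-major = raster order
  xy <- arrayInd(fg, dim(lab))
  labs <- lab[fg]
  ord <- order(labs)                          # stable: keeps raster order
  xy <- xy[ord, , drop = FALSE]
  labs <- labs[ord]
  idx <- split(seq_len(nrow(xy)), labs)
  lapply(seq_len(n), function(k) {
    px <- xy[idx[[k]], , drop = FALSE] - 1L   # 0-based
    colnames(px) <- c("x", "y")
    list(label = k,
         pixels = px,
         bbox = c(min(px[, 1L]), min(px[, 2L]), max(px[, 1L]), max(px[, 2L])))
  })
}

#' Fill enclosed holes of a component
#'
#' Background regions completely enclosed by the component (not reachable
#' from the image border through background) are added to its pixel set.
#' Idempotent; never removes pixels. Cavities open to the outside (e.g. a
#' C-shape) are left untouched.
#'
#' @param component a component from [labelComponents()].
#' @param dim image dimensions `c(width, height)` (used only for validation;
#'   holes are determined within the component's padded bounding box).
#' @return The component with an updated (raster-ordered) pixel set.
#' @export
fillHoles <- function(component, dim = NULL) {
  px <- component$pixels
  if (is.null(px) || nrow(px) == 0L) return(component)
  bb <- component$bbox
  w <- bb[3L] - bb[1L] + 3L; h <- bb[4L] - bb[2L] + 3L
  m <- matrix(0L, w, h)
  m[cbind(px[, 1L] - bb[1L] + 2L, px[, 2L] - bb[2L] + 2L)] <- 1L
  f <- EBImage::fillHull(m)
  filled <- which(f != 0)
  xy <- arrayInd(filled, c(w, h))
  out <- cbind(x = xy[, 1L] + bb[1L] - 2L, y = xy[, 2L] + bb[2L] - 2L)
  component$pixels <- out
  component
}

#' Filter components by area
#'
#' Keeps components whose pixel count lies in `[minArea, maxArea]`
#' (inclusive bounds); order is preserved. Filters out sub-deposit specks
#' (dust, dirt) and oversized artefacts such as moulding shadows.
#'
#' @param components list from [labelComponents()].
#' @param minArea,maxArea inclusive pixel-count bounds, `minArea < maxArea`.
#' @return The filtered component list.
#' @export
filterBySize <- function(components, minArea = 40, maxArea = 50000) {
  if (!(minArea < maxArea)) stop("need minArea < maxArea")
  keep <- vapply(components, function(cc) {
    a <- nrow(cc$pixels)
    a >= minArea && a <= maxArea
  }, logical(1))
  components[keep]
}

#' Detect candidate deposits in a plate scan
#'
#' Full segmentation pipeline: greyscale conversion, adaptive local-mean
#' thresholding, optional morphological opening (disc radius 1, to shave
#' pixel bridges between confluent spots), 8-connected labelling, per-object
#' hole filling and inclusive size filtering. Deterministic for fixed
#' inputs, and invariant to a global intensity offset (the threshold is
#' relative to the local mean).
#'
#' @param image RGB plate image ([EBImage::Image] or array, values in
#'   \[0,1\]).
#' @param params a [DetectionParams-class] object.
#' @return A list of components (see [labelComponents()]).
#' @examples
#' plate <- generatePlate(synthSpec(nRound = 4, nOblong = 2,
#'                                  width = 300, height = 300, seed = 11))
#' length(detectSpots(plate$image, detectionParams()))
#' @export
detectSpots <- function(image, params = detectionParams()) {
  validObject(params)
  grey <- toGreyscale(image, params@weights)
  mask <- adaptiveThreshold(grey, params@window, params@offset)
  if (params@opening) {
    mask <- EBImage::opening(mask, EBImage::makeBrush(3L, shape = "disc"))
    storage.mode(mask) <- "integer"
  }
  comps <- labelComponents(mask, params@connectivity)
  comps <- lapply(comps, fillHoles, dim = dim(grey))
  filterBySize(comps, params@minArea, params@maxArea)
}
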