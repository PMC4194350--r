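# Per-deposit graphical variables: position, area, contour perimeter,
# circularity, ROD flag, IOD and mean colour (RGB + HSL).

#' Contour perimeter of a component
#'
#' Traces the outer 8-connected border of the pixel region through pixel
#' centres (Moore-neighbour border following) and returns the length of the
#' closed polygon: 1 per axial step, sqrt(2) per diagonal step — the
#' classical chain-code arc length of the contour. Components visited by
#' fewer than 3 distinct border points return 0 by the degenerate-contour
#' convention (such specks are normally removed by the size filter).
#'
#' @param component a component from [labelComponents()].
#' @return Perimeter in pixels.
#' @examples
#' sq <- matrix(1L, 10, 10)
#' tracePerimeter(labelComponents(sq)[[1]])  # 36 = 4 * (10 - 1)
#' @export
tracePerimeter <- function(component) {
  px <- component$pixels
  if (is.null(px) || nrow(px) == 0L) stop("empty component")
  if (nrow(px) < 3L) return(0)
  bb <- component$bbox
  w <- bb[3L] - bb[1L] + 3L; h <- bb[4L] - bb[2L] + 3L
  m <- matrix(0L, w, h)
  m[cbind(px[, 1L] - bb[1L] + 2L, px[, 2L] - bb[2L] + 2L)] <- 1L
  .trace_boundary(m)
}

#' Circularity shape descriptor
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle, approaching 0 for
#' elongated shapes. Discretised contours can push the raw value above 1
#' (e.g. a 3x3 pixel square), so the result is clamped to the declared
#' \[0,1\] range; a degenerate zero perimeter yields 1 by the compactness
#' convention.
#'
#' @param area object area in pixels, > 0.
#' @param perimeter contour perimeter in pixels (see [tracePerimeter()]).
#' @return Circularity in \[0,1\] (vectorised over inputs).
#' @examples
#' r <- 7
#' circularity(pi * r^2, 2 * pi * r)  # ideal circle: exactly 1
#' circularity(4^2, 4 * 4)            # ideal square: pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0)) stop("area must be positive")
  if (any(perimeter < 0)) stop("perimeter must be >= 0")
  out <- ifelse(perimeter == 0, 1, pmin(1, 4 * pi * area / perimeter^2))
  as.numeric(out)
}

#' Classify a deposit as ROD or non-ROD
#'
#' Reproductive oblong deposits (RODs) — the long, concentrated deposits
#' typical of mated females — are the low-circularity class: a deposit is a
#' ROD iff its circularity lies strictly below the cutoff (a value exactly
#' at the cutoff is non-ROD). The pooled circularity distribution is
#' typically bimodal, so any cutoff in the valley separates the classes;
#' the default 0.5 is user-overridable.
#'
#' @param circularity circularity value(s) in \[0,1\].
#' @param cutoff circularity cutoff in \[0,1\] (default 0.5).
#' @return Logical: `TRUE` for ROD.
#' @export
classifyRod <- function(circularity, cutoff = 0.5) {
  if (any(circularity < 0 | circularity > 1) || cutoff < 0 || cutoff > 1)
    stop("circularity and cutoff must lie in [0,1]")
  circularity < cutoff
}

#' Mean RGB colour of a component
#'
#' @param component a component from [labelComponents()].
#' @param image the source RGB image.
#' @return Named vector `c(r, g, b)` of channel means in \[0,1\].
#' @export
meanRgb <- function(component, image) {
  px <- component$pixels
  if (is.null(px) || nrow(px) == 0L) stop("empty component")
  a <- asRgbArray(image)
  i <- px[, 1L] + 1L; j <- px[, 2L] + 1L
  c(r = mean(a[cbind(i, j, 1L)]),
    g = mean(a[cbind(i, j, 2L)]),
    b = mean(a[cbind(i, j, 3L)]))
}

#' RGB to HSL conversion
#'
#' Standard hexagonal hue-saturation-Lightness transform:
#' `L = (max + min) / 2`, `S = (max - min) / (1 - |2L - 1|)` for chromatic
#' colours (0 otherwise), and the piecewise hue formula wrapped to
#' \[0, 360) degrees. Achromatic colours get H = 0 by convention. With a
#' pH-sensitive dye, H is the acid-base readout (blue ~ 240 at neutral pH,
#' falling below 60 toward orange when acidic) and L the dye-concentration
#' (water-balance) readout.
#'
#' @param r,g,b channel values in \[0,1\] (vectorised).
#' @return A matrix with columns `h` (degrees), `s`, `l`.
#' @examples
#' rgbToHsl(1, 0, 0)  # pure red: h = 0, s = 1, l = 0.5
#' rgbToHsl(0, 0, 1)  # pure blue: h = 240
#' @export
rgbToHsl <- function(r, g, b) {
  if (any(c(r, g, b) < 0 | c(r, g, b) > 1)) stop("channels must lie in [0,1]")
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  ch <- mx - mn
  l <- (mx + mn) / 2
  s <- ifelse(ch == 0, 0, ch / (1 - abs(2 * l - 1)))
  hp <- numeric(length(mx))
  iR <- ch > 0 & mx == r
  iG <- ch > 0 & mx == g & !iR
  iB <- ch > 0 & mx == b & !iR & !iG
  hp[iR] <- ((g[iR] - b[iR]) / ch[iR]) %% 6
  hp[iG] <- (b[iG] - r[iG]) / ch[iG] + 2
  hp[iB] <- (r[iB] - g[iB]) / ch[iB] + 4
  h <- (hp * 60) %% 360
  cbind(h = h, s = s, l = l)
}

#' HSL to RGB conversion
#'
#' Inverse of [rgbToHsl()].
#'
#' @param h hue in degrees (any value; wrapped to \[0, 360)).
#' @param s,l saturation and lightness in \[0,1\].
#' @return A matrix with columns `r`, `g`, `b` in \[0,1\].
#' @export
hslToRgb <- function(h, s, l) {
  if (any(s < 0 | s > 1 | l < 0 | l > 1)) stop("s and l must lie in [0,1]")
  h <- h %% 360
  ch <- (1 - abs(2 * l - 1)) * s
  hp <- h / 60
  x <- ch * (1 - abs(hp %% 2 - 1))
  m <- l - ch / 2
  k <- pmin(floor(hp), 5)
  # per-sextant channel selector: 1 -> chroma, 3 -> x, 0 -> 0
  pick <- function(sel) ifelse(sel == 1, ch, ifelse(sel == 3, x, 0))
  selR <- c(1, 3, 0, 0, 3, 1)[k + 1]
  selG <- c(3, 1, 1, 3, 0, 0)[k + 1]
  selB <- c(0, 0, 3, 1, 1, 3)[k + 1]
  cbind(r = pick(selR) + m, g = pick(selG) + m, b = pick(selB) + m)
}

#' Integrated optical density
#'
#' `IOD = area * (1 - meanL)`: deposit area weighted by dye intensity.
#' Because hue shifts do not change L on a calibrated scan, IOD is a proxy
#' for the total excreted dye and hence (with appropriate controls) for
#' ingestion. The linearity of L in dye concentration is a scanner
#' calibration responsibility, not something the software can enforce.
#'
#' @param area deposit area in pixels, >= 0.
#' @param meanL mean HSL lightness in \[0,1\].
#' @return IOD value(s) >= 0.
#' @examples
#' iod(200, 0.4)  # 120
#' @export
iod <- function(area, meanL) {
  if (any(area < 0)) stop("area must be >= 0")
  if (any(meanL < 0 | meanL > 1)) stop("meanL must lie in [0,1]")
  area * (1 - meanL)
}

#' Assemble the full deposit record for one component
#'
#' Computes every per-deposit graphical variable: centroid position
#' (0-based pixels from the top-left corner), area, contour perimeter,
#' circularity, ROD flag, IOD, mean RGB, and the HSL transform of the mean
#' colour. The hue of a deposit is the hue of its mean RGB colour (the
#' single-object pooling rule applied to one object), reported as integer
#' degrees in \[0, 359\]; saturation and lightness keep full precision.
#' The `include` flag defaults to `TRUE` and supports manual curation.
#'
#' @param component a component from [labelComponents()].
#' @param image the source RGB image.
#' @param plateId plate identifier.
#' @param depositId deposit identifier, unique within the plate.
#' @param rodCutoff circularity cutoff for [classifyRod()].
#' @return A one-row `data.frame` with columns `plate_id`, `deposit_id`,
#'   `x`, `y`, `area`, `perimeter`, `circularity`, `is_rod`, `iod`,
#'   `mean_r`, `mean_g`, `mean_b`, `mean_h`, `mean_s`, `mean_l`, `include`.
#' @export
buildDeposit <- function(component, image, plateId, depositId,
                         rodCutoff = 0.5) {
  px <- component$pixels
  if (is.null(px) || nrow(px) == 0L) stop("empty component")
  area <- nrow(px)
  perim <- tracePerimeter(component)
  circ <- circularity(area, perim)
  rgb <- meanRgb(component, image)
  hsl <- rgbToHsl(rgb["r"], rgb["g"], rgb["b"])
  data.frame(
    plate_id = as.character(plateId),
    deposit_id = as.integer(depositId),
    x = mean(px[, 1L]),
    y = mean(px[, 2L]),
    area = area,
    perimeter = perim,
    circularity = circ,
    is_rod = classifyRod(circ, rodCutoff),
    iod = iod(area, hsl[1L, "l"]),
    mean_r = unname(rgb["r"]), mean_g = unname(rgb["g"]),
    mean_b = unname(rgb["b"]),
    mean_h = as.integer(round(hsl[1L, "h"])) %% 360L,
    mean_s = unname(hsl[1L, "s"]), mean_l = unname(hsl[1L, "l"]),
    include = TRUE,
    stringsAsFactors = FALSE)
}

#' Build the deposit table of a plate
#'
#' Runs [buildDeposit()] over a component list, numbering deposits 1..n in
#' detection (raster) order.
#'
#' @param components list from [detectSpots()].
#' @param image the source RGB image.
#' @param plateId plate identifier.
#' @param rodCutoff circularity cutoff.
#' @return A list with `deposits` (the stacked `data.frame`) and
#'   `pixelSets` (list of 0-based pixel matrices, one per row).
#' @export
buildDepositTable <- function(components, image, plateId, rodCutoff = 0.5) {
  rows <- lapply(seq_along(components), function(i)
    buildDeposit(components[[i]], image, plateId, i, rodCutoff))
  deposits <- if (length(rows)) do.call(rbind, rows) else emptyDepositTable()
  list(deposits = deposits,
       pixelSets = lapply(components, `[[`, "pixels"))
}

# Zero-row deposit table with the canonical column set and types.
emptyDepositTable <- function() {
  data.frame(plate_id = character(), deposit_id = integer(),
             x = numeric(), y = numeric(), area = numeric(),
             perimeter = numeric(), circularity = numeric(),
             is_rod = logical(), iod = numeric(),
             mean_r = numeric(), mean_g = numeric(), mean_b = numeric(),
             mean_h = integer(), mean_s = numeric(), mean_l = numeric(),
             include = logical(), stringsAsFactors = FALSE)
}
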