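# Seeded synthetic plate scans with per-spot ground truth. The generator
# emulates the phenomenology of dye-stained excreta scans well enough to
# exercise every stage of the pipeline: a light background with a smooth
# low-frequency gradient (so adaptive beats global thresholding), hard-edged
# round and capsule-shaped deposits with class-separated circularity and
# lightness, and sub-threshold artefact specks.

# Run expr under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# 0-based pixel footprint of a disc.
discFootprint <- function(cx, cy, r, width, height) {
  x0 <- max(0L, floor(cx - r)); x1 <- min(width - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(height - 1L, ceiling(cy + r))
  g <- expand.grid(x = x0:x1, y = y0:y1)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  as.matrix(g[keep, , drop = FALSE])
}

# 0-based pixel footprint of a capsule (segment of half-length hl and
# orientation theta, dilated by radius w/2).
capsuleFootprint <- function(cx, cy, len, w, theta, width, height) {
  hl <- (len - w) / 2
  ux <- cos(theta); uy <- sin(theta)
  r <- w / 2
  ext <- hl + r + 1
  x0 <- max(0L, floor(cx - ext)); x1 <- min(width - 1L, ceiling(cx + ext))
  y0 <- max(0L, floor(cy - ext)); y1 <- min(height - 1L, ceiling(cy + ext))
  g <- expand.grid(x = x0:x1, y = y0:y1)
  dx <- g$x - cx; dy <- g$y - cy
  t <- pmin(pmax(dx * ux + dy * uy, -hl), hl)   # clamp to the segment
  d2 <- (dx - t * ux)^2 + (dy - t * uy)^2
  as.matrix(g[d2 <= r^2, , drop = FALSE])
}

#' Generate a synthetic plate scan with ground truth
#'
#' Draws round and oblong (capsule) deposits uniformly within the class
#' ranges of the [SynthSpec-class], places them by rejection sampling
#' (non-overlapping by default, with a 4 px margin between bounding
#' circles), paints them hard-edged onto a light background carrying a
#' smooth low-frequency gradient, and adds sub-threshold artefact specks.
#' Deterministic for a fixed seed, down to the image bytes.
#'
#' @param spec a [SynthSpec-class] object.
#' @return A list with `image` (an [EBImage::Image], colour mode), `truth`
#'   (one row per generated deposit: `spot_id`, `class`, `cx`, `cy`,
#'   `area`, nominal `h`, `s`, `l`, `r`, `g`, `b`, `seed`), `footprints`
#'   (list of 0-based pixel matrices parallel to `truth` rows) and
#'   `artefacts` (speck positions and areas).
#' @examples
#' plate <- generatePlate(synthSpec(nRound = 3, nOblong = 1,
#'                                  width = 250, height = 250, seed = 5))
#' table(plate$truth$class)
#' @export
generatePlate <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    W <- spec@width; H <- spec@height
    # smooth background: base + low-frequency sinusoidal field
    phx <- runif(1, 0, 2 * pi); phy <- runif(1, 0, 2 * pi)
    xs <- (seq_len(W) - 1) / max(1, W - 1)
    ys <- (seq_len(H) - 1) / max(1, H - 1)
    field <- outer(sin(2 * pi * xs + phx), sin(2 * pi * ys + phy), `+`) / 2
    bg <- pmin(1, pmax(0, spec@background + spec@gradientAmplitude * field))
    img <- array(rep(bg, 3L), dim = c(W, H, 3L))

    classes <- c(rep("round", spec@nRound), rep("oblong", spec@nOblong),
                 rep("artefact", spec@nArtefacts))
    placedX <- numeric(0); placedY <- numeric(0); placedR <- numeric(0)
    margin <- 4
    truth <- list(); footprints <- list(); artefacts <- list()
    attempts <- 0L
    for (cls in classes) {
      if (cls == "round") {
        r <- runif(1, spec@roundRadius[1], spec@roundRadius[2])
        bound <- r
      } else if (cls == "oblong") {
        w <- runif(1, spec@oblongWidth[1], spec@oblongWidth[2])
        aspect <- runif(1, spec@oblongAspect[1], spec@oblongAspect[2])
        len <- aspect * w
        theta <- runif(1, 0, pi)
        bound <- len / 2
      } else {
        r <- runif(1, 1, 2)
        bound <- r
      }
      repeat {
        attempts <- attempts + 1L
        if (attempts > 10000L)
          stop("cannot place requested spots without overlap in 10^4 attempts")
        cx <- runif(1, bound + 1, W - bound - 2)
        cy <- runif(1, bound + 1, H - bound - 2)
        if (spec@overlap && cls != "artefact") break
        if (!length(placedR) ||
            all((cx - placedX)^2 + (cy - placedY)^2 >
                (bound + placedR + margin)^2)) break
      }
      placedX <- c(placedX, cx); placedY <- c(placedY, cy)
      placedR <- c(placedR, bound)
      if (cls == "artefact") {
        fp <- discFootprint(cx, cy, r, W, H)
        col <- c(runif(1, 0.2, 0.5), runif(1, 0.2, 0.5), runif(1, 0.2, 0.5))
        img[cbind(fp[, 1L] + 1L, fp[, 2L] + 1L, 1L)] <- col[1L]
        img[cbind(fp[, 1L] + 1L, fp[, 2L] + 1L, 2L)] <- col[2L]
        img[cbind(fp[, 1L] + 1L, fp[, 2L] + 1L, 3L)] <- col[3L]
        artefacts[[length(artefacts) + 1L]] <-
          data.frame(cx = cx, cy = cy, area = nrow(fp))
        next
      }
      if (cls == "round") {
        fp <- discFootprint(cx, cy, r, W, H)
        hue <- runif(1, spec@hueRound[1], spec@hueRound[2])
        light <- runif(1, spec@lightRound[1], spec@lightRound[2])
      } else {
        fp <- capsuleFootprint(cx, cy, len, w, theta, W, H)
        hue <- runif(1, spec@hueOblong[1], spec@hueOblong[2])
        light <- runif(1, spec@lightOblong[1], spec@lightOblong[2])
      }
      sat <- runif(1, spec@satRange[1], spec@satRange[2])
      rgb <- hslToRgb(hue, sat, light)[1L, ]
      img[cbind(fp[, 1L] + 1L, fp[, 2L] + 1L, 1L)] <- rgb["r"]
      img[cbind(fp[, 1L] + 1L, fp[, 2L] + 1L, 2L)] <- rgb["g"]
      img[cbind(fp[, 1L] + 1L, fp[, 2L] + 1L, 3L)] <- rgb["b"]
      truth[[length(truth) + 1L]] <- data.frame(
        spot_id = length(truth) + 1L, class = cls, cx = cx, cy = cy,
        area = nrow(fp), h = hue, s = sat, l = light,
        r = unname(rgb["r"]), g = unname(rgb["g"]), b = unname(rgb["b"]),
        seed = spec@seed, stringsAsFactors = FALSE)
      footprints[[length(footprints) + 1L]] <- fp
    }
    truthDf <- if (length(truth)) do.call(rbind, truth) else
      data.frame(spot_id = integer(), class = character(), cx = numeric(),
                 cy = numeric(), area = numeric(), h = numeric(),
                 s = numeric(), l = numeric(), r = numeric(), g = numeric(),
                 b = numeric(), seed = integer(), stringsAsFactors = FALSE)
    artefactsDf <- if (length(artefacts)) do.call(rbind, artefacts) else
      data.frame(cx = numeric(), cy = numeric(), area = numeric())
    list(image = EBImage::Image(img, colormode = "Color"),
         truth = truthDf, footprints = footprints, artefacts = artefactsDf)
  })
}

#' Score a detection against generator ground truth
#'
#' A truth spot is matched when exactly one detected centroid falls inside
#' its footprint (the centroid's nearest pixel). Recall is
#' matched / n_truth, precision is matched / n_detected (`NA` when nothing
#' was detected), and ROD accuracy is the fraction of matched spots whose
#' ROD flag agrees with the generated class (oblong = ROD).
#'
#' @param plate output of [generatePlate()].
#' @param deposits deposit table from the detection pipeline run on
#'   `plate$image`.
#' @return A list with `recall`, `precision`, `rod_accuracy`, `n_truth`,
#'   `n_detected`, `n_matched`, `n_correct_class`.
#' @export
scoreDetection <- function(plate, deposits) {
  truth <- plate$truth
  nT <- nrow(truth); nD <- nrow(deposits)
  if (nT == 0L)
    return(list(recall = NA_real_, precision = if (nD) 0 else NA_real_,
                rod_accuracy = NA_real_, n_truth = 0L, n_detected = nD,
                n_matched = 0L, n_correct_class = 0L))
  centKey <- if (nD) round(deposits$x) * 1e6 + round(deposits$y) else numeric(0)
  matched <- 0L; correct <- 0L
  for (i in seq_len(nT)) {
    fp <- plate$footprints[[i]]
    key <- fp[, 1L] * 1e6 + fp[, 2L]  # exact integer pair encoding
    hits <- which(centKey %in% key)
    if (length(hits) == 1L) {
      matched <- matched + 1L
      isRod <- deposits$is_rod[hits]
      if (isRod == (truth$class[i] == "oblong")) correct <- correct + 1L
    }
  }
  list(recall = matched / nT,
       precision = if (nD) matched / nD else NA_real_,
       rod_accuracy = if (matched) correct / matched else NA_real_,
       n_truth = nT, n_detected = nD, n_matched = matched,
       n_correct_class = correct)
}
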