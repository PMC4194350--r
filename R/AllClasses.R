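#' Detection parameter set
#'
#' Parameters of the deposit segmentation pipeline. Defaults are tuned for
#' wild-type defecation patterns scanned at 1200 dpi; at other resolutions
#' the size filter bounds are rescaled by `(dpi/1200)^2` (areas scale with
#' the square of the linear resolution) and a warning is emitted, since
#' shape features are resolution-sensitive and comparisons should only be
#' drawn between identically processed samples.
#'
#' @slot window odd integer, side of the square local-mean window (pixels).
#' @slot offset intensity offset in \[0,1\]; a pixel is foreground when its
#'   greyscale value is below the local mean minus this offset.
#' @slot minArea,maxArea inclusive size-filter bounds in pixels.
#' @slot weights length-3 non-negative greyscale weights (R, G, B), sum 1.
#' @slot connectivity 4 or 8 (default 8: confluent diagonal pixels merge).
#' @slot opening logical; apply a single morphological opening (disc radius
#'   1) to the binary map before labelling, to shave pixel-scale bridges
#'   between confluent spots. Off by default; no split of merged deposits
#'   is attempted.
#' @slot rodCutoff circularity cutoff in \[0,1\]; deposits strictly below it
#'   are classified as RODs.
#' @slot dpi nominal scan resolution the parameters refer to.
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(
    window = "integer", offset = "numeric",
    minArea = "numeric", maxArea = "numeric",
    weights = "numeric", connectivity = "integer",
    opening = "logical", rodCutoff = "numeric", dpi = "numeric"
  )
)

setValidity("DetectionParams", function(object) {
  msg <- character()
  w <- object@window
  if (length(w) != 1L || is.na(w) || w < 3L || w %% 2L == 0L)
    msg <- c(msg, "window must be a single odd integer >= 3")
  if (length(object@offset) != 1L || object@offset < 0)
    msg <- c(msg, "offset must be a single value >= 0")
  if (!(object@minArea >= 0 && object@minArea < object@maxArea))
    msg <- c(msg, "need 0 <= minArea < maxArea")
  if (length(object@weights) != 3L || any(object@weights < 0) ||
      abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "weights must be 3 non-negative values summing to 1")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (object@rodCutoff < 0 || object@rodCutoff > 1)
    msg <- c(msg, "rodCutoff must lie in [0,1]")
  if (object@dpi <= 0) msg <- c(msg, "dpi must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a DetectionParams object
#'
#' @param window odd local-window side in pixels (default 51 at 1200 dpi,
#'   sized to exceed typical deposit diameters).
#' @param offset local-mean offset intensity (default 0.06).
#' @param minArea,maxArea inclusive area bounds in pixels (defaults 40 and
#'   50000 at 1200 dpi; rescaled by `(dpi/1200)^2` when `dpi` differs and
#'   the bounds are left at their defaults).
#' @param weights greyscale conversion weights (default standard luma
#'   0.299, 0.587, 0.114).
#' @param connectivity 8 (default) or 4.
#' @param opening apply a radius-1 morphological opening before labelling.
#' @param rodCutoff circularity cutoff for ROD classification (default 0.5).
#' @param dpi nominal scan resolution (default 1200).
#' @return A [DetectionParams-class] object.
#' @examples
#' detectionParams()
#' detectionParams(dpi = 600)  # size bounds rescaled, with a warning
#' @export
detectionParams <- function(window = 51L, offset = 0.06,
                            minArea = NULL, maxArea = NULL,
                            weights = c(0.299, 0.587, 0.114),
                            connectivity = 8L, opening = FALSE,
                            rodCutoff = 0.5, dpi = 1200) {
  scale <- (dpi / 1200)^2
  defMin <- is.null(minArea)
  defMax <- is.null(maxArea)
  if (defMin) minArea <- 40 * scale
  if (defMax) maxArea <- 50000 * scale
  if (dpi != 1200 && (defMin || defMax))
    warning("dpi != 1200: default size-filter bounds rescaled by (dpi/1200)^2 = ",
            signif(scale, 4), call. = FALSE)
  new("DetectionParams",
      window = as.integer(window), offset = as.numeric(offset),
      minArea = as.numeric(minArea), maxArea = as.numeric(maxArea),
      weights = as.numeric(weights), connectivity = as.integer(connectivity),
      opening = isTRUE(opening), rodCutoff = as.numeric(rodCutoff),
      dpi = as.numeric(dpi))
}

#' Synthetic plate specification
#'
#' Parameters of the seeded synthetic plate generator. The generator
#' emulates the phenomenology of dye-stained excreta scans: a light, mildly
#' non-uniform background; dark round deposits; darker elongated capsule
#' deposits (RODs) so the pooled circularity distribution is bimodal;
#' deposit hue between blue (neutral pH) and orange/yellow (acidic); and
#' sub-threshold artefact specks.
#'
#' @slot width,height canvas size in pixels.
#' @slot nRound,nOblong deposit counts per class.
#' @slot roundRadius radius range (pixels) of round deposits.
#' @slot oblongWidth,oblongAspect capsule width range (pixels) and
#'   length:width aspect-ratio range of oblong deposits.
#' @slot hueRound,hueOblong hue range (degrees) per class.
#' @slot lightRound,lightOblong HSL lightness range per class (oblong
#'   deposits are darker: concentrated dye).
#' @slot satRange HSL saturation range (shared).
#' @slot background,gradientAmplitude background base intensity and
#'   amplitude of the smooth low-frequency gradient.
#' @slot nArtefacts number of sub-threshold specks (radius 1-2 px).
#' @slot overlap allow overlapping deposit footprints.
#' @slot seed integer RNG seed; a fixed seed gives bit-identical output.
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(
    width = "integer", height = "integer",
    nRound = "integer", nOblong = "integer",
    roundRadius = "numeric", oblongWidth = "numeric", oblongAspect = "numeric",
    hueRound = "numeric", hueOblong = "numeric",
    lightRound = "numeric", lightOblong = "numeric", satRange = "numeric",
    background = "numeric", gradientAmplitude = "numeric",
    nArtefacts = "integer", overlap = "logical", seed = "integer"
  )
)

setValidity("SynthSpec", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L) msg <- c(msg, "canvas must be >= 1x1")
  if (object@nRound < 0L || object@nOblong < 0L || object@nArtefacts < 0L)
    msg <- c(msg, "counts must be >= 0")
  rng2 <- function(x) length(x) == 2L && all(x > 0) && x[1] <= x[2]
  if (!rng2(object@roundRadius)) msg <- c(msg, "roundRadius must be a positive (lo, hi) pair")
  if (!rng2(object@oblongWidth)) msg <- c(msg, "oblongWidth must be a positive (lo, hi) pair")
  if (!rng2(object@oblongAspect) || object@oblongAspect[1] <= 1)
    msg <- c(msg, "oblongAspect must be a (lo, hi) pair with lo > 1")
  if (object@background < 0 || object@background > 1)
    msg <- c(msg, "background must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SynthSpec object
#'
#' Defaults describe the reference validation plate: a 1000 x 1000 px canvas
#' with 30 round and 30 oblong (capsule, aspect 5.5-7.5) deposits in the
#' blue hue band, oblong deposits darker than round ones, a light background
#' with a gentle smooth gradient, and 12 artefact specks below the default
#' minimum deposit size.
#'
#' @param width,height canvas size in pixels.
#' @param nRound,nOblong deposit counts.
#' @param roundRadius,oblongWidth,oblongAspect shape ranges (see
#'   [SynthSpec-class]).
#' @param hueRound,hueOblong hue ranges in degrees (blue ~ 240 for neutral
#'   pH; use values < 60 to emulate acidified, orange excreta).
#' @param lightRound,lightOblong,satRange HSL colour ranges per class.
#' @param background,gradientAmplitude background model.
#' @param nArtefacts sub-threshold speck count.
#' @param overlap allow overlapping footprints (default FALSE).
#' @param seed RNG seed.
#' @return A [SynthSpec-class] object.
#' @examples
#' synthSpec(nRound = 5, nOblong = 2, width = 300, height = 300, seed = 7)
#' @export
synthSpec <- function(width = 1000L, height = 1000L,
                      nRound = 30L, nOblong = 30L,
                      roundRadius = c(6, 14),
                      oblongWidth = c(7, 11), oblongAspect = c(5.5, 7.5),
                      hueRound = c(210, 250), hueOblong = c(210, 250),
                      lightRound = c(0.35, 0.55), lightOblong = c(0.15, 0.30),
                      satRange = c(0.55, 0.80),
                      background = 0.88, gradientAmplitude = 0.04,
                      nArtefacts = 12L, overlap = FALSE, seed = 1L) {
  new("SynthSpec",
      width = as.integer(width), height = as.integer(height),
      nRound = as.integer(nRound), nOblong = as.integer(nOblong),
      roundRadius = as.numeric(roundRadius),
      oblongWidth = as.numeric(oblongWidth),
      oblongAspect = as.numeric(oblongAspect),
      hueRound = as.numeric(hueRound), hueOblong = as.numeric(hueOblong),
      lightRound = as.numeric(lightRound), lightOblong = as.numeric(lightOblong),
      satRange = as.numeric(satRange),
      background = as.numeric(background),
      gradientAmplitude = as.numeric(gradientAmplitude),
      nArtefacts = as.integer(nArtefacts), overlap = isTRUE(overlap),
      seed = as.integer(seed))
}

#' One analysed plate
#'
#' Result of running the full detection and feature pipeline on one plate
#' scan: the deposit table (one row per detected deposit, all graphical
#' variables plus the editable `include` flag), the per-deposit pixel
#' memberships, and the plate-level summary (all / ROD / non-ROD subsets,
#' totals normalised per fly).
#'
#' @slot plateId plate identifier.
#' @slot imageFile source image filename (may be `NA` for in-memory images).
#' @slot timestamp processing timestamp (ISO 8601).
#' @slot nFlies number of flies that produced the plate.
#' @slot params [DetectionParams-class] snapshot used for detection.
#' @slot deposits deposit table (`data.frame`), see [buildDeposit()].
#' @slot pixelSets list of 2-column integer matrices (0-based x, y), one per
#'   deposit row.
#' @slot summary plate summary table, see [summarizePlate()].
#' @slot dim image width and height in pixels.
#' @exportClass PlateAnalysis
setClass("PlateAnalysis",
  representation(
    plateId = "character", imageFile = "character", timestamp = "character",
    nFlies = "integer", params = "DetectionParams",
    deposits = "data.frame", pixelSets = "list", summary = "data.frame",
    dim = "integer"
  )
)

setValidity("PlateAnalysis", function(object) {
  msg <- character()
  d <- object@deposits
  if (nrow(d) != length(object@pixelSets))
    msg <- c(msg, "one pixel set per deposit row required")
  if (nrow(d) > 0) {
    if (any(d$area != vapply(object@pixelSets, nrow, 1L)))
      msg <- c(msg, "deposit area must equal its pixel-set size")
    if (any(d$circularity < 0 | d$circularity > 1))
      msg <- c(msg, "circularity must lie in [0,1]")
    if (any(d$mean_h < 0 | d$mean_h > 359))
      msg <- c(msg, "mean_h must lie in [0,359]")
    if (any(abs(d$iod - d$area * (1 - d$mean_l)) > 1e-8 * pmax(1, d$area)))
      msg <- c(msg, "iod must equal area * (1 - mean_l)")
  }
  if (object@nFlies < 1L) msg <- c(msg, "nFlies must be >= 1")
  if (length(msg)) msg else TRUE
})

#' File-based experiment store
#'
#' A processed batch of plates, mirrored on disk as one directory per
#' experiment: `config.csv` (plate list with fly counts and groups),
#' `deposits_<plateId>.csv` per plate (editable `include` column),
#' `summaries.csv`, and `audit.csv` (one entry per processing attempt,
#' with timestamp and parameter snapshot).
#'
#' @slot experimentId experiment identifier.
#' @slot path store directory.
#' @slot plates plate configuration table (plate_id, image, n_flies, group,
#'   status).
#' @slot summaries stacked plate summary table.
#' @slot deposits named list of deposit tables, keyed by plate_id.
#' @slot audit audit-trail table.
#' @exportClass ExperimentStore
setClass("ExperimentStore",
  representation(
    experimentId = "character", path = "character",
    plates = "data.frame", summaries = "data.frame",
    deposits = "list", audit = "data.frame"
  )
)

setValidity("ExperimentStore", function(object) {
  msg <- character()
  if (!all(names(object@deposits) %in% object@plates$plate_id))
    msg <- c(msg, "all deposit tables must resolve to configured plates")
  if (length(msg)) msg else TRUE
})
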