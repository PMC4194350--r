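# Plate-level aggregation: per-fly totals, subset means and pooled colour
# for the whole plate and its ROD / non-ROD subsets.

#' Pooled colour of a set of deposits
#'
#' Mean colour over the union of all included deposits' pixels, i.e. the
#' colour features of the single object obtained by pooling every spot
#' pixel. Equivalently (and exactly), the area-weighted mean of the
#' per-deposit mean RGB colours, which is how the value is computed when no
#' pixel memberships are supplied — so the pooled colour can be recovered
#' from an exported deposit table alone. H, S and L are those of the pooled
#' mean colour.
#'
#' @param deposits deposit table (rows with `include = FALSE` are ignored).
#' @param image optional source image; with `pixelSets`, the value is
#'   computed from the raw pixel pool instead of the area-weighted route.
#' @param pixelSets optional list of pixel matrices parallel to
#'   `deposits` rows.
#' @return Named vector `c(r, g, b, h, s, l)`; all `NA` (with a warning)
#'   when no deposit is included.
#' @export
pooledColour <- function(deposits, image = NULL, pixelSets = NULL) {
  keep <- deposits$include
  if (!any(keep)) {
    warning("no included deposits: pooled colour undefined")
    return(c(r = NA_real_, g = NA_real_, b = NA_real_,
             h = NA_real_, s = NA_real_, l = NA_real_))
  }
  if (!is.null(image) && !is.null(pixelSets)) {
    a <- asRgbArray(image)
    px <- do.call(rbind, pixelSets[keep])
    i <- px[, 1L] + 1L; j <- px[, 2L] + 1L
    rgb <- c(r = mean(a[cbind(i, j, 1L)]),
             g = mean(a[cbind(i, j, 2L)]),
             b = mean(a[cbind(i, j, 3L)]))
  } else {
    d <- deposits[keep, , drop = FALSE]
    w <- d$area / sum(d$area)
    rgb <- c(r = sum(w * d$mean_r), g = sum(w * d$mean_g),
             b = sum(w * d$mean_b))
  }
  hsl <- rgbToHsl(rgb["r"], rgb["g"], rgb["b"])
  c(rgb, h = unname(hsl[1L, "h"]), s = unname(hsl[1L, "s"]),
    l = unname(hsl[1L, "l"]))
}

# Summary statistics of one deposit subset.
subsetSummary <- function(d, nFlies) {
  n <- nrow(d)
  totalArea <- sum(d$area)
  totalIod <- sum(d$iod)
  if (n > 0) {
    col <- pooledColour(d)
  } else {
    col <- c(r = NA_real_, g = NA_real_, b = NA_real_,
             h = NA_real_, s = NA_real_, l = NA_real_)
  }
  data.frame(
    n_spots = n,
    n_spots_per_fly = n / nFlies,
    total_area = totalArea,
    total_area_per_fly = totalArea / nFlies,
    total_iod = totalIod,
    total_iod_per_fly = totalIod / nFlies,
    mean_area = if (n > 0) mean(d$area) else NA_real_,
    mean_perimeter = if (n > 0) mean(d$perimeter) else NA_real_,
    mean_circularity = if (n > 0) mean(d$circularity) else NA_real_,
    mean_r = unname(col["r"]), mean_g = unname(col["g"]),
    mean_b = unname(col["b"]),
    mean_h = if (is.na(col["h"])) NA_integer_ else
      as.integer(round(col["h"])) %% 360L,
    mean_s = unname(col["s"]), mean_l = unname(col["l"]),
    stringsAsFactors = FALSE)
}

#' Summarise a plate's deposits
#'
#' Aggregates the included deposits of one plate into the plate-level
#' summary, for the whole plate and the ROD / non-ROD subsets separately.
#' Totals (spot count, area, IOD) are divided by the fly count; mean area,
#' perimeter and circularity are unweighted arithmetic means over deposits;
#' pooled colour follows [pooledColour()]. Empty subsets report zero totals
#' and missing (`NA`) means — never zeros — so downstream statistics skip
#' rather than bias. The ROD fraction `n_rod / n_all` is reported on the
#' `all` row.
#'
#' @param deposits deposit table of one plate.
#' @param nFlies number of flies that produced the plate (>= 1).
#' @param plateId plate identifier (defaults to the table's).
#' @param imageFile source filename for the record.
#' @param params optional [DetectionParams-class]; serialised into the
#'   `protocol` column as part of the audit contract.
#' @param timestamp processing timestamp string.
#' @return A 3-row `data.frame` (subset = `all`, `rod`, `non_rod`).
#' @export
summarizePlate <- function(deposits, nFlies, plateId = NULL,
                           imageFile = NA_character_, params = NULL,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  nFlies <- as.integer(nFlies)
  if (is.na(nFlies) || nFlies < 1L) stop("nFlies must be >= 1")
  if (is.null(plateId))
    plateId <- if (nrow(deposits)) deposits$plate_id[1L] else NA_character_
  d <- deposits[deposits$include, , drop = FALSE]
  parts <- list(all = d,
                rod = d[d$is_rod, , drop = FALSE],
                non_rod = d[!d$is_rod, , drop = FALSE])
  out <- do.call(rbind, lapply(names(parts), function(s) {
    row <- subsetSummary(parts[[s]], nFlies)
    cbind(data.frame(plate_id = as.character(plateId),
                     image_file = imageFile,
                     timestamp = timestamp,
                     protocol = if (is.null(params)) NA_character_ else
                       paramsString(params),
                     subset = s, n_flies = nFlies,
                     stringsAsFactors = FALSE),
          row)
  }))
  out$rod_fraction <- NA_real_
  nAll <- out$n_spots[out$subset == "all"]
  out$rod_fraction[out$subset == "all"] <-
    if (nAll > 0) out$n_spots[out$subset == "rod"] / nAll else NA_real_
  rownames(out) <- NULL
  out
}

# One-line parameter snapshot for summaries and the audit trail.
paramsString <- function(p) {
  sprintf(paste0("window=%d;offset=%g;minArea=%g;maxArea=%g;",
                 "weights=%g,%g,%g;connectivity=%d;opening=%s;",
                 "rodCutoff=%g;dpi=%g"),
          p@window, p@offset, p@minArea, p@maxArea,
          p@weights[1], p@weights[2], p@weights[3],
          p@connectivity, p@opening, p@rodCutoff, p@dpi)
}

#' Analyse one plate image end to end
#'
#' Detection ([detectSpots()]), feature extraction ([buildDepositTable()])
#' and plate summary ([summarizePlate()]) in one call.
#'
#' @param image an RGB image, or a file path accepted by
#'   [readPlateImage()].
#' @param params a [DetectionParams-class] object.
#' @param plateId plate identifier (defaults to the image filename stem).
#' @param nFlies number of flies on the plate.
#' @return A [PlateAnalysis-class] object.
#' @examples
#' plate <- generatePlate(synthSpec(nRound = 4, nOblong = 2,
#'                                  width = 300, height = 300, seed = 3))
#' pa <- analyzePlate(plate$image, detectionParams(), "demo", nFlies = 6)
#' plateSummary(pa)[, c("subset", "n_spots", "total_iod_per_fly")]
#' @export
analyzePlate <- function(image, params = detectionParams(), plateId = NULL,
                         nFlies = 1L) {
  imageFile <- NA_character_
  if (is.character(image)) {
    imageFile <- image
    image <- readPlateImage(image)
  }
  if (is.null(plateId))
    plateId <- if (is.na(imageFile)) "plate" else
      sub("\\.[^.]*$", "", basename(imageFile))
  comps <- detectSpots(image, params)
  tab <- buildDepositTable(comps, image, plateId, params@rodCutoff)
  ts <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  summ <- summarizePlate(tab$deposits, nFlies, plateId, imageFile, params,
                         timestamp = ts)
  a <- asRgbArray(image)
  new("PlateAnalysis",
      plateId = as.character(plateId), imageFile = imageFile, timestamp = ts,
      nFlies = as.integer(nFlies), params = params,
      deposits = tab$deposits, pixelSets = tab$pixelSets, summary = summ,
      dim = dim(a)[1:2])
}

#' Re-summarise a deposit table after manual curation
#'
#' Recomputes the plate summary from an (edited) deposit table, honouring
#' the `include` flags — the headless counterpart of unticking artefacts in
#' an inspector window.
#'
#' @inheritParams summarizePlate
#' @return A 3-row summary `data.frame`.
#' @export
resummarize <- function(deposits, nFlies, plateId = NULL,
                        imageFile = NA_character_, params = NULL) {
  summarizePlate(deposits, nFlies, plateId, imageFile, params)
}
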