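# File I/O: plate images, annotated overlays, CSV export/import.

#' Read a plate scan
#'
#' Reads a PNG/TIFF/JPEG plate image, normalises channels to \[0,1\]
#' (8- or 16-bit), promotes greyscale to RGB, drops any alpha channel, and
#' attaches the scan resolution as the `"dpi"` attribute — taken from the
#' file metadata when available, otherwise assumed 1200 with a warning.
#'
#' @param path image file path.
#' @return An [EBImage::Image] in colour mode with a `"dpi"` attribute.
#' @export
readPlateImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  a <- asRgbArray(img)
  out <- EBImage::Image(a, colormode = "Color")
  dpi <- imageDpi(path)
  if (is.na(dpi)) {
    warning("no resolution metadata in ", basename(path),
            ": assuming 1200 dpi", call. = FALSE)
    dpi <- 1200
  }
  attr(out, "dpi") <- dpi
  out
}

# Best-effort dpi from PNG/TIFF metadata; NA when absent.
imageDpi <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower) && requireNamespace("png", quietly = TRUE)) {
    info <- attr(png::readPNG(path, info = TRUE), "info")
    if (!is.null(info$dpi) && all(is.finite(info$dpi)))
      return(mean(info$dpi))
  }
  if (grepl("\\.tiff?$", lower) && requireNamespace("tiff", quietly = TRUE)) {
    im <- tiff::readTIFF(path, info = TRUE)
    res <- attr(im, "x.resolution")
    unit <- attr(im, "resolution.unit")
    if (!is.null(res) && is.finite(res)) {
      if (is.null(unit) || unit == "inch") return(res)
      if (unit == "cm") return(res * 2.54)
    }
  }
  NA_real_
}

# 3x5 bitmap digit font for annotation labels, rows top to bottom.
.digitFont <- lapply(list(
  c("111", "101", "101", "101", "111"),  # 0
  c("010", "110", "010", "010", "111"),
  c("111", "001", "111", "100", "111"),
  c("111", "001", "111", "001", "111"),
  c("101", "101", "111", "001", "001"),
  c("111", "100", "111", "001", "111"),
  c("111", "100", "111", "101", "111"),
  c("111", "001", "010", "010", "010"),
  c("111", "101", "111", "101", "111"),
  c("111", "101", "111", "001", "111")   # 9
), function(rows) {
  m <- do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]])))
  t(m)  # -> [x, y]
})

# Stamp an integer label into an RGB array at 0-based (x, y), top-left
# anchored, with pixel scale `scale` and colour `col`. Clipped at borders.
stampNumber <- function(a, number, x, y, col, scale = 2L) {
  digits <- strsplit(as.character(number), "")[[1]]
  W <- dim(a)[1L]; H <- dim(a)[2L]
  for (d in seq_along(digits)) {
    glyph <- .digitFont[[as.integer(digits[d]) + 1L]]
    offx <- x + (d - 1L) * 4L * scale
    on <- which(glyph == 1L, arr.ind = TRUE)
    for (s1 in 0:(scale - 1L)) for (s2 in 0:(scale - 1L)) {
      px <- offx + (on[, 1L] - 1L) * scale + s1 + 1L
      py <- y + (on[, 2L] - 1L) * scale + s2 + 1L
      ok <- px >= 1L & px <= W & py >= 1L & py <= H
      if (any(ok)) {
        a[cbind(px[ok], py[ok], 1L)] <- col[1L]
        a[cbind(px[ok], py[ok], 2L)] <- col[2L]
        a[cbind(px[ok], py[ok], 3L)] <- col[3L]
      }
    }
  }
  a
}

# Border pixels of a pixel set: members with an 8-neighbour outside the set.
borderPixels <- function(px) {
  if (nrow(px) == 0L) return(px)
  bb <- c(min(px[, 1L]), min(px[, 2L]), max(px[, 1L]), max(px[, 2L]))
  w <- bb[3L] - bb[1L] + 3L; h <- bb[4L] - bb[2L] + 3L
  m <- matrix(0L, w, h)
  i <- px[, 1L] - bb[1L] + 2L; j <- px[, 2L] - bb[2L] + 2L
  m[cbind(i, j)] <- 1L
  nb <- m[i - 1L + (j - 2L) * w] + m[i + (j - 2L) * w] + m[i + 1L + (j - 2L) * w] +
    m[i - 1L + (j - 1L) * w] + m[i + 1L + (j - 1L) * w] +
    m[i - 1L + j * w] + m[i + j * w] + m[i + 1L + j * w]
  px[nb < 8L, , drop = FALSE]
}

#' Write an annotated plate image
#'
#' Renders the detection result for visual curation: each deposit is
#' outlined and labelled with its deposit ID near its bounding box — blue
#' labels for RODs, red for non-RODs, mirroring the blue-coded ROD
#' annotation convention. Excluded deposits are drawn grey with a
#' strike-through line. The output has exactly the input dimensions.
#'
#' @param image the source RGB image.
#' @param deposits deposit table of the plate.
#' @param pixelSets per-deposit pixel memberships (e.g. [pixelSets()]).
#' @param path output file (format from the extension, e.g. `.png`).
#' @return `path`, invisibly.
#' @export
writeAnnotatedImage <- function(image, deposits, pixelSets, path) {
  a <- asRgbArray(image)
  colRod <- c(0, 0, 1); colNon <- c(0.85, 0, 0); colOut <- c(0.45, 0.45, 0.45)
  for (i in seq_len(nrow(deposits))) {
    px <- pixelSets[[i]]
    inc <- deposits$include[i]
    col <- if (!inc) colOut else if (deposits$is_rod[i]) colRod else colNon
    bp <- borderPixels(px)
    a[cbind(bp[, 1L] + 1L, bp[, 2L] + 1L, 1L)] <- col[1L]
    a[cbind(bp[, 1L] + 1L, bp[, 2L] + 1L, 2L)] <- col[2L]
    a[cbind(bp[, 1L] + 1L, bp[, 2L] + 1L, 3L)] <- col[3L]
    lx <- max(0L, min(px[, 1L]) - 2L)
    ly <- max(0L, min(px[, 2L]) - 12L)
    a <- stampNumber(a, deposits$deposit_id[i], lx, ly, col)
    if (!inc) {  # strike through the bounding box diagonal
      bb <- c(min(px[, 1L]), min(px[, 2L]), max(px[, 1L]), max(px[, 2L]))
      n <- max(bb[3L] - bb[1L], bb[4L] - bb[2L]) + 1L
      t <- seq(0, 1, length.out = max(2L, n))
      sx <- round(bb[1L] + t * (bb[3L] - bb[1L])) + 1L
      sy <- round(bb[2L] + t * (bb[4L] - bb[2L])) + 1L
      a[cbind(sx, sy, 1L)] <- colOut[1L]
      a[cbind(sx, sy, 2L)] <- colOut[2L]
      a[cbind(sx, sy, 3L)] <- colOut[3L]
    }
  }
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Export a table as CSV
#'
#' Fixed CSV dialect for cross-tool portability: comma separator, `.`
#' decimal point, UTF-8, header row, missing values as empty fields, no
#' row names. The full column set of the table is always written.
#'
#' @param table a `data.frame` (deposits, summaries, descriptives or
#'   comparisons).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportCsv <- function(table, path) {
  if (is.null(table)) stop("table must not be NULL")
  tryCatch(
    write.csv(table, path, row.names = FALSE, na = "", quote = TRUE,
              fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write ", path, ": ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("cannot write ", path, ": ",
                               conditionMessage(w), call. = FALSE))
  invisible(path)
}

#' Read back an exported deposit table
#'
#' Restores column types, including the editable `include` flag, so a
#' manually curated table can be re-summarised ([resummarize()]).
#'
#' @param path CSV file written by [exportCsv()].
#' @return A deposit `data.frame`.
#' @export
readDepositCsv <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  tmpl <- emptyDepositTable()
  missing <- setdiff(names(tmpl), names(d))
  if (length(missing))
    stop("not a deposit table (missing: ", paste(missing, collapse = ", "), ")")
  d$plate_id <- as.character(d$plate_id)
  d$deposit_id <- as.integer(d$deposit_id)
  d$mean_h <- as.integer(d$mean_h)
  d$is_rod <- as.logical(d$is_rod)
  d$include <- as.logical(d$include)
  d
}
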