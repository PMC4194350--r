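# Independent brute-force oracles used to cross-check the pipeline
# implementations, plus small fixture builders.

# --- fixtures -------------------------------------------------------------

discMask <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad
  cx <- r + pad
  m <- outer(seq_len(n), seq_len(n),
             function(x, y) as.integer((x - cx)^2 + (y - cx)^2 <= r^2))
  storage.mode(m) <- "integer"
  m
}

# Flat grey RGB image from a mask: foreground dark, background light.
maskToRgb <- function(mask, fg = 0.2, bg = 0.9) {
  g <- ifelse(mask == 1L, fg, bg)
  array(rep(g, 3L), dim = c(dim(mask), 3L))
}

randomMask <- function(nx, ny, pFg = 0.3) {
  m <- matrix(as.integer(runif(nx * ny) < pFg), nx, ny)
  storage.mode(m) <- "integer"
  m
}

# --- adaptive threshold: naive sliding-window mean with reflect padding ---

bruteLocalMeanThreshold <- function(grey, window, offset) {
  nx <- nrow(grey); ny <- ncol(grey)
  p <- (window - 1L) %/% 2L
  reflect <- function(i, n) {
    # tiled symmetric reflection (edge included)
    base <- c(seq_len(n), rev(seq_len(n)))
    base[((i - 1L) %% (2L * n)) + 1L]
  }
  out <- matrix(0L, nx, ny)
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    xs <- reflect((x - p):(x + p), nx)
    ys <- reflect((y - p):(y + p), ny)
    out[x, y] <- as.integer(grey[x, y] < mean(grey[xs, ys]) - offset)
  }
  out
}

# --- connected components: union-find over foreground pixels --------------

unionFindLabel <- function(mask, connectivity = 8L) {
  nx <- nrow(mask); ny <- ncol(mask)
  parent <- seq_len(nx * ny)
  find <- function(i) {
    i <- as.integer(i)
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  offs <- if (connectivity == 8L)
    list(c(-1, -1), c(0, -1), c(1, -1), c(-1, 0)) else
    list(c(0, -1), c(-1, 0))
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (mask[x, y] == 0L) next
    i <- x + (y - 1L) * nx
    for (o in offs) {
      qx <- x + o[1]; qy <- y + o[2]
      if (qx >= 1L && qx <= nx && qy >= 1L && qy <= ny && mask[qx, qy] == 1L)
        union(i, qx + (qy - 1L) * nx)
    }
  }
  lab <- matrix(0L, nx, ny)
  fg <- which(mask == 1L)
  roots <- vapply(fg, find, 1L)
  lab[fg] <- match(roots, unique(roots))  # raster order of first pixels
  lab
}

# --- hole filling: flood fill background from the border ------------------

floodFillHoles <- function(pixels, bbox) {
  w <- bbox[3] - bbox[1] + 3L; h <- bbox[4] - bbox[2] + 3L
  m <- matrix(0L, w, h)
  m[cbind(pixels[, 1] - bbox[1] + 2L, pixels[, 2] - bbox[2] + 2L)] <- 1L
  outside <- matrix(FALSE, w, h)
  border <- row(m) == 1L | row(m) == w | col(m) == 1L | col(m) == h
  queue <- which(border & m == 0L)
  outside[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    x <- ((i - 1L) %% w) + 1L; y <- ((i - 1L) %/% w) + 1L
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      qx <- x + o[1]; qy <- y + o[2]
      if (qx < 1L || qy < 1L || qx > w || qy > h) next
      j <- qx + (qy - 1L) * w
      if (!outside[j] && m[j] == 0L) {
        outside[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  filled <- which(m == 1L | !outside)
  xy <- arrayInd(filled, c(w, h))
  cbind(x = xy[, 1] + bbox[1] - 2L, y = xy[, 2] + bbox[2] - 2L)
}

# --- Mann-Whitney exact two-sided p by full enumeration -------------------

enumMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n <- length(a); m <- length(b)
  uStat <- function(x, y) sum(outer(x, y, ">"))
  uObs <- uStat(a, b)
  combos <- combn(length(pooled), n)
  us <- apply(combos, 2L, function(ix) uStat(pooled[ix], pooled[-ix]))
  pLess <- mean(us <= uObs)
  pGreater <- mean(us >= uObs)
  min(1, 2 * min(pLess, pGreater))
}

# --- reference HSL values for the classic named-colour probe set ----------
# (independent of the package conversion; hand-checkable)

hslProbe <- data.frame(
  name = c("red", "lime", "blue", "yellow", "cyan", "magenta",
           "black", "white", "gray", "silver", "maroon", "olive"),
  r = c(1, 0, 0, 1, 0, 1, 0, 1, 0.5, 0.75, 0.5, 0.5),
  g = c(0, 1, 0, 1, 1, 0, 0, 1, 0.5, 0.75, 0, 0.5),
  b = c(0, 0, 1, 0, 1, 1, 0, 1, 0.5, 0.75, 0, 0),
  h = c(0, 120, 240, 60, 180, 300, 0, 0, 0, 0, 0, 60),
  s = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 1, 1),
  l = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0, 1, 0.5, 0.75, 0.25, 0.25))

# small synthetic plate spec used across tests (fast, well separated)
testSpec <- function(seed = 1L, ...) {
  args <- list(width = 420L, height = 420L, nRound = 6L, nOblong = 4L,
               nArtefacts = 4L, seed = seed)
  do.call(synthSpec, utils::modifyList(args, list(...)))
}
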