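#' Internal utilities: seeded evaluation, stable seed derivation, rasters
#'
#' @name tissuemil-utils
#' @keywords internal
NULL

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Stages of a pipeline must be independently reproducible, so each stage's
#' RNG seed is derived from the global seed and the stage name by a stable
#' polynomial string hash (no external state). Result is always in
#' `[0, 2^31 - 1)`.
#'
#' @param seed Integer global seed.
#' @param label Character scalar naming the consumer (e.g. a stage name).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  codes <- utf8ToInt(label)
  h <- as.double(seed) %% 2147483647
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Logical matrix -> integer label matrix of 8-connected components.
# EBImage::bwlabel is 4-connected, so components are taken on the pixel
# adjacency graph instead.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  n <- sum(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0L) return(lab)
  idx <- which(mask)                      # column-major pixel ids
  id_of <- integer(length(mask))
  id_of[idx] <- seq_len(n)
  H <- nrow(mask); W <- ncol(mask)
  yy <- ((idx - 1L) %% H) + 1L
  xx <- ((idx - 1L) %/% H) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    ny <- yy + o[1L]; nx <- xx + o[2L]
    ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
    nidx <- (nx[ok] - 1L) * H + ny[ok]
    hit <- mask[nidx]
    from <- c(from, id_of[idx[ok]][hit])
    to <- c(to, id_of[nidx[hit]])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Gaussian blur of a 2D matrix or H x W x C array via EBImage, with
# replicated borders so constant images stay constant.
blur_raster <- function(x, sigma) {
  if (sigma <= 0) return(x)
  blur1 <- function(m) {
    pad <- max(4L, ceiling(3 * sigma))
    H <- nrow(m); W <- ncol(m)
    ry <- c(rep(1L, pad), seq_len(H), rep(H, pad))
    rx <- c(rep(1L, pad), seq_len(W), rep(W, pad))
    mp <- m[ry, rx, drop = FALSE]
    bp <- EBImage::gblur(mp, sigma = sigma)
    bp[pad + seq_len(H), pad + seq_len(W), drop = FALSE]
  }
  if (is.matrix(x)) return(blur1(x))
  stopifnot(length(dim(x)) == 3L)
  out <- x
  for (k in seq_len(dim(x)[3L])) out[, , k] <- blur1(x[, , k])
  out
}

# Bounding box of a logical matrix: 0-based half-open c(y0, y1, x0, x1).
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  c(min(idx[, 1L]) - 1L, max(idx[, 1L]), min(idx[, 2L]) - 1L, max(idx[, 2L]))
}

# Binary erosion by a disc of radius r (px) using EBImage.
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask != 0)
  k <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  EBImage::erode(mask * 1, k) > 0.5
}

# Luminance of an H x W x 3 array (Rec. 601 weights).
luminance <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

# Softmax of a numeric vector, numerically stable.
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Area of a polygon given vertex coordinates (shoelace).
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex hull area over full pixel extents: the four corners of every
# foreground pixel feed the hull, so the hull covers whole pixels and
# hull area >= pixel-count area for convex shapes.
chull_area <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  y <- idx[, 1L]; x <- idx[, 2L]
  xs <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  ys <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  h <- grDevices::chull(xs, ys)
  polygon_area(xs[h], ys[h])
}
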