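#' Attention overlay confined to tissue outlines
#'
#' Colours each instance's outline (and optionally its interior) on a
#' diverging blue-to-red scale monotone in the attention weight, leaving
#' every non-instance pixel untouched — so the highlighting is strictly
#' confined to the anatomical boundaries of the tissues rather than to
#' arbitrary rectangles.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param instances List of `tissue_instance` objects with masks in slide
#'   coordinates.
#' @param attention Numeric vector aligned with `instances`, summing
#'   to 1.
#' @param fill Also tint instance interiors (alpha-blended).
#' @param outline_px Outline thickness in pixels.
#' @return Object of class `overlay_figure`: `image` (modified copy),
#'   `coloured` (tibble `y`, `x`, `instance_id`), `attention`, `scale`
#'   (tibble `instance_id`, `attention`, `value`, `colour`).
#' @export
attention_overlay <- function(image, instances, attention, fill = FALSE,
                              outline_px = 2L) {
  stopifnot(length(instances) == length(attention))
  if (abs(sum(attention) - 1) > 1e-6) {
    stop("attention weights must sum to 1", call. = FALSE)
  }
  H <- dim(image)[1L]; W <- dim(image)[2L]
  rng <- range(attention)
  val <- if (diff(rng) < 1e-12) rep(0.5, length(attention)) else
    (attention - rng[1L]) / diff(rng)
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  cols <- ramp(val) / 255
  out <- image
  coloured <- list()
  for (i in seq_along(instances)) {
    m <- instances[[i]]$mask
    if (!all(dim(m) == c(H, W))) stop("instance ", i, " outside image", call. = FALSE)
    edge <- m & !erode_mask(m, outline_px)
    tgt <- if (fill) m else edge
    idx <- which(tgt)
    for (k in 1:3) {
      ch <- out[, , k]
      if (fill) {
        ch[idx] <- 0.5 * ch[idx] + 0.5 * cols[i, k]
        eidx <- which(edge)
        ch[eidx] <- cols[i, k]
      } else {
        ch[idx] <- cols[i, k]
      }
      out[, , k] <- ch
    }
    w <- which(tgt, arr.ind = TRUE)
    coloured[[i]] <- tibble::tibble(y = w[, 1L], x = w[, 2L], instance_id = i)
  }
  structure(list(image = out,
                 coloured = dplyr::bind_rows(coloured),
                 attention = attention,
                 scale = tibble::tibble(
                   instance_id = seq_along(attention),
                   attention = attention, value = val,
                   colour = grDevices::rgb(cols[, 1], cols[, 2], cols[, 3]))),
            class = "overlay_figure")
}

#' Rectangular tile heatmap (comparison baseline)
#'
#' Renders per-tile scores as a grid heatmap at tile resolution with no
#' interpolation between tiles: smoothing the map could not add back
#' information the tiling already discarded. The grid has exactly
#' `ceiling(H / t) x ceiling(W / t)` cells; the last row/column is
#' padded.
#'
#' @param image H x W x 3 array.
#' @param tile_size Tile side in pixels.
#' @param tile_scores Matrix of scores, dimensions
#'   `ceiling(H / t) x ceiling(W / t)`.
#' @param alpha Blend factor of the heatmap over the image.
#' @return An `overlay_figure` (with `tile_size` and `tile_scores`
#'   recorded).
#' @export
tile_overlay <- function(image, tile_size, tile_scores, alpha = 0.5) {
  H <- dim(image)[1L]; W <- dim(image)[2L]
  nr <- ceiling(H / tile_size); nc <- ceiling(W / tile_size)
  if (!all(dim(tile_scores) == c(nr, nc))) {
    stop("`tile_scores` must be ", nr, " x ", nc, call. = FALSE)
  }
  rng <- range(tile_scores)
  val <- if (diff(rng) < 1e-12) matrix(0.5, nr, nc) else
    (tile_scores - rng[1L]) / diff(rng)
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  out <- image
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ys <- ((i - 1L) * tile_size + 1L):min(i * tile_size, H)
      xs <- ((j - 1L) * tile_size + 1L):min(j * tile_size, W)
      col <- ramp(val[i, j]) / 255
      for (k in 1:3) {
        out[ys, xs, k] <- (1 - alpha) * out[ys, xs, k] + alpha * col[k]
      }
    }
  }
  structure(list(image = out, tile_size = tile_size, tile_scores = tile_scores,
                 resolution = c(nr, nc)),
            class = c("tile_overlay", "overlay_figure"))
}

# Downsample a crop to a fixed grey thumbnail feature vector.
.student_features <- function(crop, side = 16L) {
  lum <- luminance(crop)
  H <- nrow(lum); W <- ncol(lum)
  yi <- pmin(pmax(ceiling(seq_len(side) * H / side), 1L), H)
  xi <- pmin(pmax(ceiling(seq_len(side) * W / side), 1L), W)
  as.vector(lum[yi, xi])
}

#' Train an attention-distilled per-instance student model
#'
#' Fits a small per-instance image regressor to the slide label with a
#' squared-error loss in which each instance's term is multiplied by its
#' attention weight from the bag model, so low-attention instances
#' contribute vanishingly to the gradient. All instances are used; the
#' fit is seeded and early-stopped on a held-out subset. The student maps
#' one instance crop to one slide-label score and exists so that
#' within-instance occlusion saliency can be computed even when the bag
#' model consumes handcrafted features that do not backpropagate to
#' pixels.
#'
#' @param crops List of H x W x 3 crops.
#' @param attentions Per-crop attention weights (nonnegative, not all
#'   zero).
#' @param labels Per-crop slide labels (numeric; binary tasks use 0/1).
#' @param hidden Hidden width of the one-hidden-layer student (0 for a
#'   linear student; depth is a free choice — the contract is the
#'   weighted loss, not the architecture).
#' @param side Thumbnail side used as student input.
#' @param lr,epochs,patience Optimiser settings.
#' @param val_frac Held-out fraction for early stopping.
#' @param seed Integer seed.
#' @return Object of class `student_model` with a `predict()` method
#'   mapping a crop to a score.
#' @export
train_student <- function(crops, attentions, labels, hidden = 16L,
                          side = 16L, lr = 1e-2, epochs = 300L,
                          patience = 30L, val_frac = 0.2, seed = 1L) {
  stopifnot(length(crops) == length(attentions),
            length(crops) == length(labels))
  if (all(attentions <= 0)) stop("all attentions are zero; nothing to learn from",
                                 call. = FALSE)
  X <- t(vapply(crops, .student_features, numeric(side^2), side = side))
  y <- as.numeric(labels)
  a <- attentions / mean(attentions)
  n <- nrow(X); D <- ncol(X)
  with_seed(seed, {
    val_idx <- sample.int(n, max(1L, round(val_frac * n)))
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0L) tr_idx <- val_idx
    if (hidden > 0L) {
      W1 <- matrix(stats::rnorm(hidden * D, 0, sqrt(1 / D)), hidden, D)
      b1 <- numeric(hidden)
      w2 <- stats::rnorm(hidden, 0, sqrt(1 / hidden)); b2 <- 0
    } else {
      W1 <- NULL; b1 <- NULL
      w2 <- stats::rnorm(D, 0, sqrt(1 / D)); b2 <- 0
    }
    fwd <- function(Xm) {
      if (hidden > 0L) {
        Hm <- tanh(Xm %*% t(W1) + rep(b1, each = nrow(Xm)))
        list(H = Hm, out = as.vector(Hm %*% w2 + b2))
      } else {
        list(H = Xm, out = as.vector(Xm %*% w2 + b2))
      }
    }
    best <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, loss = Inf)
    stall <- 0L
    for (ep in seq_len(epochs)) {
      fw <- fwd(X[tr_idx, , drop = FALSE])
      resid <- fw$out - y[tr_idx]
      aw <- a[tr_idx]
      dout <- 2 * aw * resid / length(tr_idx)
      gw2 <- as.vector(t(fw$H) %*% dout)
      gb2 <- sum(dout)
      if (hidden > 0L) {
        dH <- dout %o% w2 * (1 - fw$H^2)
        gW1 <- t(dH) %*% X[tr_idx, , drop = FALSE]
        gb1 <- colSums(dH)
        W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
      }
      w2 <- w2 - lr * gw2; b2 <- b2 - lr * gb2
      vd <- fwd(X[val_idx, , drop = FALSE])
      vloss <- mean(a[val_idx] * (vd$out - y[val_idx])^2)
      if (vloss < best$loss - 1e-8) {
        best <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, loss = vloss)
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= patience) break
    }
    structure(list(W1 = best$W1, b1 = best$b1, w2 = best$w2, b2 = best$b2,
                   hidden = hidden, side = side, val_loss = best$loss),
              class = "student_model")
  })
}

#' @export
predict.student_model <- function(object, crop, ...) {
  x <- .student_features(crop, object$side)
  if (object$hidden > 0L) {
    h <- tanh(as.vector(object$W1 %*% x) + object$b1)
    sum(object$w2 * h) + object$b2
  } else {
    sum(object$w2 * x) + object$b2
  }
}

#' Occlusion saliency within one instance crop
#'
#' Slides a square occlusion window (filled with a neutral colour) over
#' the crop and scores each occluded copy with the student; the saliency
#' at a pixel is the mean drop in the student's score over all windows
#' covering it. With `stride = window` each pixel is covered exactly
#' once. The map is confined to the instance mask when one is given.
#'
#' @param student A `student_model`, or any function mapping a crop to a
#'   single score.
#' @param crop H x W x 3 array.
#' @param window Window side in pixels (default 16; must not exceed the
#'   crop).
#' @param stride Step between window positions (default 8).
#' @param mask Optional logical matrix; saliency outside is zeroed.
#' @param fill Occlusion fill value(s); default the crop's mean colour.
#' @return Matrix of per-pixel saliency (same H x W as the crop).
#' @export
occlusion_saliency <- function(student, crop, window = 16L, stride = 8L,
                               mask = NULL, fill = NULL) {
  H <- dim(crop)[1L]; W <- dim(crop)[2L]
  if (window > H || window > W) stop("`window` exceeds the crop", call. = FALSE)
  score <- if (is.function(student)) student else
    function(cr) predict(student, cr)
  if (is.null(fill)) fill <- apply(crop, 3L, mean)
  if (length(fill) == 1L) fill <- rep(fill, 3L)
  base <- score(crop)
  drops <- matrix(0, H, W); cover <- matrix(0, H, W)
  ys <- unique(c(seq(1L, H - window + 1L, by = stride), H - window + 1L))
  xs <- unique(c(seq(1L, W - window + 1L, by = stride), W - window + 1L))
  for (y0 in ys) {
    for (x0 in xs) {
      occ <- crop
      for (k in 1:3) occ[y0:(y0 + window - 1L), x0:(x0 + window - 1L), k] <- fill[k]
      d <- base - score(occ)
      drops[y0:(y0 + window - 1L), x0:(x0 + window - 1L)] <-
        drops[y0:(y0 + window - 1L), x0:(x0 + window - 1L)] + d
      cover[y0:(y0 + window - 1L), x0:(x0 + window - 1L)] <-
        cover[y0:(y0 + window - 1L), x0:(x0 + window - 1L)] + 1
    }
  }
  sal <- drops / pmax(cover, 1)
  if (!is.null(mask)) sal[!mask] <- 0
  sal
}

#' Write an overlay figure to PNG
#'
#' @param figure An `overlay_figure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_overlay <- function(figure, path) {
  stopifnot(inherits(figure, "overlay_figure"))
  png::writePNG(figure$image, path)
  invisible(path)
}
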