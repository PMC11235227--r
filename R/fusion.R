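#' Uncertainty-penalised fusion of an ensemble probability stack
#'
#' Combines per-model probability maps into a corrected map
#' `p_tilde = max(p_mean - A * p_sigma, 0)`: pixels where the ensemble
#' members disagree are penalised in proportion to the across-model
#' standard deviation, which suppresses overconfident false-positive
#' segments that only a subset of models produce.
#'
#' @param stack A [prob_stack()].
#' @param A Nonnegative penalty constant; `A = 0` leaves the mean
#'   untouched. In practice `A` is chosen on training data, e.g. with
#'   [sweep_penalty()].
#' @param sd_type `"population"` (divide by the number of models; the
#'   ensemble is the full model set) or `"sample"`.
#' @return A list of class `fused_map` with per-class 2D maps `p_mean`,
#'   `p_sigma`, `p_tilde` (arrays indexed `(class, y, x)`), `A`,
#'   `class_names` and `mpp`.
#' @export
fuse_ensemble <- function(stack, A, sd_type = c("population", "sample")) {
  stopifnot(inherits(stack, "prob_stack"))
  sd_type <- match.arg(sd_type)
  if (!is.numeric(A) || length(A) != 1L || A < 0) {
    stop("`A` must be a single nonnegative number", call. = FALSE)
  }
  d <- dim(stack$maps)
  M <- d[1L]
  if (M < 2L) stop("sigma is undefined for a single-model stack", call. = FALSE)
  flat <- matrix(stack$maps, nrow = M)    # models x (class*y*x)
  m1 <- colMeans(flat)
  m2 <- colMeans(flat^2)
  v <- pmax(m2 - m1^2, 0)
  if (sd_type == "sample") v <- v * M / (M - 1)
  p_mean <- array(m1, d[-1L])
  p_sigma <- array(sqrt(v), d[-1L])
  p_tilde <- pmax(p_mean - A * p_sigma, 0)
  structure(list(p_mean = p_mean, p_sigma = p_sigma, p_tilde = p_tilde,
                 A = A, class_names = stack$class_names, mpp = stack$mpp),
            class = "fused_map")
}

#' Extract tissue instances from a fused map by min-cut
#'
#' Binarises the corrected map `p_tilde` of one class by solving a
#' two-label max-flow/min-cut problem: unary costs are the negative
#' log-odds (`-log p` for foreground, `-log(1 - p)` for background, with
#' probabilities clamped to `[eps, 1 - eps]`) and the pairwise term is a
#' Potts penalty of weight `smoothness` on the 4-neighbour grid.
#' Foreground pixels are grouped into 8-connected components; components
#' smaller than `min_area_px` are discarded. At `smoothness = 0` the cut
#' is equivalent to thresholding `p_tilde` at 0.5.
#'
#' @param fused A [fuse_ensemble()] result.
#' @param class_label One of `fused$class_names`.
#' @param min_area_px Minimum component area in pixels (default 32,
#'   appropriate at 0.44 microns per pixel).
#' @param smoothness Nonnegative Potts weight.
#' @param eps Probability clamp.
#' @return A list of `tissue_instance` objects (fields `instance_id`,
#'   `class_label`, `mask`); empty when no foreground survives.
#' @export
extract_instances <- function(fused, class_label, min_area_px = 32L,
                              smoothness = 0, eps = 1e-6) {
  stopifnot(inherits(fused, "fused_map"))
  if (!class_label %in% fused$class_names) {
    stop("unknown class '", class_label, "'", call. = FALSE)
  }
  if (min_area_px < 1L) stop("`min_area_px` must be >= 1", call. = FALSE)
  if (smoothness < 0) stop("`smoothness` must be >= 0", call. = FALSE)
  ci <- match(class_label, fused$class_names)
  p <- fused$p_tilde[ci, , ]
  if (!is.matrix(p)) p <- matrix(p, dim(fused$p_tilde)[2L], dim(fused$p_tilde)[3L])
  fg <- mincut_binarise(p, smoothness, eps)
  if (!any(fg)) return(list())
  lab <- label_components(fg, connectivity = 8L)
  out <- list()
  for (k in seq_len(max(lab))) {
    m <- lab == k
    if (sum(m) < min_area_px) next
    out[[length(out) + 1L]] <- structure(
      list(instance_id = length(out) + 1L, class_label = class_label, mask = m),
      class = "tissue_instance")
  }
  out
}

# Min-cut binarisation of a probability map. Source side = foreground.
# t-links: source -> pixel with capacity -log(1-p) (cost of calling it
# background), pixel -> sink with capacity -log(p); n-links: Potts weight
# on the 4-neighbour grid, both directions.
#
# Exact decided-pixel reduction for large maps: a pixel whose unary
# log-odds margin exceeds 4*smoothness (the largest possible total
# neighbour influence) keeps its unary-preferred label in every optimal
# labelling, so the flow problem only needs the ambiguous pixels, with
# fixed neighbours folded into their t-links. Small maps solve the full
# graph.
mincut_binarise <- function(p, smoothness, eps = 1e-6,
                            reduce_over = 4096L) {
  stopifnot(is.matrix(p))
  p <- pmin(pmax(p, eps), 1 - eps)
  H <- nrow(p); W <- ncol(p); N <- H * W
  margin <- log(p) - log(1 - p)        # >0 prefers foreground
  if (N > reduce_over) {
    free <- abs(margin) <= 4 * smoothness + 1e-12
  } else {
    free <- matrix(TRUE, H, W)
  }
  fg <- margin > 0                     # start from unary labels
  nf <- sum(free)
  if (nf == 0L) return(fg)
  ids <- which(free)                   # column-major pixel ids of free set
  node <- integer(N); node[ids] <- seq_len(nf)
  src <- nf + 1L; snk <- nf + 2L
  cap_bg <- -log(1 - as.vector(p))[ids]   # cut when labelled background
  cap_fg <- -log(as.vector(p))[ids]       # cut when labelled foreground
  e_from <- integer(0); e_to <- integer(0); e_cap <- numeric(0)
  if (smoothness > 0) {
    y <- ((ids - 1L) %% H) + 1L
    x <- ((ids - 1L) %/% H) + 1L
    for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      ny <- y + o[1L]; nx <- x + o[2L]
      ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
      nid <- (nx[ok] - 1L) * H + ny[ok]
      i_free <- node[ids[ok]]
      j_node <- node[nid]
      is_free <- j_node > 0L
      # free-free links once per unordered pair (from the first two offsets)
      if (identical(o, c(1L, 0L)) || identical(o, c(0L, 1L))) {
        ff_i <- i_free[is_free]; ff_j <- j_node[is_free]
        e_from <- c(e_from, ff_i, ff_j)
        e_to <- c(e_to, ff_j, ff_i)
        e_cap <- c(e_cap, rep(smoothness, 2L * length(ff_i)))
      }
      # fixed neighbours act as unary terms
      fixed_fg <- !is_free & fg[nid]
      fixed_bg <- !is_free & !fg[nid]
      if (any(fixed_fg)) {
        t1 <- tapply(rep(smoothness, sum(fixed_fg)), i_free[fixed_fg], sum)
        cap_bg[as.integer(names(t1))] <- cap_bg[as.integer(names(t1))] + t1
      }
      if (any(fixed_bg)) {
        t2 <- tapply(rep(smoothness, sum(fixed_bg)), i_free[fixed_bg], sum)
        cap_fg[as.integer(names(t2))] <- cap_fg[as.integer(names(t2))] + t2
      }
    }
  }
  from <- c(rep(src, nf), seq_len(nf), e_from)
  to <- c(seq_len(nf), rep(snk, nf), e_to)
  cap <- c(cap_bg, cap_fg, e_cap)
  g <- igraph::make_graph(edges = rbind(from, to), n = nf + 2L, directed = TRUE)
  mf <- igraph::max_flow(g, source = src, target = snk, capacity = cap)
  part <- as.integer(mf$partition1)
  fg[ids] <- FALSE
  fg[ids[part[part <= nf]]] <- TRUE
  fg
}

# Per-slide quality-weight rule on squared disagreement means:
# g_k = (max_j s_j^2 - s_k^2) / (max_j s_j^2 - min_j s_j^2), all 1 when
# the denominator degenerates (equal evidence quality should not
# down-weight anyone).
quality_weight_rule <- function(s) {
  s2 <- s^2
  lo <- min(s2); hi <- max(s2)
  if (hi - lo <= .Machine$double.eps * max(1, hi)) return(rep(1, length(s)))
  (hi - s2) / (hi - lo)
}

#' Per-instance segmentation quality weights
#'
#' For each instance `k` of a slide, `s_k` is the mean of the ensemble
#' standard deviation map over the instance mask; the quality weight is
#' `g_k = (max_j s_j^2 - s_k^2) / (max_j s_j^2 - min_j s_j^2)`, so the
#' most consistently segmented instance in the slide gets weight 1 and the
#' most contentious gets 0. When all `s_j^2` are equal (including a
#' single-instance slide) every weight is 1. The max/min run over the
#' instances supplied, i.e. per slide.
#'
#' @param instances List of `tissue_instance` objects (from
#'   [extract_instances()]), each with a nonempty mask.
#' @param p_sigma 2D ensemble standard deviation map for the instances'
#'   class (from [fuse_ensemble()], one class slice).
#' @return The same list with `s2` (squared mean sigma) and `g` filled in.
#' @export
compute_quality_weights <- function(instances, p_sigma) {
  if (length(instances) == 0L) stop("need >= 1 instance", call. = FALSE)
  stopifnot(is.matrix(p_sigma))
  s <- vapply(seq_along(instances), function(k) {
    m <- instances[[k]]$mask
    if (!any(m)) stop("instance ", k, " has an empty mask", call. = FALSE)
    mean(p_sigma[m])
  }, numeric(1))
  g <- quality_weight_rule(s)
  for (k in seq_along(instances)) {
    instances[[k]]$s2 <- s[k]^2
    instances[[k]]$g <- g[k]
  }
  instances
}

#' Crop one tissue instance with physical padding and outside blurring
#'
#' The crop bounds are the mask bounding box expanded by
#' `round(pad_um / mpp)` pixels per side (1.32 um at 0.44 mpp gives 3 px),
#' clipped to the image. Pixels outside the mask are replaced by a
#' Gaussian-blurred copy of the image — the blur is computed before
#' masking so out-of-tissue structure cannot leak sharp detail into later
#' feature extraction — while pixels inside the mask are untouched.
#' Instances touching the image border are clipped and flagged truncated,
#' not rejected (biopsies keep their truncated tissues).
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param instance A `tissue_instance` whose mask lies within the image.
#' @param pad_um Physical padding per side in microns (default 1.32).
#' @param mpp Microns per pixel.
#' @param blur_sigma_px Gaussian sigma of the outside blur (default 8 px).
#' @return The instance with fields `crop` (RGB array), `crop_mask`
#'   (mask restricted to the crop), `bbox` (0-based, half-open
#'   `c(y0, y1, x0, x1)` in slide coordinates) and `truncated` added.
#' @export
crop_instance <- function(image, instance, pad_um = 1.32, mpp,
                          blur_sigma_px = 8) {
  stopifnot(length(dim(image)) == 3L, inherits(instance, "tissue_instance"))
  if (pad_um < 0) stop("`pad_um` must be >= 0", call. = FALSE)
  if (missing(mpp) || mpp <= 0) stop("`mpp` must be positive", call. = FALSE)
  mask <- instance$mask
  if (!all(dim(mask) == dim(image)[1:2])) {
    stop("instance mask does not match the image", call. = FALSE)
  }
  pad <- as.integer(round(pad_um / mpp))
  bb <- mask_bbox(mask)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  y0 <- bb[1L] - pad; y1 <- bb[2L] + pad
  x0 <- bb[3L] - pad; x1 <- bb[4L] + pad
  truncated <- y0 < 0 || x0 < 0 || y1 > H || x1 > W
  y0 <- max(y0, 0L); x0 <- max(x0, 0L); y1 <- min(y1, H); x1 <- min(x1, W)
  ys <- (y0 + 1L):y1; xs <- (x0 + 1L):x1
  # blur a margin-expanded window so the crop sees the same blur it would
  # under whole-image blurring
  m <- as.integer(ceiling(3 * blur_sigma_px))
  wy <- max(y0 + 1L - m, 1L):min(y1 + m, H)
  wx <- max(x0 + 1L - m, 1L):min(x1 + m, W)
  blurred <- blur_raster(image[wy, wx, , drop = FALSE], blur_sigma_px)
  crop <- blurred[match(ys, wy), match(xs, wx), , drop = FALSE]
  cm <- mask[ys, xs, drop = FALSE]
  for (k in 1:3) {
    ch <- crop[, , k]; orig <- image[ys, xs, k]
    ch[cm] <- orig[cm]
    crop[, , k] <- ch
  }
  instance$crop <- crop
  instance$crop_mask <- cm
  instance$bbox <- c(y0, y1, x0, x1)
  instance$truncated <- truncated
  instance
}

#' Choose the fusion penalty constant on validation slides
#'
#' Sweeps candidate values of `A` and returns the one maximising the mean
#' instance-level Jaccard index between extracted and ground-truth masks,
#' standing in for choosing the penalty empirically from training data.
#'
#' @param slides List of [synth_slide()] results with ground truth.
#' @param stacks Matching list of [synth_stack()] results.
#' @param A_grid Candidate penalties.
#' @param class_label Class to score.
#' @param ... Passed to [extract_instances()].
#' @return A tibble (`A`, `mean_jaccard`) with the best row first;
#'   the chosen `A` in `attr(, "best_A")`.
#' @export
sweep_penalty <- function(slides, stacks, A_grid = c(0, 0.5, 1, 2),
                          class_label = "tubule", ...) {
  stopifnot(length(slides) == length(stacks))
  score_one <- function(A) {
    js <- c()
    for (i in seq_along(slides)) {
      fused <- fuse_ensemble(stacks[[i]], A)
      found <- extract_instances(fused, class_label, ...)
      gt <- Filter(function(z) z$class_label == class_label, slides[[i]]$instances)
      for (g in gt) {
        best <- 0
        for (f in found) {
          inter <- sum(g$mask & f$mask)
          uni <- sum(g$mask | f$mask)
          if (uni > 0) best <- max(best, inter / uni)
        }
        js <- c(js, best)
      }
    }
    if (length(js) == 0L) 0 else mean(js)
  }
  res <- tibble::tibble(A = A_grid,
                        mean_jaccard = vapply(A_grid, score_one, numeric(1)))
  res <- dplyr::arrange(res, dplyr::desc(.data$mean_jaccard))
  attr(res, "best_A") <- res$A[1L]
  res
}

#' Export instances as a polygon record table
#'
#' One record per instance with class, quality weight, squared
#' disagreement, bounding box and the mask outline as a coordinate list
#' (GeoJSON-style ring), written as JSON.
#'
#' @param instances List of `tissue_instance` objects.
#' @param path File to write.
#' @return Invisibly, `path`.
#' @export
write_instances <- function(instances, path) {
  recs <- lapply(instances, function(ins) {
    bb <- if (!is.null(ins$bbox)) ins$bbox else mask_bbox(ins$mask)
    edge <- ins$mask & !erode_mask(ins$mask, 1)
    idx <- which(edge, arr.ind = TRUE)
    list(instance_id = ins$instance_id, class_label = ins$class_label,
         g = ins$g, s2 = ins$s2, bbox = bb,
         outline = list(x = idx[, 2L], y = idx[, 1L]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
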