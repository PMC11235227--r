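#' Probability stack container
#'
#' Per-model, per-class 2D probability maps for one slide region, with the
#' physical pixel scale. This is the interchange format consumed by
#' [fuse_ensemble()]; it can hold output from any segmentation ensemble.
#'
#' @param maps 4D array indexed `(model, class, y, x)` with values in
#'   `[0, 1]`.
#' @param class_names Character vector naming the class axis.
#' @param mpp Microns per pixel.
#' @return A list of class `prob_stack`.
#' @export
prob_stack <- function(maps, class_names, mpp) {
  stopifnot(is.array(maps), length(dim(maps)) == 4L)
  if (dim(maps)[1L] < 2L) stop("a probability stack needs >= 2 models", call. = FALSE)
  if (dim(maps)[2L] != length(class_names)) {
    stop("`class_names` length must match the class axis", call. = FALSE)
  }
  if (min(maps) < 0 || max(maps) > 1) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (!is.numeric(mpp) || mpp <= 0) stop("`mpp` must be positive", call. = FALSE)
  structure(list(maps = maps, class_names = class_names, mpp = mpp),
            class = "prob_stack")
}

#' Simulate an ensemble probability stack for a synthetic slide
#'
#' Emulates the behaviour of a segmentation ensemble: each model's map for
#' a class is the ground-truth indicator smoothed with a Gaussian
#' (`smooth_sigma`, default 1 px, so maps are soft like network outputs)
#' plus model-specific noise whose amplitude over each instance follows the
#' requested `disagreement`, clipped to `[0, 1]`. Optionally injects
#' false-positive blobs present in only a subset of models, mimicking
#' single-model hallucinations that ensemble averaging suppresses.
#'
#' @param slide A [synth_slide()] result.
#' @param n_models Number of ensemble members (>= 2).
#' @param disagreement Noise amplitude; either a scalar applied to every
#'   instance or a vector with one value per instance of the slide.
#' @param seed Integer seed.
#' @param smooth_sigma Gaussian sigma (px) applied to the ground-truth
#'   indicator before noise.
#' @param noise_sigma Gaussian sigma (px) applied to the noise fields so
#'   disagreement is spatially correlated like real model errors.
#' @param fp_blobs Number of false-positive blobs to inject.
#' @param fp_models How many models see each false-positive blob.
#' @param fp_prob Probability value of an injected blob.
#' @param fp_radius Radius (px) of injected blobs.
#' @param classes Class axis of the output stack.
#' @return A [prob_stack()]; the injected blob geometry is attached as the
#'   `fp_blobs` attribute for tests.
#' @export
synth_stack <- function(slide, n_models, disagreement = 0.1, seed = 1L,
                        smooth_sigma = 1, noise_sigma = 1,
                        fp_blobs = 0L, fp_models = 1L, fp_prob = 0.8,
                        fp_radius = 8,
                        classes = c("tubule", "glomerulus", "vessel", "nucleus")) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (n_models < 2L) stop("`n_models` must be >= 2", call. = FALSE)
  if (any(disagreement < 0)) stop("`disagreement` must be >= 0", call. = FALSE)
  n_inst <- length(slide$instances)
  dis <- if (length(disagreement) == 1L) rep(disagreement, n_inst) else disagreement
  if (n_inst > 0L && length(dis) != n_inst) {
    stop("`disagreement` must be scalar or one value per instance", call. = FALSE)
  }
  H <- dim(slide$image)[1L]; W <- dim(slide$image)[2L]
  with_seed(seed, {
    base <- array(0, c(length(classes), H, W))
    amp <- array(0, c(length(classes), H, W))
    for (ci in seq_along(classes)) {
      ind <- matrix(0, H, W)
      for (j in seq_len(n_inst)) {
        ins <- slide$instances[[j]]
        if (ins$class_label == classes[ci]) {
          ind[ins$mask] <- 1
          a <- amp[ci, , ]
          a[ins$mask] <- pmax(a[ins$mask], dis[j])
          amp[ci, , ] <- a
        }
      }
      base[ci, , ] <- blur_raster(ind, smooth_sigma)
    }
    maps <- array(0, c(n_models, length(classes), H, W))
    for (m in seq_len(n_models)) {
      for (ci in seq_along(classes)) {
        a <- amp[ci, , ]
        if (any(a > 0)) {
          noise <- blur_raster(matrix(stats::rnorm(H * W), H, W), noise_sigma)
          # renormalise so the requested amplitude is the pointwise SD
          if (noise_sigma > 0) noise <- noise / stats::sd(as.vector(noise))
          maps[m, ci, , ] <- base[ci, , ] + a * noise
        } else {
          maps[m, ci, , ] <- base[ci, , ]
        }
      }
    }
    blobs <- list()
    if (fp_blobs > 0L) {
      for (b in seq_len(fp_blobs)) {
        cx <- stats::runif(1, fp_radius + 1, W - fp_radius - 1)
        cy <- stats::runif(1, fp_radius + 1, H - fp_radius - 1)
        ci <- sample.int(length(classes), 1L)
        who <- sample.int(n_models, min(fp_models, n_models))
        bm <- .ellipse_field(H, W, cx, cy, fp_radius, fp_radius) <= 1
        for (m in who) {
          pm <- maps[m, ci, , ]
          pm[bm] <- pmax(pm[bm], fp_prob)
          maps[m, ci, , ] <- pm
        }
        blobs[[b]] <- list(cx = cx, cy = cy, radius = fp_radius,
                           class = classes[ci], models = who, prob = fp_prob,
                           mask = bm)
      }
    }
    maps[maps < 0] <- 0; maps[maps > 1] <- 1
    out <- prob_stack(maps, classes, slide$mpp)
    attr(out, "fp_blobs") <- blobs
    out
  })
}

#' Write and read a probability stack as a multichannel TIFF-style archive
#'
#' Maps are flattened to a plain-text serialisation (JSON header plus a
#' numeric payload) so stacks survive text-only storage; for in-memory use
#' the `prob_stack` object itself is the canonical form.
#'
#' @param stack A `prob_stack`.
#' @param path File path to write.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "prob_stack"))
  obj <- list(dim = dim(stack$maps), class_names = stack$class_names,
              mpp = stack$mpp, values = as.vector(stack$maps))
  jsonlite::write_json(obj, path, digits = 8)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prob_stack(array(obj$values, obj$dim), obj$class_names, obj$mpp)
}
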