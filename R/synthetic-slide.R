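#' Configuration for a synthetic biopsy-like slide
#'
#' Defines the canvas, physical scale and tissue content of a generated
#' slide. Shapes mimic the four coarse renal tissue classes: tubules are
#' rings (annular ellipses with a lumen), glomeruli are capsule rings
#' enclosing a tuft of packed blobs with an empty urinary-space gap,
#' vessels are thick rings with a configurable lumen fraction, and nuclei
#' are small dark disks scattered inside compartments.
#'
#' @param width,height Canvas size in pixels (at least 256 each by default;
#'   smaller canvases are allowed for unit fixtures via `min_canvas`).
#' @param mpp Microns per pixel, strictly positive. Default 0.44, the
#'   working scale of the feature extractor.
#' @param n_tubule,n_glomerulus,n_vessel Number of instances per class.
#' @param tubule_radius,glomerulus_radius,vessel_radius Ranges (min, max)
#'   of the outer radius in pixels.
#' @param tubule_lumen_frac Range of the tubule lumen radius as a fraction
#'   of the outer radius.
#' @param vessel_lumen_frac Range of the vessel lumen radius fraction.
#' @param glomerulus_gap_px Width in pixels of the empty urinary-space gap
#'   between the capsule ring and the tuft.
#' @param glomerulus_ring_px Capsule ring thickness in pixels.
#' @param nuclei_per_compartment Range of nucleus count seeded inside each
#'   tubule ring and glomerular tuft.
#' @param nucleus_radius Range of nucleus radius in pixels.
#' @param texture_sd Standard deviation of the additive background texture.
#' @param min_canvas Minimum allowed canvas side.
#' @return A list of class `slide_config`.
#' @export
slide_config <- function(width = 256L, height = 256L, mpp = 0.44,
                         n_tubule = 3L, n_glomerulus = 1L, n_vessel = 1L,
                         tubule_radius = c(18, 26),
                         tubule_lumen_frac = c(0.35, 0.55),
                         glomerulus_radius = c(32, 44),
                         glomerulus_gap_px = 4,
                         glomerulus_ring_px = 3,
                         vessel_radius = c(22, 32),
                         vessel_lumen_frac = c(0.4, 0.6),
                         nuclei_per_compartment = c(3L, 8L),
                         nucleus_radius = c(2, 3),
                         texture_sd = 0.015,
                         min_canvas = 256L) {
  if (!is.numeric(mpp) || mpp <= 0) stop("`mpp` must be positive", call. = FALSE)
  if (any(c(n_tubule, n_glomerulus, n_vessel) < 0)) {
    stop("class frequencies must be nonnegative", call. = FALSE)
  }
  if (width < min_canvas || height < min_canvas) {
    stop("canvas must be at least ", min_canvas, "x", min_canvas, call. = FALSE)
  }
  structure(as.list(environment()), class = "slide_config")
}

# Parametric boundary polygon of a circle/ellipse, for the manifest.
.ellipse_poly <- function(cx, cy, rx, ry, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + rx * cos(t), y = cy + ry * sin(t))
}

# Squared normalised radius field of an ellipse on the pixel grid.
.ellipse_field <- function(H, W, cx, cy, rx, ry) {
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2
}

#' Generate a synthetic biopsy-like slide
#'
#' Draws the configured tissue compartments on a pale background with a
#' small amount of seeded texture noise, and records a ground-truth binary
#' mask, class label and generative shape parameters for every instance.
#' The shape parameters are sufficient to recompute analytic areas and
#' ratios, which downstream feature extraction is checked against.
#' Generation is a pure function of `(config, seed)`.
#'
#' @param config A [slide_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_slide` with elements `image`
#'   (H x W x 3 array in `[0, 1]`), `mpp`, `instances` (list of
#'   `mask`/`class_label`/`shape_params`), and `seed`.
#' @export
synth_slide <- function(config, seed) {
  stopifnot(inherits(config, "slide_config"))
  with_seed(seed, {
    H <- as.integer(config$height); W <- as.integer(config$width)
    img <- array(0, c(H, W, 3L))
    base <- c(0.94, 0.90, 0.92)
    for (k in 1:3) {
      img[, , k] <- base[k] + matrix(stats::rnorm(H * W, 0, config$texture_sd), H, W)
    }
    instances <- list()

    placed <- matrix(numeric(0), ncol = 3L)  # cx, cy, clearance radius
    place <- function(r) {
      for (try in seq_len(400L)) {
        cx <- stats::runif(1, r + 2, W - r - 2)
        cy <- stats::runif(1, r + 2, H - r - 2)
        if (nrow(placed) == 0L ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                  placed[, 3] + r + 2)) {
          placed <<- rbind(placed, c(cx, cy, r))
          return(c(cx, cy))
        }
      }
      stop("could not fit a shape of radius ", round(r),
           " on the canvas; reduce counts or radii", call. = FALSE)
    }
    paint <- function(mask, col) {
      for (k in 1:3) {
        ch <- img[, , k]
        ch[mask] <- col[k]
        img[, , k] <<- ch
      }
    }
    add_nuclei <- function(region_mask, host_class) {
      n <- sample(seq(config$nuclei_per_compartment[1],
                      config$nuclei_per_compartment[2]), 1L)
      pool <- which(region_mask)
      if (length(pool) == 0L || n == 0L) return(invisible(NULL))
      for (i in seq_len(n)) {
        p <- pool[sample.int(length(pool), 1L)]
        cy <- ((p - 1L) %% H) + 1L
        cx <- ((p - 1L) %/% H) + 1L
        r <- stats::runif(1, config$nucleus_radius[1], config$nucleus_radius[2])
        f <- .ellipse_field(H, W, cx, cy, r, r)
        m <- f <= 1 & region_mask   # keep nuclei inside the host compartment
        if (!any(m)) next
        shade <- stats::runif(1, 0.15, 0.5)  # varying darkness
        paint(m, c(0.30, 0.18, 0.42) * shade + c(0.30, 0.18, 0.42) * 0.5)
        instances[[length(instances) + 1L]] <<- list(
          mask = m, class_label = "nucleus",
          shape_params = list(cx = cx, cy = cy, r = r, darkness = shade,
                              area = pi * r^2,
                              polygon = .ellipse_poly(cx, cy, r, r)))
      }
    }

    for (i in seq_len(config$n_glomerulus)) {
      R <- stats::runif(1, config$glomerulus_radius[1], config$glomerulus_radius[2])
      ctr <- place(R)
      rw <- config$glomerulus_ring_px
      gap <- config$glomerulus_gap_px
      Rt <- R - rw - gap
      if (Rt < 5) stop("glomerulus tuft too small; enlarge radii", call. = FALSE)
      f <- .ellipse_field(H, W, ctr[1], ctr[2], R, R)
      ring <- f <= 1 & f >= ((R - rw) / R)^2
      tuft <- .ellipse_field(H, W, ctr[1], ctr[2], Rt, Rt) <= 1
      paint(ring, c(0.80, 0.55, 0.65))
      paint(tuft, c(0.88, 0.68, 0.74))
      # packed blobs inside the tuft
      nb <- max(4L, round(Rt / 3))
      for (b in seq_len(nb)) {
        a <- stats::runif(1, 0, 2 * pi); rr <- stats::runif(1, 0, Rt * 0.75)
        br <- stats::runif(1, 2.5, 4.5)
        bm <- .ellipse_field(H, W, ctr[1] + rr * cos(a), ctr[2] + rr * sin(a),
                             br, br) <= 1 & tuft
        paint(bm, c(0.74, 0.45, 0.58))
      }
      mask <- ring | tuft
      instances[[length(instances) + 1L]] <- list(
        mask = mask, class_label = "glomerulus",
        shape_params = list(cx = ctr[1], cy = ctr[2], R = R, ring_px = rw,
                            gap_px = gap, tuft_radius = Rt,
                            area = pi * (R^2 - (R - rw)^2) + pi * Rt^2,
                            urinary_space = pi * ((R - rw)^2 - Rt^2),
                            polygon = .ellipse_poly(ctr[1], ctr[2], R, R)))
      add_nuclei(tuft, "glomerulus")
    }

    for (i in seq_len(config$n_vessel)) {
      R <- stats::runif(1, config$vessel_radius[1], config$vessel_radius[2])
      lf <- stats::runif(1, config$vessel_lumen_frac[1], config$vessel_lumen_frac[2])
      r <- R * lf
      ctr <- place(R)
      f <- .ellipse_field(H, W, ctr[1], ctr[2], R, R)
      mask <- f <= 1 & f >= (r / R)^2
      lum <- f < (r / R)^2
      paint(mask, c(0.80, 0.50, 0.60))
      paint(lum, c(0.97, 0.95, 0.96))
      instances[[length(instances) + 1L]] <- list(
        mask = mask, class_label = "vessel",
        shape_params = list(cx = ctr[1], cy = ctr[2], outer_radius = R,
                            lumen_radius = r,
                            area = pi * (R^2 - r^2),
                            lumen_area = pi * r^2,
                            lumen_total_ratio = (r / R)^2,
                            polygon = .ellipse_poly(ctr[1], ctr[2], R, R)))
    }

    for (i in seq_len(config$n_tubule)) {
      rx <- stats::runif(1, config$tubule_radius[1], config$tubule_radius[2])
      ry <- rx * stats::runif(1, 0.7, 1.0)
      lf <- stats::runif(1, config$tubule_lumen_frac[1], config$tubule_lumen_frac[2])
      ctr <- place(max(rx, ry))
      f <- .ellipse_field(H, W, ctr[1], ctr[2], rx, ry)
      mask <- f <= 1 & f >= lf^2
      lum <- f < lf^2
      paint(mask, c(0.85, 0.60, 0.70))
      paint(lum, c(0.97, 0.95, 0.96))
      instances[[length(instances) + 1L]] <- list(
        mask = mask, class_label = "tubule",
        shape_params = list(cx = ctr[1], cy = ctr[2], rx = rx, ry = ry,
                            lumen_frac = lf,
                            area = pi * rx * ry * (1 - lf^2),
                            lumen_area = pi * rx * ry * lf^2,
                            polygon = .ellipse_poly(ctr[1], ctr[2], rx, ry)))
      add_nuclei(mask, "tubule")
    }

    img[img < 0] <- 0; img[img > 1] <- 1
    structure(list(image = img, mpp = config$mpp, instances = instances,
                   seed = as.integer(seed), config = config),
              class = "synthetic_slide")
  })
}

#' Write a synthetic slide to disk
#'
#' Stores the image as PNG plus a JSON sidecar manifest holding the scale,
#' seed and per-instance class labels, shape parameters and boundary
#' polygons (coordinate lists).
#'
#' @param slide A `synthetic_slide`.
#' @param path Directory to write into (created if needed).
#' @param name Basename for the two files.
#' @return Invisibly, the manifest path.
#' @export
write_slide <- function(slide, path, name = "slide") {
  stopifnot(inherits(slide, "synthetic_slide"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(slide$image, file.path(path, paste0(name, ".png")))
  manifest <- list(
    mpp = slide$mpp, seed = slide$seed,
    instances = lapply(slide$instances, function(ins) {
      sp <- ins$shape_params
      poly <- sp$polygon
      sp$polygon <- NULL
      list(class_label = ins$class_label, shape_params = sp,
           polygon = list(x = poly$x, y = poly$y))
    }))
  mp <- file.path(path, paste0(name, ".json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
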