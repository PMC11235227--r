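#' Feature schema for a stain profile
#'
#' The handcrafted feature set covers every feature family used for
#' tissue-compartment description: morphology (areas, ratios,
#' cavity/lumen geometry, urinary-space analogue), colour statistics
#' inside the compartment, second-order boundary-vs-interior colour
#' contrasts, texture (gradient statistics), nuclei distribution and
#' darkness pooled at every tenth percentile, and slide-level context
#' (total biopsy area). Sirius Red (`SR`) excludes the nuclei group
#' because nuclei are not visible under that stain.
#'
#' @param stain_profile `"PAS"` or `"SR"`.
#' @param percentiles `"0-100"` (11 values, every tenth percentile
#'   inclusive) or `"10-90"` (9 values).
#' @return A tibble (`name`, `group`) of class `feature_schema`, with the
#'   profile and percentile grid as attributes.
#' @export
feature_schema <- function(stain_profile = c("PAS", "SR"),
                           percentiles = c("0-100", "10-90")) {
  stain_profile <- match.arg(stain_profile)
  percentiles <- match.arg(percentiles)
  probs <- if (percentiles == "0-100") seq(0, 1, 0.1) else seq(0.1, 0.9, 0.1)
  ptag <- paste0("p", round(probs * 100))
  rows <- list(
    tibble::tibble(name = c("area_um2", "perimeter_um", "eccentricity",
                            "solidity", "lumen_area_um2", "lumen_total_ratio",
                            "urinary_space_um2"),
                   group = "morphology"),
    tibble::tibble(name = c("mean_R", "mean_G", "mean_B",
                            "sd_R", "sd_G", "sd_B",
                            "edge_contrast_R", "edge_contrast_G", "edge_contrast_B"),
                   group = "colour"),
    tibble::tibble(name = c("grad_mean", "grad_sd"), group = "texture"))
  if (stain_profile == "PAS") {
    rows <- c(rows, list(
      tibble::tibble(name = c("n_nuclei", "nuclei_density",
                              paste0("nuc_darkness_", ptag),
                              paste0("nuc_borderdist_", ptag)),
                     group = "nuclei")))
  }
  rows <- c(rows, list(
    tibble::tibble(name = "total_biopsy_area_um2", group = "slide_level")))
  out <- dplyr::bind_rows(rows)
  stopifnot(!anyDuplicated(out$name))
  structure(out, class = c("feature_schema", class(out)),
            stain_profile = stain_profile, percentile_probs = probs)
}

# Eccentricity from central moments of the mask.
.mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1L]; x <- idx[, 2L]
  mu20 <- stats::var(x) * (length(x) - 1) / length(x)
  mu02 <- stats::var(y) * (length(y) - 1) / length(y)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(1 - l2 / l1, 0))
}

# Enclosed background cavities ("lumen"): background components of the
# padded mask window, 4-connected (complement convention of 8-connected
# foreground), that do not touch the window border.
.cavity_mask <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(FALSE, H + 2L, W + 2L)
  padded[2:(H + 1L), 2:(W + 1L)] <- mask
  bg <- label_components(!padded, connectivity = 4L)
  border_labels <- unique(c(bg[1L, ], bg[H + 2L, ], bg[, 1L], bg[, W + 2L]))
  hole <- bg > 0 & !(bg %in% border_labels)
  hole[2:(H + 1L), 2:(W + 1L), drop = FALSE]
}

# Boundary-pixel count scaled by mpp: crude but translation-invariant.
.mask_perimeter_px <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  inner <- mask &
    rbind(FALSE, mask[-H, , drop = FALSE]) &
    rbind(mask[-1L, , drop = FALSE], FALSE) &
    cbind(FALSE, mask[, -W, drop = FALSE]) &
    cbind(mask[, -1L, drop = FALSE], FALSE)
  sum(mask & !inner)
}

#' Handcrafted features for one tissue instance
#'
#' Computes the full handcrafted record for a padded, outside-blurred crop
#' and its mask: morphology (area in square microns, perimeter,
#' eccentricity, solidity, enclosed-cavity "lumen" area found as
#' background holes inside the mask, lumen-to-total *area* ratio — a
#' ratio of areas rather than diameters so no geometric template is
#' fitted — and the urinary-space analogue, convex-hull area minus mask
#' area); colour (per-channel mean/SD inside the compartment and the
#' boundary-band minus interior colour contrast, a second-order statistic
#' of how colour is distributed with respect to the compartment); texture
#' (gradient-magnitude mean/SD inside the mask); nuclei (count, count
#' density, and nucleus darkness and nucleus-to-boundary distances each
#' pooled at every tenth percentile — darker nuclei and
#' boundary-distant nuclei are injury-relevant); and the slide-level
#' total biopsy area appended to every instance. Nuclei features are
#' *missing* (`NA`), not zero, when `nuclei_masks` is empty; under the SR
#' profile the nuclei group is absent entirely.
#'
#' @param crop H x W x 3 array (an instance crop).
#' @param mask Logical H x W matrix, nonempty, in crop coordinates.
#' @param nuclei_masks List of logical H x W matrices, possibly empty.
#' @param slide_context List with `total_area_um2` (and optionally
#'   `tissue_counts`).
#' @param mpp Microns per pixel.
#' @param schema A [feature_schema()].
#' @param boundary_px Erosion depth of the boundary band (default 3 px at
#'   0.44 mpp).
#' @return A one-row tibble following the schema column order.
#' @export
handcrafted_features <- function(crop, mask, nuclei_masks = list(),
                                 slide_context = list(total_area_um2 = NA_real_),
                                 mpp, schema = feature_schema("PAS"),
                                 boundary_px = 3L) {
  stopifnot(length(dim(crop)) == 3L, is.matrix(mask))
  if (!any(mask)) stop("mask has zero area", call. = FALSE)
  if (missing(mpp) || mpp <= 0) stop("`mpp` must be positive", call. = FALSE)
  probs <- attr(schema, "percentile_probs")
  area_px <- sum(mask)
  hole <- .cavity_mask(mask)
  lumen_px <- sum(hole)
  hull_px <- chull_area(mask)
  vals <- list(
    area_um2 = area_px * mpp^2,
    perimeter_um = .mask_perimeter_px(mask) * mpp,
    eccentricity = .mask_eccentricity(mask),
    solidity = area_px / max(hull_px, 1e-12),
    lumen_area_um2 = lumen_px * mpp^2,
    lumen_total_ratio = lumen_px / (lumen_px + area_px),
    urinary_space_um2 = max(hull_px - area_px - lumen_px, 0) * mpp^2)

  lum <- luminance(crop)
  for (k in 1:3) {
    ch <- crop[, , k][mask]
    vals[[paste0("mean_", c("R", "G", "B")[k])]] <- mean(ch)
    vals[[paste0("sd_", c("R", "G", "B")[k])]] <- stats::sd(ch)
  }
  interior <- erode_mask(mask, boundary_px)
  band <- mask & !interior
  for (k in 1:3) {
    ch <- crop[, , k]
    contrast <- if (any(band) && any(interior)) {
      mean(ch[band]) - mean(ch[interior])
    } else 0
    vals[[paste0("edge_contrast_", c("R", "G", "B")[k])]] <- contrast
  }
  gy <- rbind(lum[2L, , drop = FALSE], lum[-1L, , drop = FALSE]) -
    rbind(lum[1L, , drop = FALSE], lum[-nrow(lum), , drop = FALSE])
  gx <- cbind(lum[, 2L, drop = FALSE], lum[, -1L, drop = FALSE]) -
    cbind(lum[, 1L, drop = FALSE], lum[, -ncol(lum), drop = FALSE])
  gmag <- sqrt(gx^2 + gy^2)[mask]
  vals$grad_mean <- mean(gmag)
  vals$grad_sd <- if (length(gmag) > 1L) stats::sd(gmag) else 0

  if (attr(schema, "stain_profile") == "PAS") {
    ptag <- paste0("p", round(probs * 100))
    if (length(nuclei_masks) == 0L) {
      vals$n_nuclei <- NA_real_
      vals$nuclei_density <- NA_real_
      for (t in ptag) {
        vals[[paste0("nuc_darkness_", t)]] <- NA_real_
        vals[[paste0("nuc_borderdist_", t)]] <- NA_real_
      }
    } else {
      dist <- EBImage::distmap(mask * 1)   # distance to background
      darkness <- vapply(nuclei_masks, function(nm) {
        if (!any(nm)) return(NA_real_)
        mean(lum[nm])
      }, numeric(1))
      borderdist <- vapply(nuclei_masks, function(nm) {
        idx <- which(nm, arr.ind = TRUE)
        if (nrow(idx) == 0L) return(NA_real_)
        cy <- round(mean(idx[, 1L])); cx <- round(mean(idx[, 2L]))
        cy <- min(max(cy, 1L), nrow(mask)); cx <- min(max(cx, 1L), ncol(mask))
        dist[cy, cx] * mpp
      }, numeric(1))
      darkness <- darkness[!is.na(darkness)]
      borderdist <- borderdist[!is.na(borderdist)]
      vals$n_nuclei <- length(nuclei_masks)
      vals$nuclei_density <- length(nuclei_masks) / vals$area_um2
      qd <- stats::quantile(darkness, probs, names = FALSE, type = 7)
      qb <- stats::quantile(borderdist, probs, names = FALSE, type = 7)
      for (i in seq_along(ptag)) {
        vals[[paste0("nuc_darkness_", ptag[i])]] <- qd[i]
        vals[[paste0("nuc_borderdist_", ptag[i])]] <- qb[i]
      }
    }
  }
  vals$total_biopsy_area_um2 <- slide_context$total_area_um2
  out <- tibble::as_tibble(vals)
  out[, schema$name]
}

#' Deep features by spatial average pooling at native size
#'
#' Feeds the crop to a pluggable image-embedding extractor at its native
#' size — no resizing, so objects of equal physical size elicit equal
#' filter responses — and average-pools the extractor's spatial feature
#' map over space into one fixed-length vector. Crops smaller than the
#' extractor's minimum input are padded reflectively and flagged.
#'
#' @param crop H x W x 3 array.
#' @param extractor Function mapping such an array to a spatial feature
#'   map (H' x W' x F array). May carry a `min_size` attribute. The
#'   default [identity_extractor()] returns the input itself, giving the
#'   per-channel spatial means.
#' @return Numeric vector of length F, with attribute `padded` when
#'   reflective padding was applied.
#' @export
deep_features <- function(crop, extractor = identity_extractor()) {
  stopifnot(length(dim(crop)) == 3L)
  min_size <- attr(extractor, "min_size")
  padded <- FALSE
  if (!is.null(min_size) &&
      (dim(crop)[1L] < min_size || dim(crop)[2L] < min_size)) {
    crop <- reflect_pad(crop, min_size)
    padded <- TRUE
  }
  fm <- extractor(crop)
  if (is.matrix(fm)) fm <- array(fm, c(dim(fm), 1L))
  stopifnot(length(dim(fm)) == 3L)
  v <- apply(fm, 3L, mean)
  attr(v, "padded") <- padded
  v
}

#' @rdname deep_features
#' @export
identity_extractor <- function() {
  f <- function(crop) crop
  attr(f, "min_size") <- 1L
  f
}

# Reflect-pad an H x W x C array to at least `size` per side.
reflect_pad <- function(x, size) {
  H <- dim(x)[1L]; W <- dim(x)[2L]
  refl <- function(n, target) {
    if (n >= target) return(seq_len(n))
    idx <- seq_len(n)
    while (length(idx) < target) idx <- c(idx, rev(idx))
    idx[seq_len(target)]
  }
  x[refl(H, max(H, size)), refl(W, max(W, size)), , drop = FALSE]
}

#' Fit imputation and normalisation statistics on a training split
#'
#' Missing values are imputed with the per-feature training mean and every
#' feature is normalised to zero mean and unit variance; both sets of
#' statistics are fitted on the training split only and applied unchanged
#' to validation/test data, guarding against leakage. A `scope = "global"`
#' mode reproduces pooling statistics over all rows passed in, for
#' comparison. Constant features are flagged and pass through as zeros
#' after centring.
#'
#' @param train A feature tibble; non-numeric columns (`bag_id`,
#'   `instance_id`, `role`, ...) are carried through untouched.
#' @param scope `"train"` (default) or `"global"` (statistics are then
#'   whatever rows were supplied, caller's responsibility).
#' @param sd_type Population (`n` denominator) or sample SD.
#' @return An object of class `feature_stats`.
#' @export
fit_feature_stats <- function(train, scope = c("train", "global"),
                              sd_type = c("population", "sample")) {
  scope <- match.arg(scope); sd_type <- match.arg(sd_type)
  if (nrow(train) == 0L) stop("training matrix is empty", call. = FALSE)
  num <- names(train)[vapply(train, is.numeric, logical(1))]
  num <- setdiff(num, c("bag_id", "instance_id", "label"))
  mu <- sds <- stats::setNames(numeric(length(num)), num)
  for (f in num) {
    v <- train[[f]]
    if (all(is.na(v))) stop("feature '", f, "' entirely missing in training",
                            call. = FALSE)
    v <- v[!is.na(v)]
    mu[f] <- mean(v)
    s <- if (sd_type == "population") {
      sqrt(mean((v - mean(v))^2))
    } else stats::sd(v)
    sds[f] <- if (is.na(s)) 0 else s
  }
  structure(list(mean = mu, sd = sds, features = num,
                 constant = num[sds <= 0], scope = scope, sd_type = sd_type),
            class = "feature_stats")
}

#' @rdname fit_feature_stats
#' @param stats A fitted `feature_stats`.
#' @param data Any feature tibble with the same feature columns.
#' @return `apply_feature_stats()`: the tibble with features imputed and
#'   normalised; constant features become exact zeros.
#' @export
apply_feature_stats <- function(stats, data) {
  stopifnot(inherits(stats, "feature_stats"))
  for (f in stats$features) {
    v <- data[[f]]
    v[is.na(v)] <- stats$mean[[f]]
    v <- if (f %in% stats$constant) rep(0, length(v)) else
      (v - stats$mean[[f]]) / stats$sd[[f]]
    data[[f]] <- unname(v)
  }
  data
}

#' Assemble the final per-instance feature set
#'
#' Column-wise concatenation of handcrafted and deep feature tables keyed
#' by `(bag_id, instance_id)`, optionally appending the segmentation
#' quality weight `g` as one extra feature column.
#'
#' @param handcrafted Tibble with key columns `bag_id`, `instance_id`.
#' @param deep Optional tibble with the same keys; `NULL` or zero-column
#'   for none.
#' @param g Optional tibble (`bag_id`, `instance_id`, `g`).
#' @param include_g Append `g` as a feature column.
#' @return A tibble; the provenance of every feature column is recorded in
#'   the `provenance` attribute.
#' @export
assemble_featureset <- function(handcrafted, deep = NULL, g = NULL,
                                include_g = FALSE) {
  keys <- c("bag_id", "instance_id")
  stopifnot(all(keys %in% names(handcrafted)))
  out <- handcrafted
  prov <- stats::setNames(rep("handcrafted", ncol(handcrafted)), names(handcrafted))
  join_checked <- function(a, b, what) {
    ka <- do.call(paste, a[keys]); kb <- do.call(paste, b[keys])
    if (!setequal(ka, kb) || length(ka) != length(kb)) {
      diff <- c(setdiff(ka, kb), setdiff(kb, ka))
      stop("instance keys mismatch with ", what, ": ",
           paste(utils::head(diff, 5L), collapse = ", "), call. = FALSE)
    }
    dplyr::inner_join(a, b, by = keys)
  }
  if (!is.null(deep) && ncol(deep) > length(keys)) {
    out <- join_checked(out, deep, "deep features")
    newc <- setdiff(names(out), names(prov))
    prov[newc] <- "deep"
  }
  if (include_g) {
    if (is.null(g)) stop("`include_g = TRUE` needs a `g` table", call. = FALSE)
    out <- join_checked(out, g[, c(keys, "g")], "quality weights")
    prov["g"] <- "quality_weight"
  }
  attr(out, "provenance") <- prov
  out
}
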