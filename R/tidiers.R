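#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a bag set into one instance-level tibble
#'
#' @param x A `bag_set`.
#' @param ... Unused.
#' @return Instances joined with their bag's donor and label.
#' @export
tidy.bag_set <- function(x, ...) {
  dplyr::left_join(x$instances, x$bags, by = "bag_id")
}

#' @export
glance.bag_set <- function(x, ...) {
  tibble::tibble(n_bags = nrow(x$bags), n_instances = nrow(x$instances),
                 n_donors = length(unique(x$bags$donor_id)),
                 n_classes = length(unique(x$bags$label)))
}

#' Tidy a fitted MIL model: one row per parameter
#'
#' @param x A `mil_model`.
#' @param ... Unused.
#' @export
tidy.mil_model <- function(x, ...) {
  purrr::map_dfr(names(x$params), function(nm) {
    p <- x$params[[nm]]
    tibble::tibble(layer = nm, term = seq_along(p), value = as.vector(p))
  })
}

#' @export
glance.mil_model <- function(x, ...) {
  tibble::tibble(model_type = x$config$model_type,
                 gated = x$config$gated,
                 n_classes = x$config$n_classes,
                 n_params = sum(vapply(x$params, length, integer(1))),
                 epochs_run = nrow(x$log),
                 best_epoch = x$best_epoch,
                 best_val_auc = x$best_val_auc)
}

#' @export
tidy.mil_cv <- function(x, ...) x$predictions

#' @export
glance.mil_cv <- function(x, ...) {
  tibble::tibble(n_models = length(x$models), n_folds = x$n_folds,
                 n_seeds = x$n_seeds,
                 n_test_predictions = nrow(x$predictions))
}

#' @export
tidy.weighted_roc <- function(x, ...) x$curve

#' @export
glance.weighted_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, prevalence = x$prevalence)
}

#' @export
tidy.weighted_pr <- function(x, ...) x$curve

#' @export
glance.weighted_pr <- function(x, ...) {
  tibble::tibble(auc = x$auc, prevalence = x$prevalence)
}

#' Plot a weighted ROC curve
#'
#' @param object A `weighted_roc`.
#' @param ... Unused.
#' @export
autoplot.weighted_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#B2182B") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Weighted false positive rate",
                  y = "Weighted true positive rate",
                  title = sprintf("Weighted ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.weighted_pr <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "hv", colour = "#2166AC") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Weighted recall", y = "Weighted precision",
                  title = sprintf("Weighted PR (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bootstrap_bands <- function(object, ...) {
  med <- object$median_curve
  if (object$type == "roc") {
    df <- tibble::tibble(x = med$fpr, y = med$tpr)
    labs <- c("Weighted FPR", "Weighted TPR")
  } else {
    df <- tibble::tibble(x = med$recall, y = med$precision)
    labs <- c("Weighted recall", "Weighted precision")
  }
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = object$band,
                         ggplot2::aes(x = .data$x, ymin = .data$lo,
                                      ymax = .data$hi),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_step(data = df, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "#B2182B") +
    ggplot2::labs(x = labs[1], y = labs[2],
                  title = sprintf("Median AUC = %.3f (range of %d bootstraps)",
                                  object$median_auc, object$n_boot)) +
    ggplot2::theme_minimal()
}

#' Render an overlay figure with ggplot2
#'
#' @param object An `overlay_figure`.
#' @param ... Unused.
#' @export
autoplot.overlay_figure <- function(object, ...) {
  img <- object$image
  H <- dim(img)[1L]; W <- dim(img)[2L]
  rast <- grDevices::rgb(img[, , 1L], img[, , 2L], img[, , 3L])
  dim(rast) <- c(H, W)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(rast, xmin = 0, xmax = W, ymin = -H, ymax = 0) +
    ggplot2::coord_fixed(xlim = c(0, W), ylim = c(-H, 0), expand = FALSE) +
    ggplot2::theme_void()
}

#' Plot the training log of a MIL model
#'
#' @param model A `mil_model`.
#' @export
plot_training <- function(model) {
  stopifnot(inherits(model, "mil_model"))
  df <- tidyr::pivot_longer(model$log, c("train_loss", "val_auc"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal()
}
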