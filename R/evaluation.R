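#' Tissue-count-weighted ROC curve and AUC
#'
#' Each bag (slide) contributes to the true/false-positive accumulators
#' in proportion to its weight — in the intended use, the number of
#' segmented tissues in the slide — which down-weights inadequate
#' biopsies. Bags tied on score step simultaneously; the AUC is the
#' trapezoid area, equal to the weighted pairwise Mann-Whitney statistic
#' with half credit for ties.
#'
#' @param data A data frame of per-bag results.
#' @param truth Column (unquoted) with the true label.
#' @param score Column with the positive-class score.
#' @param weights Column with positive bag weights; omit for equal
#'   weights.
#' @param positive_class Value of `truth` counted as positive.
#' @return An object of class `weighted_roc`: `curve` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `prevalence` (weighted), and the
#'   inputs needed by [optimal_threshold()].
#' @export
weighted_roc <- function(data, truth, score, weights = NULL,
                         positive_class = 1) {
  truth <- rlang::eval_tidy(rlang::enquo(truth), data)
  score <- rlang::eval_tidy(rlang::enquo(score), data)
  wq <- rlang::enquo(weights)
  w <- if (rlang::quo_is_null(wq)) rep(1, length(score)) else rlang::eval_tidy(wq, data)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  pos <- truth == positive_class
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]; ww <- w[ord]
  grp <- cumsum(!duplicated(s))
  tp <- unname(tapply(ww * p, grp, sum))
  fp <- unname(tapply(ww * !p, grp, sum))
  Wp <- sum(ww[p]); Wn <- sum(ww[!p])
  tpr <- c(0, cumsum(tp) / Wp)
  fpr <- c(0, cumsum(fp) / Wn)
  thr <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, prevalence = Wp / (Wp + Wn),
                 W_pos = Wp, W_neg = Wn),
            class = "weighted_roc")
}

#' Tissue-count-weighted precision-recall curve and AUC
#'
#' Weighted precision and recall over a descending threshold sweep; the
#' AUC uses step interpolation with precision held constant to the right
#' of each recall level. With constant scores the curve collapses to a
#' single step and the AUC equals the weighted positive prevalence.
#'
#' @inheritParams weighted_roc
#' @return An object of class `weighted_pr`: `curve` (tibble `threshold`,
#'   `recall`, `precision`), `auc`, `prevalence`.
#' @export
weighted_pr <- function(data, truth, score, weights = NULL,
                        positive_class = 1) {
  truth <- rlang::eval_tidy(rlang::enquo(truth), data)
  score <- rlang::eval_tidy(rlang::enquo(score), data)
  wq <- rlang::enquo(weights)
  w <- if (rlang::quo_is_null(wq)) rep(1, length(score)) else rlang::eval_tidy(wq, data)
  pos <- truth == positive_class
  if (!any(pos)) stop("no positive bags", call. = FALSE)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]; ww <- w[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(unname(tapply(ww * p, grp, sum)))
  fp <- cumsum(unname(tapply(ww * !p, grp, sum)))
  Wp <- sum(ww[p])
  recall <- tp / Wp
  precision <- tp / (tp + fp)
  thr <- s[!duplicated(s)]
  auc <- sum(diff(c(0, recall)) * precision)
  structure(list(curve = tibble::tibble(threshold = thr, recall = recall,
                                        precision = precision),
                 auc = auc, prevalence = Wp / sum(ww)),
            class = "weighted_pr")
}

#' Macro-averaged one-vs-rest weighted AUC
#'
#' For multi-class tasks, one-vs-rest weighted ROC (or PR) AUCs are
#' averaged with equal class weights.
#'
#' @param data Per-bag tibble with one `.pred_<class>` column per class.
#' @param truth,weights Columns as in [weighted_roc()].
#' @param classes Class values; default taken from the `.pred_` columns.
#' @param type `"roc"` or `"pr"`.
#' @return Mean one-vs-rest AUC.
#' @export
macro_weighted_auc <- function(data, truth, weights = NULL, classes = NULL,
                               type = c("roc", "pr")) {
  type <- match.arg(type)
  truth_v <- rlang::eval_tidy(rlang::enquo(truth), data)
  wq <- rlang::enquo(weights)
  w_v <- if (rlang::quo_is_null(wq)) rep(1, nrow(data)) else rlang::eval_tidy(wq, data)
  if (is.null(classes)) {
    classes <- sub("^\\.pred_", "", grep("^\\.pred_", names(data), value = TRUE))
  }
  fun <- if (type == "roc") weighted_roc else weighted_pr
  aucs <- c()
  for (cl in classes) {
    d <- tibble::tibble(y = truth_v == cl, s = data[[paste0(".pred_", cl)]], w = w_v)
    if (!any(d$y) || all(d$y)) next
    aucs <- c(aucs, fun(d, y, s, w, positive_class = TRUE)$auc)
  }
  mean(aucs)
}

#' Aggregate AUCs over folds and seeds, and pool tasks
#'
#' `aggregate_auc()` returns the mean AUC over the fold-by-seed models of
#' one task with its unbiased standard error (sample SD over models
#' divided by the square root of the model count). `combine_tasks()`
#' pools task means: ROC with inverse-variance weights (`1/se^2`; pooled
#' SE `1/sqrt(sum(1/se^2))`) so consistent tasks dominate, PR with the
#' arithmetic mean (pooled SE by error propagation).
#'
#' @param aucs Numeric vector of per-model AUCs (>= 2 values for a
#'   standard error).
#' @return `aggregate_auc()`: tibble `mean`, `se`, `n_models`.
#' @export
aggregate_auc <- function(aucs) {
  aucs <- aucs[!is.na(aucs)]
  n <- length(aucs)
  tibble::tibble(mean = mean(aucs),
                 se = if (n >= 2L) stats::sd(aucs) / sqrt(n) else NA_real_,
                 n_models = n)
}

#' @rdname aggregate_auc
#' @param task_means,task_ses Per-task means and standard errors.
#' @param method `"inverse_variance"` (ROC convention) or `"arithmetic"`
#'   (PR convention).
#' @return `combine_tasks()`: tibble `mean`, `se`, `n_tasks`.
#' @export
combine_tasks <- function(task_means, task_ses,
                          method = c("inverse_variance", "arithmetic")) {
  method <- match.arg(method)
  stopifnot(length(task_means) == length(task_ses), length(task_means) >= 1L)
  if (method == "inverse_variance") {
    if (any(task_ses == 0)) {
      stop("zero standard error with inverse-variance weighting; ",
           "use method = \"arithmetic\"", call. = FALSE)
    }
    wt <- 1 / task_ses^2
    tibble::tibble(mean = sum(wt * task_means) / sum(wt),
                   se = 1 / sqrt(sum(wt)), n_tasks = length(task_means))
  } else {
    n <- length(task_means)
    tibble::tibble(mean = mean(task_means),
                   se = sqrt(sum(task_ses^2)) / n, n_tasks = n)
  }
}

#' Optimal operating threshold of a weighted ROC curve
#'
#' Returns the operating point where the curve touches the maximum
#' iso-accuracy line, i.e. the threshold maximising weighted accuracy
#' `tpr * prev + (1 - fpr) * (1 - prev)` with `prev` the weighted
#' prevalence of the evaluated pool. Ties break towards higher `tpr`.
#'
#' @param roc A [weighted_roc()] object.
#' @return Tibble with `threshold`, `tpr`, `fpr`, `accuracy`.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "weighted_roc"))
  cv <- roc$curve
  acc <- cv$tpr * roc$prevalence + (1 - cv$fpr) * (1 - roc$prevalence)
  best <- which(acc >= max(acc) - 1e-15)
  best <- best[which.max(cv$tpr[best])]
  tibble::tibble(threshold = cv$threshold[best], tpr = cv$tpr[best],
                 fpr = cv$fpr[best], accuracy = acc[best])
}

#' Bootstrap bands for weighted ROC/PR curves
#'
#' Resamples bags with replacement within the test pool, recomputes the
#' weighted curve, and reports the curve with the median AUC as the solid
#' line plus the pointwise min/max range of the resamples as the band.
#' Degenerate resamples missing a class are redrawn (capped retries).
#'
#' @inheritParams weighted_roc
#' @param n_boot Number of bootstrap resamples (default 5).
#' @param type `"roc"` or `"pr"`.
#' @param seed Integer seed.
#' @param max_retries Redraw cap per resample.
#' @return Object of class `bootstrap_bands`: `curves` (list),
#'   `aucs`, `median_auc`, `band` (tibble `x`, `lo`, `hi` on a common
#'   grid), `median_curve`.
#' @export
bootstrap_bands <- function(data, truth, score, weights = NULL,
                            positive_class = 1, n_boot = 5L,
                            type = c("roc", "pr"), seed = 1L,
                            max_retries = 100L) {
  type <- match.arg(type)
  truth_q <- rlang::enquo(truth); score_q <- rlang::enquo(score)
  w_q <- rlang::enquo(weights)
  fun <- function(d) {
    if (type == "roc") {
      weighted_roc(d, !!truth_q, !!score_q, !!w_q, positive_class = positive_class)
    } else {
      weighted_pr(d, !!truth_q, !!score_q, !!w_q, positive_class = positive_class)
    }
  }
  truth_v <- rlang::eval_tidy(truth_q, data)
  curves <- list(); aucs <- numeric(0)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (r in seq_len(max_retries)) {
        idx <- sample.int(nrow(data), nrow(data), replace = TRUE)
        tv <- truth_v[idx]
        if (length(unique(tv == positive_class)) == 2L) break
        if (r == max_retries) stop("could not draw a two-class resample",
                                   call. = FALSE)
      }
      obj <- fun(data[idx, , drop = FALSE])
      curves[[b]] <- obj$curve
      aucs[b] <- obj$auc
    }
  })
  med_i <- order(aucs)[ceiling(length(aucs) / 2)]
  grid <- seq(0, 1, length.out = 101L)
  interp <- function(cv) {
    if (type == "roc") {
      stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y
    } else {
      stats::approx(c(0, cv$recall), c(cv$precision[1L], cv$precision),
                    xout = grid, ties = min, method = "constant",
                    f = 1, rule = 2)$y
    }
  }
  ys <- vapply(curves, interp, numeric(length(grid)))
  band <- tibble::tibble(x = grid,
                         lo = apply(ys, 1L, min), hi = apply(ys, 1L, max))
  structure(list(curves = curves, aucs = aucs, median_auc = aucs[med_i],
                 median_curve = curves[[med_i]], band = band, type = type,
                 n_boot = n_boot),
            class = "bootstrap_bands")
}

#' Build an evaluation report from cross-validation predictions
#'
#' Computes, per prediction task, the tissue-count-weighted ROC and PR
#' AUCs of every fold-by-seed model, their mean and unbiased standard
#' error, the pooled curves and the optimal operating threshold; ROC
#' means across tasks are combined with inverse-variance weighting and PR
#' means with the arithmetic mean.
#'
#' @param predictions Tibble of out-of-fold predictions (from
#'   [mil_crossval()]s `predictions`, one task) with columns `bag_id`,
#'   `label`, `fold`, `seed`, `.pred_*`.
#' @param bags Bag table carrying the evaluation weights.
#' @param weight_col Name of the weight column (default `n_instances`,
#'   the tissue count).
#' @param task Task name recorded in the report.
#' @return Tibble of class `evaluation_report` with one row per task:
#'   ROC/PR mean and SE, macro flag, optimal threshold columns.
#' @export
evaluation_report <- function(predictions, bags, weight_col = "n_instances",
                              task = "task") {
  stopifnot(all(c("fold", "seed", "label") %in% names(predictions)))
  preds <- dplyr::left_join(predictions,
                            bags[, c("bag_id", weight_col)], by = "bag_id")
  preds$.w <- preds[[weight_col]]
  classes <- sub("^\\.pred_", "", grep("^\\.pred_", names(preds), value = TRUE))
  per_model <- preds |>
    dplyr::group_by(.data$fold, .data$seed) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        roc_auc = macro_weighted_auc(d, .data$label, .data$.w,
                                     classes = classes, type = "roc"),
        pr_auc = macro_weighted_auc(d, .data$label, .data$.w,
                                    classes = classes, type = "pr"))
    }) |>
    dplyr::ungroup()
  roc_agg <- aggregate_auc(per_model$roc_auc)
  pr_agg <- aggregate_auc(per_model$pr_auc)
  pos <- classes[length(classes)]
  pooled_roc <- weighted_roc(preds, .data$label, .data[[paste0(".pred_", pos)]],
                             .data$.w, positive_class = pos)
  opt <- optimal_threshold(pooled_roc)
  out <- tibble::tibble(task = task,
                        roc_auc_mean = roc_agg$mean, roc_auc_se = roc_agg$se,
                        pr_auc_mean = pr_agg$mean, pr_auc_se = pr_agg$se,
                        n_models = roc_agg$n_models,
                        opt_threshold = opt$threshold,
                        opt_tpr = opt$tpr, opt_fpr = opt$fpr)
  attr(out, "per_model") <- per_model
  attr(out, "pooled_roc") <- pooled_roc
  class(out) <- c("evaluation_report", class(out))
  out
}
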