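test_that("perfect separation gives AUC 1 and constant scores give 0.5", {
  d <- tibble::tibble(y = c(1, 1, 0, 0), s = c(0.9, 0.8, 0.2, 0.1),
                      w = c(3, 1, 2, 5))
  expect_equal(weighted_roc(d, y, s, w)$auc, 1)
  d2 <- tibble::tibble(y = c(1, 0, 1, 0), s = rep(0.4, 4), w = c(1, 2, 3, 4))
  expect_equal(weighted_roc(d2, y, s, w)$auc, 0.5)
})

test_that("weighted ROC-AUC equals the exhaustive pairwise Mann-Whitney statistic", {
  withr::with_seed(179, {
    for (i in 1:200) {
      n <- sample(3:8, 1)
      y <- sample(c(0, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties happen often
      w <- sample(1:4, n, replace = TRUE)
      d <- tibble::tibble(y = y, s = s, w = w)
      expect_equal(weighted_roc(d, y, s, w)$auc,
                   pairwise_wauc(s, y == 1, w), tolerance = 1e-12)
    }
  })
})

test_that("equal weights reduce the weighted AUC to the unweighted one", {
  withr::with_seed(181, {
    y <- sample(c(0, 1), 40, replace = TRUE)
    s <- round(runif(40), 2)
    d <- tibble::tibble(y = y, s = s, w = rep(2.5, 40))
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(weighted_roc(d, y, s, w)$auc, ref, tolerance = 1e-12)
    expect_equal(weighted_roc(d, y, s)$auc, ref, tolerance = 1e-12)
  })
})

test_that("the ROC is invariant under strictly monotone score transforms", {
  withr::with_seed(191, {
    d <- tibble::tibble(y = sample(c(0, 1), 30, replace = TRUE),
                        s = runif(30), w = sample(1:5, 30, replace = TRUE))
    a <- weighted_roc(d, y, s, w)$auc
    d$s <- exp(3 * d$s) - 1
    expect_equal(weighted_roc(d, y, s, w)$auc, a, tolerance = 1e-12)
  })
})

test_that("weighted PR behaves at the trivial endpoints and matches brute force", {
  d <- tibble::tibble(y = c(1, 1, 0, 0), s = c(0.9, 0.8, 0.2, 0.1),
                      w = c(3, 1, 2, 5))
  expect_equal(weighted_pr(d, y, s, w)$auc, 1)
  d2 <- tibble::tibble(y = c(1, 0, 0, 1), s = rep(0.3, 4), w = c(2, 1, 1, 2))
  expect_equal(weighted_pr(d2, y, s, w)$auc, 4 / 6)  # weighted prevalence
  # brute-force threshold enumeration oracle
  withr::with_seed(193, {
    for (i in 1:50) {
      n <- sample(3:8, 1)
      y <- sample(c(0, 1), n, replace = TRUE)
      if (!any(y == 1)) next
      s <- sample(seq(0, 1, 0.2), n, replace = TRUE)
      w <- sample(1:3, n, replace = TRUE)
      thr <- sort(unique(s), decreasing = TRUE)
      Wp <- sum(w[y == 1])
      rec <- prec <- numeric(length(thr))
      for (j in seq_along(thr)) {
        sel <- s >= thr[j]
        rec[j] <- sum(w[sel & y == 1]) / Wp
        prec[j] <- sum(w[sel & y == 1]) / sum(w[sel])
      }
      oracle <- sum(diff(c(0, rec)) * prec)
      d3 <- tibble::tibble(y = y, s = s, w = w)
      expect_equal(weighted_pr(d3, y, s, w)$auc, oracle, tolerance = 1e-12)
    }
  })
  expect_error(weighted_pr(tibble::tibble(y = c(0, 0), s = c(1, 2)), y, s),
               "no positive")
})

test_that("AUC aggregation and inverse-variance task pooling follow the formulas", {
  agg <- aggregate_auc(c(0.6, 0.7, 0.65, 0.62, 0.68))
  expect_equal(agg$mean, mean(c(0.6, 0.7, 0.65, 0.62, 0.68)))
  expect_equal(agg$se, sd(c(0.6, 0.7, 0.65, 0.62, 0.68)) / sqrt(5))
  pooled <- combine_tasks(c(0.6, 0.5), c(0.01, 0.1))
  expect_equal(pooled$mean, 0.599, tolerance = 1e-3)
  expect_equal(pooled$se, 1 / sqrt(1 / 0.01^2 + 1 / 0.1^2))
  # degenerate cases
  expect_equal(combine_tasks(0.7, 0.05)$mean, 0.7)
  expect_equal(combine_tasks(c(0.6, 0.6), c(0.02, 0.02))$mean, 0.6)
  expect_error(combine_tasks(c(0.6, 0.5), c(0, 0.1)), "arithmetic")
  expect_equal(combine_tasks(c(0.3, 0.5), c(0.02, 0.04),
                             method = "arithmetic")$mean, 0.4)
})

test_that("the optimal threshold sits on the maximum iso-accuracy point", {
  d <- tibble::tibble(y = c(1, 1, 0, 0), s = c(0.9, 0.8, 0.2, 0.1),
                      w = c(1, 1, 1, 1))
  opt <- optimal_threshold(weighted_roc(d, y, s, w))
  expect_equal(opt$tpr, 1)
  expect_equal(opt$fpr, 0)
  # brute force over all thresholds on a random weighted set
  withr::with_seed(197, {
    y <- sample(c(0, 1), 15, replace = TRUE)
    s <- round(runif(15), 1)
    w <- sample(1:4, 15, replace = TRUE)
    d2 <- tibble::tibble(y = y, s = s, w = w)
    roc <- weighted_roc(d2, y, s, w)
    best <- -Inf
    for (t in c(Inf, sort(unique(s), decreasing = TRUE))) {
      acc <- (sum(w[y == 1 & s >= t]) + sum(w[y == 0 & s < t])) / sum(w)
      best <- max(best, acc)
    }
    opt2 <- optimal_threshold(roc)
    expect_equal(opt2$accuracy, best, tolerance = 1e-12)
    prev <- sum(w[y == 1]) / sum(w)
    expect_gte(opt2$accuracy, max(prev, 1 - prev) - 1e-12)
  })
})

test_that("macro averaging over one-vs-rest classes matches the manual mean", {
  withr::with_seed(199, {
    d <- tibble::tibble(label = sample(0:2, 60, replace = TRUE),
                        w = sample(1:3, 60, replace = TRUE))
    for (cl in 0:2) d[[paste0(".pred_", cl)]] <- runif(60) + (d$label == cl)
    manual <- mean(vapply(0:2, function(cl) {
      dd <- tibble::tibble(y = d$label == cl, s = d[[paste0(".pred_", cl)]],
                           w = d$w)
      weighted_roc(dd, y, s, w, positive_class = TRUE)$auc
    }, numeric(1)))
    expect_equal(macro_weighted_auc(d, label, w), manual)
  })
})

test_that("bootstrap bands collapse for degenerate inputs and bracket the median", {
  d <- tibble::tibble(y = rep(c(1, 0), each = 6),
                      s = rep(c(0.9, 0.1), each = 6), w = 1)
  bb1 <- bootstrap_bands(d, y, s, w, n_boot = 1, seed = 3)
  expect_equal(bb1$median_auc, bb1$aucs[1])
  expect_equal(bb1$band$lo, bb1$band$hi)
  # identical duplicated bags: every resample has the same curve
  bb <- bootstrap_bands(d, y, s, w, n_boot = 5, seed = 5)
  expect_equal(bb$band$lo, bb$band$hi)
  withr::with_seed(211, {
    d2 <- tibble::tibble(y = sample(c(0, 1), 30, replace = TRUE),
                         s = runif(30), w = sample(1:3, 30, replace = TRUE))
    bb2 <- bootstrap_bands(d2, y, s, w, n_boot = 5, seed = 7)
    expect_gte(bb2$median_auc, min(bb2$aucs))
    expect_lte(bb2$median_auc, max(bb2$aucs))
  })
})

test_that("the evaluation report aggregates folds and exposes operating points", {
  withr::with_seed(223, {
    bags <- tibble::tibble(bag_id = 1:40, n_instances = sample(3:20, 40, TRUE))
    preds <- dplyr::bind_rows(lapply(1:2, function(f) {
      dplyr::bind_rows(lapply(1:2, function(s) {
        lab <- sample(c(0, 1), 40, replace = TRUE)
        tibble::tibble(bag_id = 1:40, label = lab, fold = f, seed = s,
                       .pred_0 = runif(40), .pred_1 = runif(40) + 0.5 * lab)
      }))
    }))
    rep <- evaluation_report(preds, bags, task = "demo")
    expect_equal(rep$n_models, 4)
    expect_gt(rep$roc_auc_mean, 0.5)
    expect_gte(rep$roc_auc_se, 0)
    expect_true(all(c("opt_tpr", "opt_fpr") %in% names(rep)))
    expect_equal(nrow(attr(rep, "per_model")), 4)
  })
})
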