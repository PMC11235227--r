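#' Configuration of the attention MIL model
#'
#' @param input_dim Feature dimension (set automatically by [mil_train()]
#'   when `NULL`).
#' @param embed_dim Width of the instance-embedding layer producing `h`.
#' @param attn_dim Width of the attention branches (`V`, `U` rows).
#' @param gated Use gated attention (tanh x sigmoid branches, the
#'   default) rather than the plain tanh branch.
#' @param n_classes Number of bag classes (>= 2).
#' @param lr Adam learning rate.
#' @param weight_decay L2 regularisation weight.
#' @param patience Early stopping: training ends this many epochs after
#'   the validation AUC stops improving by more than `min_delta`
#'   (default 40), restoring the best-validation parameters.
#' @param max_epochs Hard cap on epochs.
#' @param min_delta Smallest validation-AUC change that counts as an
#'   improvement.
#' @param seed Seed controlling weight initialisation and bag sampling.
#' @param use_quality_weights Multiply attention scores by the
#'   per-instance quality weight `g` at *both* training and test time.
#' @param include_g_feature Append `g` as an input feature column.
#' @param model_type `"attention"` or `"milmax"` (the classic
#'   max-pooling MIL baseline: per-instance probabilities, bag score by
#'   max).
#' @param attn_denominator `"gj"` (normalising softmax over `g_j`-scaled
#'   scores, the default) or `"gk"` (a literal variant where the
#'   denominator reuses the numerator's own weight; kept for comparison
#'   only — its outputs do not sum to one).
#' @return A list of class `mil_config`.
#' @export
mil_config <- function(input_dim = NULL, embed_dim = 32L, attn_dim = 16L,
                       gated = TRUE, n_classes = 2L, lr = 5e-3,
                       weight_decay = 1e-4, patience = 40L,
                       max_epochs = 300L, min_delta = 1e-4, seed = 1L,
                       use_quality_weights = FALSE,
                       include_g_feature = FALSE,
                       model_type = c("attention", "milmax"),
                       attn_denominator = c("gj", "gk")) {
  model_type <- match.arg(model_type)
  attn_denominator <- match.arg(attn_denominator)
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  if (patience <= 0L) stop("`patience` must be positive", call. = FALSE)
  structure(as.list(environment()), class = "mil_config")
}

# Xavier-style initialisation of all parameter matrices.
.mil_init <- function(config) {
  D <- config$input_dim; M <- config$embed_dim
  L <- config$attn_dim; C <- config$n_classes
  rn <- function(r, c) matrix(stats::rnorm(r * c, 0, sqrt(1 / c)), r, c)
  list(W1 = rn(M, D), b1 = numeric(M),
       V = rn(L, M), U = rn(L, M), w = stats::rnorm(L, 0, sqrt(1 / L)),
       W2 = rn(C, M), b2 = numeric(C))
}

#' Gated soft attention over instance embeddings
#'
#' Computes the fractional contribution of each instance: raw scores are
#' `w' (tanh(V h') * sigmoid(U h'))` in gated mode or `w' tanh(V h')`
#' un-gated, passed through a softmax so the weights are positive and sum
#' to one over the bag.
#'
#' @param h K x M matrix of instance embeddings (rows are instances).
#' @param weights List with matrices `V`, `U` and vector `w` (e.g.
#'   `model$params` of a fitted [mil_train()] model).
#' @param gated Logical.
#' @return Numeric vector of K attention weights summing to 1.
#' @export
attend <- function(h, weights, gated = TRUE) {
  h <- rbind(h)
  scores <- .attn_scores(h, weights, gated)
  softmax(scores)
}

.attn_scores <- function(h, weights, gated) {
  T_ <- tanh(h %*% t(weights$V))
  if (gated) {
    S_ <- sigmoid(h %*% t(weights$U))
    as.vector((T_ * S_) %*% weights$w)
  } else {
    as.vector(T_ %*% weights$w)
  }
}

#' Quality-weighted attention
#'
#' Multiplies each instance's raw attention score by its segmentation
#' quality weight `g` in `[0, 1]` before the softmax, so instances whose
#' segmentation the ensemble disagrees on contribute less. With every
#' `g = 1` this reduces exactly to [attend()]; with all scores zeroed
#' (`g = 0` everywhere) attention is uniform.
#'
#' @inheritParams attend
#' @param g Numeric vector of per-instance weights in `[0, 1]`.
#' @param denominator `"gj"` (default, normalising softmax) or `"gk"`
#'   (literal variant whose denominator reuses the numerator's weight;
#'   outputs then need not sum to 1 — kept for comparison).
#' @return Numeric vector of K attention weights.
#' @export
attend_weighted <- function(h, g, weights, gated = TRUE,
                            denominator = c("gj", "gk")) {
  denominator <- match.arg(denominator)
  h <- rbind(h)
  if (length(g) != nrow(h)) stop("`g` must have one value per instance", call. = FALSE)
  if (any(g < 0 | g > 1)) stop("`g` must lie in [0, 1]", call. = FALSE)
  r <- .attn_scores(h, weights, gated)
  if (denominator == "gj") return(softmax(r * g))
  # literal form: a_k = exp(r_k g_k) / sum_j exp(r_j g_k)
  vapply(seq_along(r), function(k) {
    exp(r[k] * g[k]) / sum(exp(r * g[k]))
  }, numeric(1))
}

# Forward pass for one bag. X: K x D. Returns cache for backprop.
.mil_forward <- function(params, X, g, config) {
  H <- tanh(X %*% t(params$W1) + rep(params$b1, each = nrow(X)))
  T_ <- tanh(H %*% t(params$V))
  if (config$gated) {
    S_ <- sigmoid(H %*% t(params$U))
    r <- as.vector((T_ * S_) %*% params$w)
  } else {
    S_ <- NULL
    r <- as.vector(T_ %*% params$w)
  }
  e <- if (config$use_quality_weights) r * g else r
  a <- softmax(e)
  z <- as.vector(t(H) %*% a)
  logits <- as.vector(params$W2 %*% z + params$b2)
  p <- softmax(logits)
  list(H = H, T_ = T_, S_ = S_, r = r, a = a, z = z, p = p)
}

# Backward pass; returns gradients with the same shapes as params.
.mil_backward <- function(params, X, g, y, fw, config) {
  K <- nrow(X)
  dlogits <- fw$p
  dlogits[y + 1L] <- dlogits[y + 1L] - 1
  dW2 <- dlogits %o% fw$z
  db2 <- dlogits
  dz <- as.vector(t(params$W2) %*% dlogits)
  da <- as.vector(fw$H %*% dz)
  dH <- fw$a %o% dz
  de <- fw$a * (da - sum(fw$a * da))
  dr <- if (config$use_quality_weights) de * g else de
  if (config$gated) {
    TS <- fw$T_ * fw$S_
    dw <- as.vector(t(TS) %*% dr)
    dTS <- dr %o% params$w
    dpreV <- dTS * fw$S_ * (1 - fw$T_^2)
    dpreU <- dTS * fw$T_ * fw$S_ * (1 - fw$S_)
    dV <- t(dpreV) %*% fw$H
    dU <- t(dpreU) %*% fw$H
    dH <- dH + dpreV %*% params$V + dpreU %*% params$U
  } else {
    dw <- as.vector(t(fw$T_) %*% dr)
    dpreV <- (dr %o% params$w) * (1 - fw$T_^2)
    dV <- t(dpreV) %*% fw$H
    dU <- params$U * 0
    dH <- dH + dpreV %*% params$V
  }
  dpre1 <- dH * (1 - fw$H^2)
  dW1 <- t(dpre1) %*% X
  db1 <- colSums(dpre1)
  list(W1 = dW1, b1 = db1, V = dV, U = dU, w = dw, W2 = dW2, b2 = db2)
}

# Max-pooling MIL baseline: per-instance class probabilities from the
# head; bag positive logit = max over instances. Gradient flows through
# the selected instance only.
.milmax_forward <- function(params, X, config) {
  H <- tanh(X %*% t(params$W1) + rep(params$b1, each = nrow(X)))
  logits <- H %*% t(params$W2) + rep(params$b2, each = nrow(X))  # K x C
  pos <- config$n_classes   # last class is "positive"
  k_star <- which.max(logits[, pos])
  p <- softmax(logits[k_star, ])
  list(H = H, logits = logits, k_star = k_star, p = p)
}

.milmax_backward <- function(params, X, y, fw, config) {
  k <- fw$k_star
  dlogit <- fw$p
  dlogit[y + 1L] <- dlogit[y + 1L] - 1
  dW2 <- dlogit %o% fw$H[k, ]
  db2 <- dlogit
  dh <- as.vector(t(params$W2) %*% dlogit)
  dpre <- dh * (1 - fw$H[k, ]^2)
  dW1 <- dpre %o% X[k, ]
  db1 <- dpre
  list(W1 = dW1, b1 = db1, V = params$V * 0, U = params$U * 0,
       w = params$w * 0, W2 = dW2, b2 = db2)
}

.adam_step <- function(params, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    gr <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Turn (instances, bags) tibbles into a list of per-bag matrices.
.make_bag_list <- function(instances, bags, feature_cols, include_g) {
  cols <- feature_cols
  if (include_g) {
    if (!"g" %in% names(instances)) {
      stop("`include_g_feature` needs a `g` column; see bag_quality_weights()",
           call. = FALSE)
    }
    cols <- c(cols, "g")
  }
  instances <- dplyr::arrange(instances, .data$bag_id, .data$instance_id)
  split_idx <- split(seq_len(nrow(instances)), instances$bag_id)
  X_all <- as.matrix(instances[, cols])
  g_all <- if ("g" %in% names(instances)) instances$g else rep(1, nrow(instances))
  out <- vector("list", nrow(bags))
  names(out) <- as.character(bags$bag_id)
  for (i in seq_len(nrow(bags))) {
    bid <- as.character(bags$bag_id[i])
    ri <- split_idx[[bid]]
    if (is.null(ri)) stop("bag ", bid, " has no instances", call. = FALSE)
    out[[bid]] <- list(X = X_all[ri, , drop = FALSE], g = g_all[ri],
                       label = bags$label[i], bag_id = bags$bag_id[i])
  }
  out
}

# Macro one-vs-rest unweighted ROC AUC of a probability matrix.
.macro_auc <- function(prob, labels, n_classes) {
  if (n_classes == 2L) {
    return(.auc_unweighted(prob[, 2L], labels == 1L))
  }
  aucs <- c()
  for (c in seq_len(n_classes) - 1L) {
    pos <- labels == c
    if (all(pos) || !any(pos)) next
    aucs <- c(aucs, .auc_unweighted(prob[, c + 1L], pos))
  }
  if (length(aucs) == 0L) return(NA_real_)
  mean(aucs)
}

# Fast rank-based AUC (ties handled by midranks).
.auc_unweighted <- function(score, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the attention MIL model
#'
#' Minimises bag-level cross-entropy with Adam, one bag per step. Bags
#' are sampled with probability inversely proportional to their class
#' frequency in the training split, so rare classes are seen as often as
#' common ones. Training stops `patience` epochs (default 40) after the
#' validation AUC stops improving, and the best-validation parameters are
#' restored. When `use_quality_weights` is set, quality-weighted
#' attention is used at both training and test time. Fully seeded and
#' reproducible.
#'
#' @param bag_set A [synth_bags()]-style `bag_set` (tibbles `instances`,
#'   `bags`). Run [bag_quality_weights()] first if quality weights are
#'   used.
#' @param config A [mil_config()].
#' @param split List with integer vectors `train` and `val` of bag ids;
#'   donor-disjoint splits are the caller's contract (see
#'   [mil_crossval()]).
#' @param feature_cols Feature column names; default all `f_*` columns.
#' @return An object of class `mil_model` with elements `params`,
#'   `config`, `feature_cols`, `log` (per-epoch tibble), and
#'   `best_val_auc`.
#' @export
mil_train <- function(bag_set, config, split, feature_cols = NULL) {
  stopifnot(inherits(bag_set, "bag_set"), inherits(config, "mil_config"))
  instances <- bag_set$instances; bags <- bag_set$bags
  if (is.null(feature_cols)) {
    feature_cols <- grep("^f_", names(instances), value = TRUE)
  }
  train_bags <- bags[bags$bag_id %in% split$train, ]
  val_bags <- bags[bags$bag_id %in% split$val, ]
  classes <- sort(unique(bags$label))
  if (!all(classes %in% train_bags$label)) {
    stop("every class must be present in the training split", call. = FALSE)
  }
  if (!all(classes %in% val_bags$label)) {
    stop("validation split is missing a class", call. = FALSE)
  }
  config$n_classes <- length(classes)
  config$input_dim <- length(feature_cols) + as.integer(config$include_g_feature)
  bl <- .make_bag_list(instances, bags, feature_cols, config$include_g_feature)
  tr_ids <- as.character(train_bags$bag_id)
  va_ids <- as.character(val_bags$bag_id)
  freq <- table(factor(train_bags$label, levels = classes))
  samp_w <- as.vector(1 / freq[as.character(train_bags$label)])
  samp_w <- samp_w / sum(samp_w)

  eval_val <- function(params) {
    prob <- t(vapply(va_ids, function(id) {
      b <- bl[[id]]
      if (config$model_type == "milmax") {
        .milmax_forward(params, b$X, config)$p
      } else {
        .mil_forward(params, b$X, b$g, config)$p
      }
    }, numeric(config$n_classes)))
    .macro_auc(prob, val_bags$label, config$n_classes)
  }

  with_seed(config$seed, {
    params <- .mil_init(config)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    best <- list(params = params, auc = -Inf, epoch = 0L)
    stall <- 0L; t_glob <- 0L
    log_rows <- vector("list", config$max_epochs)
    for (epoch in seq_len(config$max_epochs)) {
      draw <- sample(tr_ids, length(tr_ids), replace = TRUE, prob = samp_w)
      loss_sum <- 0
      for (id in draw) {
        b <- bl[[id]]
        y <- match(b$label, classes) - 1L
        if (config$model_type == "milmax") {
          fw <- .milmax_forward(params, b$X, config)
          gr <- .milmax_backward(params, b$X, y, fw, config)
        } else {
          fw <- .mil_forward(params, b$X, b$g, config)
          gr <- .mil_backward(params, b$X, b$g, y, fw, config)
        }
        loss_sum <- loss_sum - log(max(fw$p[y + 1L], 1e-12))
        t_glob <- t_glob + 1L
        upd <- .adam_step(params, gr, state, config$lr, config$weight_decay, t_glob)
        params <- upd$params; state <- upd$state
      }
      val_auc <- eval_val(params)
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = loss_sum / length(draw), val_auc = val_auc)
      if (!is.na(val_auc) && val_auc > best$auc + config$min_delta) {
        best <- list(params = params, auc = val_auc, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (stall >= config$patience) break
    }
    structure(list(params = best$params, config = config, classes = classes,
                   feature_cols = feature_cols,
                   log = dplyr::bind_rows(log_rows),
                   best_val_auc = best$auc, best_epoch = best$epoch),
              class = "mil_model")
  })
}

#' Predict bag labels and attention with a fitted model
#'
#' Instances are processed in canonical order (sorted by `bag_id`,
#' `instance_id`), which makes predictions exactly invariant to the row
#' order of the input. The bag representation is the attention-weighted
#' average of instance embeddings; for the max-pooling baseline the bag
#' probability comes from the best-scoring instance.
#'
#' @param model A fitted `mil_model`.
#' @param bag_set A `bag_set`.
#' @param bag_ids Bags to predict (default: all).
#' @return Tibble with `bag_id`, `label` and `.pred_<class>` columns;
#'   per-instance attention in the `attention` attribute (tibble
#'   `bag_id`, `instance_id`, `attention`).
#' @export
mil_predict <- function(model, bag_set, bag_ids = NULL) {
  stopifnot(inherits(model, "mil_model"), inherits(bag_set, "bag_set"))
  bags <- bag_set$bags
  if (!is.null(bag_ids)) bags <- bags[bags$bag_id %in% bag_ids, ]
  bl <- .make_bag_list(bag_set$instances, bags, model$feature_cols,
                       model$config$include_g_feature)
  C <- model$config$n_classes
  probs <- matrix(NA_real_, nrow(bags), C)
  attn <- vector("list", nrow(bags))
  for (i in seq_len(nrow(bags))) {
    b <- bl[[as.character(bags$bag_id[i])]]
    if (model$config$model_type == "milmax") {
      fw <- .milmax_forward(model$params, b$X, model$config)
      a <- as.numeric(seq_len(nrow(b$X)) == fw$k_star)
    } else {
      fw <- .mil_forward(model$params, b$X, b$g, model$config)
      a <- fw$a
    }
    probs[i, ] <- fw$p
    attn[[i]] <- tibble::tibble(bag_id = bags$bag_id[i],
                                instance_id = seq_along(a), attention = a)
  }
  colnames(probs) <- paste0(".pred_", model$classes)
  out <- dplyr::bind_cols(bags[, c("bag_id", "label")], tibble::as_tibble(probs))
  attr(out, "attention") <- dplyr::bind_rows(attn)
  out
}

#' Donor-grouped cross-validation of the attention MIL model
#'
#' Donors (never bags) are partitioned into `n_folds` groups; fold `f`
#' uses group `f` as test, the next group as validation and the remaining
#' three as training (a 3:1:1 split by donor), so all slides from one
#' donor stay on the same side of every split. For each fold,
#' `n_seeds` differently seeded weight initialisations are trained —
#' `n_folds * n_seeds` models in total — and out-of-fold test predictions
#' are pooled for evaluation.
#'
#' @param bag_set A `bag_set`.
#' @param config A [mil_config()]; its seed drives fold assignment.
#' @param n_folds,n_seeds Protocol sizes (defaults 5 and 5: 25 models).
#' @return An object of class `mil_cv`: `predictions` (tibble with
#'   `fold`, `seed`, per-class scores), `models`, `fold_assignment`.
#' @export
mil_crossval <- function(bag_set, config, n_folds = 5L, n_seeds = 5L) {
  stopifnot(inherits(bag_set, "bag_set"))
  bags <- bag_set$bags
  donors <- unique(bags$donor_id)
  if (length(donors) < n_folds) {
    stop("need at least ", n_folds, " donors for ", n_folds, "-fold grouped CV",
         call. = FALSE)
  }
  donors <- with_seed(derive_seed(config$seed, "fold-assignment"),
                      sample(donors))
  group <- rep_len(seq_len(n_folds), length(donors))
  assignment <- tibble::tibble(donor_id = donors, group = group)
  preds <- list(); models <- list()
  for (f in seq_len(n_folds)) {
    test_d <- donors[group == f]
    val_d <- donors[group == (f %% n_folds) + 1L]
    train_d <- setdiff(donors, c(test_d, val_d))
    split <- list(train = bags$bag_id[bags$donor_id %in% train_d],
                  val = bags$bag_id[bags$donor_id %in% val_d])
    test_ids <- bags$bag_id[bags$donor_id %in% test_d]
    for (s in seq_len(n_seeds)) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0("fold", f, ".seed", s))
      m <- mil_train(bag_set, cfg, split)
      p <- mil_predict(m, bag_set, test_ids)
      p$fold <- f; p$seed <- s
      preds[[length(preds) + 1L]] <- p
      models[[length(models) + 1L]] <- m
    }
  }
  structure(list(predictions = dplyr::bind_rows(preds), models = models,
                 fold_assignment = assignment,
                 n_folds = n_folds, n_seeds = n_seeds),
            class = "mil_cv")
}

#' Random-search hyperparameter tuning on a count-adequacy task
#'
#' Hyperparameters (gated vs un-gated attention, layer widths,
#' regularisation weight, learning rate) are tuned by seeded random
#' search on a fully labelled, near-trivial task — ordinal 3-class bags
#' keyed to the signal-instance count — and the chosen configuration is
#' then frozen for all other tasks, so featureset comparisons stay fair.
#'
#' @param bag_set A `bag_set` (typically `synth_bags(bag_config(mode =
#'   "ordinal"))`).
#' @param search_space Named list of candidate values per hyperparameter.
#' @param budget Number of sampled configurations (>= 1).
#' @param base_config Starting [mil_config()].
#' @return The winning `mil_config`; the search trace is in the
#'   `search_results` attribute.
#' @export
mil_tune <- function(bag_set,
                     search_space = list(gated = c(TRUE, FALSE),
                                         embed_dim = c(16L, 32L),
                                         attn_dim = c(8L, 16L),
                                         weight_decay = c(0, 1e-4, 1e-3),
                                         lr = c(2e-3, 5e-3, 1e-2)),
                     budget = 5L, base_config = mil_config()) {
  if (length(search_space) == 0L) stop("empty search space", call. = FALSE)
  if (budget < 1L) stop("`budget` must be >= 1", call. = FALSE)
  n_points <- prod(vapply(search_space, length, integer(1)))
  bags <- bag_set$bags
  donors <- with_seed(derive_seed(base_config$seed, "tune-split"),
                      sample(unique(bags$donor_id)))
  grp <- rep_len(1:5, length(donors))
  split <- list(train = bags$bag_id[bags$donor_id %in% donors[grp <= 3L]],
                val = bags$bag_id[bags$donor_id %in% donors[grp == 4L]])
  draw_cfg <- with_seed(derive_seed(base_config$seed, "tune-draw"), {
    lapply(seq_len(if (n_points == 1L) 1L else budget), function(i) {
      lapply(search_space, function(v) v[[sample.int(length(v), 1L)]])
    })
  })
  if (n_points == 1L) draw_cfg <- list(lapply(search_space, `[[`, 1L))
  draw_cfg <- unique(draw_cfg)
  rows <- list()
  best <- NULL; best_auc <- -Inf
  for (i in seq_along(draw_cfg)) {
    cfg <- base_config
    for (nm in names(draw_cfg[[i]])) cfg[[nm]] <- draw_cfg[[i]][[nm]]
    m <- mil_train(bag_set, cfg, split)
    rows[[i]] <- tibble::as_tibble(c(draw_cfg[[i]], list(val_auc = m$best_val_auc)))
    if (!is.na(m$best_val_auc) && m$best_val_auc > best_auc) {
      best_auc <- m$best_val_auc; best <- cfg
    }
  }
  attr(best, "search_results") <- dplyr::bind_rows(rows)
  best
}

#' @export
print.mil_model <- function(x, ...) {
  cat("<mil_model> ", x$config$model_type,
      if (x$config$gated) " (gated)" else " (un-gated)",
      ", ", length(x$classes), " classes, best val AUC ",
      round(x$best_val_auc, 3), " @ epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' @export
print.mil_cv <- function(x, ...) {
  cat("<mil_cv> ", x$n_folds, " folds x ", x$n_seeds, " seeds = ",
      length(x$models), " models; ", nrow(x$predictions),
      " pooled test predictions\n", sep = "")
  invisible(x)
}
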