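test_that("attention weights form a proper distribution over any bag", {
  wts <- make_attn_weights()
  withr::with_seed(79, {
    for (K in c(1, 2, 7, 20)) {
      h <- matrix(rnorm(K * 8), K, 8)
      for (gated in c(TRUE, FALSE)) {
        a <- attend(h, wts, gated = gated)
        expect_length(a, K)
        expect_equal(sum(a), 1, tolerance = 1e-6)
        expect_true(all(a > 0))
      }
    }
  })
})

test_that("a single instance takes all attention and twins split it evenly", {
  wts <- make_attn_weights()
  h1 <- matrix(rnorm(8), 1, 8)
  expect_equal(attend(h1, wts), 1)
  h2 <- rbind(h1[1, ], h1[1, ])
  expect_equal(attend(h2, wts), c(0.5, 0.5))
})

test_that("quality weighting with g = 1 reduces exactly to plain attention", {
  wts <- make_attn_weights()
  withr::with_seed(83, {
    h <- matrix(rnorm(5 * 8), 5, 8)
    expect_identical(attend_weighted(h, rep(1, 5), wts), attend(h, wts))
    # all-zero g: every score is zeroed, attention is uniform
    expect_equal(attend_weighted(h, rep(0, 5), wts), rep(0.2, 5))
  })
})

test_that("down-weighting one of two identical instances follows the closed form", {
  wts <- make_attn_weights()
  withr::with_seed(89, {
    h1 <- rnorm(8)
    h <- rbind(h1, h1)
    s <- tissuemil:::.attn_scores(rbind(h1), wts, gated = TRUE)
    a <- attend_weighted(h, c(1, 0), wts)
    expect_equal(a, as.vector(tissuemil:::softmax(c(s, 0))), tolerance = 1e-12)
    if (s > 0) expect_gt(a[1], a[2]) else expect_lt(a[1], a[2])
  })
})

test_that("the literal gk-denominator variant matches its formula", {
  wts <- make_attn_weights()
  withr::with_seed(97, {
    h <- matrix(rnorm(3 * 8), 3, 8)
    g <- c(0.9, 0.5, 0.1)
    r <- tissuemil:::.attn_scores(h, wts, gated = TRUE)
    manual <- vapply(1:3, function(k) exp(r[k] * g[k]) / sum(exp(r * g[k])),
                     numeric(1))
    expect_equal(attend_weighted(h, g, wts, denominator = "gk"), manual)
  })
  expect_error(attend_weighted(matrix(0, 2, 8), c(0.5, 1.2), wts), "\\[0, 1\\]")
})

test_that("bag prediction is permutation invariant and duplication stable", {
  bs <- synth_bags(bag_config(n_bags = 40, seed = 101))
  sp <- grouped_split(bs)
  m <- mil_train(bs, mil_config(seed = 1, max_epochs = 5, patience = 3),
                 list(train = sp$train, val = sp$val))
  p1 <- mil_predict(m, bs, sp$test)
  # permute instance rows: canonical ordering makes predictions bit-identical
  bs_perm <- bs
  withr::with_seed(5, {
    bs_perm$instances <- bs_perm$instances[sample.int(nrow(bs_perm$instances)), ]
  })
  p2 <- mil_predict(m, bs_perm, sp$test)
  expect_identical(p1$.pred_1, p2$.pred_1)
  # duplicating every instance leaves bag probabilities unchanged
  bs_dup <- bs
  dup <- bs$instances
  dup$instance_id <- dup$instance_id + max(dup$instance_id)
  bs_dup$instances <- dplyr::bind_rows(bs$instances, dup)
  p3 <- mil_predict(m, bs_dup, sp$test)
  expect_equal(p3$.pred_1, p1$.pred_1, tolerance = 1e-10)
})

test_that("a one-instance bag's representation is its own embedding", {
  bs <- synth_bags(bag_config(n_bags = 20, instances_per_bag = c(1L, 1L),
                              signal_per_bag = c(1L, 1L), seed = 103))
  sp <- grouped_split(bs)
  m <- mil_train(bs, mil_config(seed = 2, max_epochs = 3, patience = 2),
                 list(train = sp$train, val = sp$val))
  b1 <- bs$instances[bs$instances$bag_id == 1, ]
  X <- as.matrix(b1[, paste0("f_", 1:10)])
  fw <- tissuemil:::.mil_forward(m$params, X, 1, m$config)
  expect_equal(fw$a, 1)
  H <- tanh(X %*% t(m$params$W1) + m$params$b1)
  expect_equal(fw$z, as.vector(H), tolerance = 1e-12)
  expect_equal(fw$p, tissuemil:::softmax(
    as.vector(m$params$W2 %*% as.vector(H) + m$params$b2)), tolerance = 1e-12)
})

test_that("the max-pooling baseline takes the best instance and grows with the bag", {
  cfg <- mil_config(input_dim = 4L, model_type = "milmax", seed = 7)
  params <- withr::with_seed(7, tissuemil:::.mil_init(cfg))
  withr::with_seed(107, {
    X <- matrix(rnorm(6 * 4), 6, 4)
    fw <- tissuemil:::.milmax_forward(params, X, cfg)
    per_inst <- tanh(X %*% t(params$W1) + rep(params$b1, each = 6)) %*%
      t(params$W2) + rep(params$b2, each = 6)
    expect_equal(fw$k_star, which.max(per_inst[, 2]))
    # adding instances never lowers the bag positive logit
    best <- -Inf
    for (K in 1:6) {
      fwK <- tissuemil:::.milmax_forward(params, X[1:K, , drop = FALSE], cfg)
      logit <- max(per_inst[1:K, 2])
      expect_gte(logit, best)
      best <- logit
    }
  })
})
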