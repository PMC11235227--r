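make_stack <- function(values, H = 4, W = 4) {
  # values: vector of per-model constants for a single class
  M <- length(values)
  maps <- array(0, c(M, 1, H, W))
  for (m in seq_len(M)) maps[m, 1, , ] <- values[m]
  prob_stack(maps, "tubule", mpp = 0.44)
}

test_that("the corrected map reduces to the mean at A = 0 and at zero variance", {
  st <- make_stack(c(0.3, 0.5, 0.7))
  f0 <- fuse_ensemble(st, A = 0)
  expect_equal(f0$p_tilde, f0$p_mean)
  st_flat <- make_stack(rep(0.8, 4))
  f <- fuse_ensemble(st_flat, A = 5)
  expect_equal(unique(as.vector(f$p_tilde)), 0.8)
})

test_that("a single dissenting model is suppressed by the sigma penalty", {
  st <- make_stack(c(1, 0, 0, 0))
  f <- fuse_ensemble(st, A = 1)
  expect_equal(unique(as.vector(f$p_mean)), 0.25)
  expect_equal(unique(as.vector(f$p_sigma)), sqrt(3) / 4, tolerance = 1e-12)
  expect_equal(unique(as.vector(f$p_tilde)), 0)  # max(0.25 - 0.433, 0)
})

test_that("raising A never raises any corrected probability", {
  withr::with_seed(31, {
    maps <- array(runif(3 * 2 * 6 * 6), c(3, 2, 6, 6))
    st <- prob_stack(maps, c("a", "b"), mpp = 0.5)
    prev <- fuse_ensemble(st, A = 0)$p_tilde
    for (A in c(0.5, 1, 2, 4)) {
      cur <- fuse_ensemble(st, A = A)$p_tilde
      expect_true(all(cur <= prev + 1e-12))
      expect_true(all(cur >= 0))
      prev <- cur
    }
  })
})

test_that("the sigma convention switch matches population and sample formulas", {
  st <- make_stack(c(0.2, 0.4, 0.9))
  v <- c(0.2, 0.4, 0.9)
  fp <- fuse_ensemble(st, A = 0, sd_type = "population")
  fs <- fuse_ensemble(st, A = 0, sd_type = "sample")
  expect_equal(unique(as.vector(fp$p_sigma)), sqrt(mean((v - mean(v))^2)),
               tolerance = 1e-12)
  expect_equal(unique(as.vector(fs$p_sigma)), sd(v), tolerance = 1e-12)
})

test_that("single-model stacks are rejected", {
  expect_error(prob_stack(array(0.5, c(1, 1, 4, 4)), "a", 0.44), ">= 2")
})

test_that("min-cut extraction recovers clean separated disks exactly", {
  H <- 40; W <- 40
  p <- matrix(0, H, W)
  d1 <- disk_mask(H, W, 10, 10, 6)
  d2 <- disk_mask(H, W, 30, 30, 5)
  p[d1 | d2] <- 1
  maps <- array(0, c(2, 1, H, W)); maps[1, 1, , ] <- p; maps[2, 1, , ] <- p
  fused <- fuse_ensemble(prob_stack(maps, "tubule", 0.44), A = 0)
  inst <- extract_instances(fused, "tubule", min_area_px = 10, smoothness = 0)
  expect_length(inst, 2)
  masks <- lapply(inst, `[[`, "mask")
  areas <- vapply(masks, sum, numeric(1))
  expect_setequal(areas, c(sum(d1), sum(d2)))
  expect_equal(Reduce(`|`, masks), d1 | d2)
  # all-zero map: empty result, not an error
  fused0 <- fuse_ensemble(prob_stack(array(0, c(2, 1, H, W)), "tubule", 0.44), 0)
  expect_length(extract_instances(fused0, "tubule"), 0)
})

test_that("min-cut at zero smoothness equals 0.5-thresholding on random maps", {
  withr::with_seed(37, {
    for (i in 1:60) {
      p <- matrix(runif(64), 8, 8)
      fg <- tissuemil:::mincut_binarise(p, smoothness = 0)
      expect_identical(fg, p > 0.5)
    }
  })
})

test_that("the decided-pixel reduction is exact against the full graph", {
  withr::with_seed(41, {
    for (lambda in c(0.3, 1, 2.5)) {
      p <- matrix(runif(70 * 70), 70, 70)
      a <- tissuemil:::mincut_binarise(p, lambda, reduce_over = 1000)
      b <- tissuemil:::mincut_binarise(p, lambda, reduce_over = 10^9)
      expect_identical(a, b)
    }
  })
})

test_that("smoothness regularises salt-and-pepper noise", {
  results <- withr::with_seed(43, replicate(10, {
    H <- 48; W <- 48
    gt <- disk_mask(H, W, 24, 24, 14)
    p <- ifelse(gt, 0.9, 0.1)
    flip <- matrix(runif(H * W) < 0.05, H, W)
    p[flip] <- 1 - p[flip]
    maps <- array(0, c(2, 1, H, W)); maps[1, 1, , ] <- p; maps[2, 1, , ] <- p
    fused <- fuse_ensemble(prob_stack(maps, "tubule", 0.44), A = 0)
    per_s <- lapply(c(0, 1, 5), function(s) {
      inst <- extract_instances(fused, "tubule", min_area_px = 1, smoothness = s)
      fg <- Reduce(`|`, lapply(inst, `[[`, "mask"), matrix(FALSE, H, W))
      list(n = length(inst), jac = sum(fg & gt) / sum(fg | gt))
    })
    c(n0 = per_s[[1]]$n, n1 = per_s[[2]]$n, n5 = per_s[[3]]$n,
      j0 = per_s[[1]]$jac, j5 = per_s[[3]]$jac)
  }))
  expect_true(all(results["n1", ] <= results["n0", ]))
  expect_true(all(results["n5", ] <= results["n1", ]))
  expect_true(all(results["j5", ] > results["j0", ]))
})

test_that("small components are filtered by the minimum area", {
  H <- 30; W <- 30
  p <- matrix(0, H, W)
  p[disk_mask(H, W, 15, 15, 8)] <- 1
  p[5, 5] <- 1  # single-pixel speck
  maps <- array(0, c(2, 1, H, W)); maps[1, 1, , ] <- p; maps[2, 1, , ] <- p
  fused <- fuse_ensemble(prob_stack(maps, "tubule", 0.44), A = 0)
  expect_length(extract_instances(fused, "tubule", min_area_px = 5), 1)
  expect_length(extract_instances(fused, "tubule", min_area_px = 1), 2)
  expect_error(extract_instances(fused, "nope"), "unknown class")
})
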