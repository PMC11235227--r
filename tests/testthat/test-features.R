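test_that("the synthetic vessel lumen/total area ratio is recovered within 2%", {
  H <- 128; W <- 128
  m <- ring_mask(H, W, 64, 64, 50, 25)
  crop <- flat_image(H, W)
  hc <- handcrafted_features(crop, m, mpp = 0.44)
  expect_equal(hc$lumen_total_ratio, 0.25, tolerance = 0.02)
})

test_that("shape areas agree with analytic values within 2% at radius >= 20", {
  for (r in c(20, 30, 45)) {
    H <- 2 * r + 20
    m <- disk_mask(H, H, H / 2, H / 2, r)
    hc <- handcrafted_features(flat_image(H, H), m, mpp = 1)
    expect_equal(hc$area_um2, pi * r^2, tolerance = 0.02)
  }
  ring <- ring_mask(110, 110, 55, 55, 45, 20)
  hc <- handcrafted_features(flat_image(110, 110), ring, mpp = 0.5)
  expect_equal(hc$area_um2, pi * (45^2 - 20^2) * 0.25, tolerance = 0.02)
  expect_equal(hc$lumen_area_um2, pi * 20^2 * 0.25, tolerance = 0.02)
})

test_that("a filled disk is solid and cavity-free", {
  m <- disk_mask(80, 80, 40, 40, 25)
  hc <- handcrafted_features(flat_image(80, 80), m, mpp = 0.44)
  expect_equal(hc$solidity, 1, tolerance = 0.05)
  expect_equal(hc$lumen_area_um2, 0)
  expect_lt(hc$eccentricity, 0.1)
})

test_that("morphology and colour are invariant to translation", {
  withr::with_seed(67, {
    base <- array(runif(3), c(1, 1, 3))
    img <- array(rep(base, each = 120 * 120), c(120, 120, 3))
    f <- list()
    for (ctr in list(c(35, 35), c(80, 70))) {
      m <- ring_mask(120, 120, ctr[1], ctr[2], 28, 12)
      f[[length(f) + 1]] <- handcrafted_features(img, m, mpp = 0.44)
    }
    morpho_colour <- c("area_um2", "perimeter_um", "eccentricity", "solidity",
                       "lumen_area_um2", "lumen_total_ratio",
                       "urinary_space_um2", "mean_R", "mean_G", "mean_B")
    expect_equal(f[[1]][, morpho_colour], f[[2]][, morpho_colour],
                 tolerance = 1e-10)
  })
})

test_that("missing nuclei yield missing (not zero) nuclei features", {
  m <- disk_mask(60, 60, 30, 30, 20)
  hc <- handcrafted_features(flat_image(60, 60), m, nuclei_masks = list(),
                             mpp = 0.44)
  schema <- feature_schema("PAS")
  nuc_cols <- schema$name[schema$group == "nuclei"]
  expect_true(all(is.na(hc[, nuc_cols])))
  other <- setdiff(schema$name, c(nuc_cols, "total_biopsy_area_um2"))
  expect_false(any(is.na(hc[, other])))
})

test_that("the SR profile drops the nuclei group entirely", {
  sr <- feature_schema("SR")
  expect_false(any(sr$group == "nuclei"))
  pas <- feature_schema("PAS")
  expect_equal(nrow(pas) - nrow(sr), 24)  # nuclei family width
  m <- disk_mask(50, 50, 25, 25, 15)
  hc <- handcrafted_features(flat_image(50, 50), m, mpp = 0.44, schema = sr)
  expect_equal(names(hc), sr$name)
})

test_that("percentile pooling ignores nucleus order and tracks a new darkest nucleus", {
  withr::with_seed(71, {
    H <- 90
    img <- array(runif(H * H * 3, 0.3, 0.9), c(H, H, 3))
    m <- disk_mask(H, H, 45, 45, 35)
    nucs <- lapply(1:12, function(i) {
      disk_mask(H, H, 20 + (i %% 4) * 15, 20 + (i %/% 4) * 15, 3)
    })
    a <- handcrafted_features(img, m, nucs, mpp = 0.44)
    b <- handcrafted_features(img, m, rev(nucs), mpp = 0.44)
    expect_equal(a, b)
    # darken one extra nucleus below every existing one
    img2 <- img
    dm <- disk_mask(H, H, 45, 45, 2)
    for (k in 1:3) { ch <- img2[, , k]; ch[dm] <- 0; img2[, , k] <- ch }
    c_ <- handcrafted_features(img2, m, c(nucs, list(dm)), mpp = 0.44)
    dark_cols <- grep("nuc_darkness_", names(a), value = TRUE)
    expect_true(all(as.numeric(c_[, dark_cols]) <=
                      as.numeric(a[, dark_cols]) + 1e-12))
    expect_lt(c_$nuc_darkness_p0, a$nuc_darkness_p0)
  })
})

test_that("feature extraction is deterministic and rejects empty masks", {
  m <- disk_mask(40, 40, 20, 20, 10)
  img <- flat_image(40, 40)
  expect_identical(handcrafted_features(img, m, mpp = 0.44),
                   handcrafted_features(img, m, mpp = 0.44))
  expect_error(handcrafted_features(img, matrix(FALSE, 40, 40), mpp = 0.44),
               "zero area")
})

test_that("deep features pool the identity extractor as channel means", {
  crop <- flat_image(30, 30, c(0.2, 0.5, 0.7))
  v <- deep_features(crop)
  expect_equal(as.vector(v), c(0.2, 0.5, 0.7))
  withr::with_seed(73, {
    crop2 <- array(runif(30 * 30 * 3), c(30, 30, 3))
    expect_identical(deep_features(crop2), deep_features(crop2))
  })
})

test_that("background dilution of pooled features follows area weighting", {
  col <- c(0.8, 0.2, 0.4); bg <- c(0.1, 0.1, 0.1)
  make <- function(H) {
    img <- flat_image(H, H, bg)
    m <- disk_mask(H, H, H / 2, H / 2, 10)
    for (k in 1:3) { ch <- img[, , k]; ch[m] <- col[k]; img[, , k] <- ch }
    list(img = img, area = sum(m), n = H * H)
  }
  a <- make(40); b <- make(80)
  va <- deep_features(a$img); vb <- deep_features(b$img)
  expected_a <- (a$area * col + (a$n - a$area) * bg) / a$n
  expected_b <- (b$area * col + (b$n - b$area) * bg) / b$n
  expect_equal(as.vector(va), expected_a, tolerance = 1e-12)
  expect_equal(as.vector(vb), expected_b, tolerance = 1e-12)
})

test_that("undersized crops are padded reflectively and flagged", {
  ext <- identity_extractor()
  attr(ext, "min_size") <- 32L
  crop <- flat_image(10, 10, c(0.3, 0.3, 0.3))
  v <- deep_features(crop, ext)
  expect_true(attr(v, "padded"))
  expect_equal(as.vector(v), rep(0.3, 3), tolerance = 1e-12)
})
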