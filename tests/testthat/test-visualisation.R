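overlay_fixture <- function() {
  img <- flat_image(60, 90)
  inst <- list(as_instance(disk_mask(60, 90, 20, 20, 9), id = 1),
               as_instance(ring_mask(60, 90, 35, 60, 12, 6), id = 2),
               as_instance(disk_mask(60, 90, 45, 25, 7), id = 3))
  list(img = img, inst = inst)
}

test_that("overlay colouring is strictly confined to instance geometry", {
  fx <- overlay_fixture()
  fig <- attention_overlay(fx$img, fx$inst, c(0.6, 0.3, 0.1))
  diff <- apply(abs(fig$image - fx$img), c(1, 2), max)
  changed <- diff > 1e-12
  union_mask <- Reduce(`|`, lapply(fx$inst, `[[`, "mask"))
  expect_true(all(union_mask[changed]))        # containment
  fig2 <- attention_overlay(fx$img, fx$inst, c(0.6, 0.3, 0.1), fill = TRUE)
  diff2 <- apply(abs(fig2$image - fx$img), c(1, 2), max) > 1e-12
  expect_true(all(union_mask[diff2]))
})

test_that("uniform attention maps to one mid-scale colour and ranks are monotone", {
  fx <- overlay_fixture()
  fig <- attention_overlay(fx$img, fx$inst, rep(1 / 3, 3))
  expect_equal(length(unique(fig$scale$colour)), 1)
  expect_equal(unique(fig$scale$value), 0.5)
  fig2 <- attention_overlay(fx$img, fx$inst, c(0.2, 0.5, 0.3))
  expect_equal(order(fig2$scale$value), order(fig2$scale$attention))
  # one instance holding all attention sits at the scale maximum
  fig3 <- attention_overlay(fx$img, fx$inst, c(1, 0, 0))
  expect_equal(fig3$scale$value, c(1, 0, 0))
})

test_that("overlays validate attention and geometry", {
  fx <- overlay_fixture()
  expect_error(attention_overlay(fx$img, fx$inst, c(0.5, 0.2, 0.2)), "sum to 1")
  small <- as_instance(disk_mask(30, 30, 10, 10, 5))
  expect_error(attention_overlay(fx$img, list(small), 1), "outside")
})

test_that("tile overlays have the exact ceiling grid and localise a hot tile", {
  img <- flat_image(50, 70)
  nr <- ceiling(50 / 16); nc <- ceiling(70 / 16)
  scores <- matrix(0, nr, nc)
  fig <- tile_overlay(img, 16, scores)
  expect_equal(fig$resolution, c(nr, nc))
  # constant scores tint everything equally
  d <- abs(fig$image - img)
  expect_lt(diff(range(d[, , 1])), 1e-12)
  # one hot tile: its cell is coloured differently from every other cell,
  # and all the cold cells share one colour
  scores2 <- scores; scores2[2, 3] <- 1
  fig2 <- tile_overlay(img, 16, scores2)
  cell_col <- function(i, j) fig2$image[(i - 1) * 16 + 2, (j - 1) * 16 + 2, ]
  hot <- cell_col(2, 3)
  cold <- lapply(setdiff(seq_len(nr * nc), (3 - 1) * nr + 2), function(idx) {
    cell_col(((idx - 1) %% nr) + 1, ((idx - 1) %/% nr) + 1)
  })
  expect_true(all(vapply(cold, function(cc) identical(cc, cold[[1]]), logical(1))))
  expect_false(identical(hot, cold[[1]]))
  expect_error(tile_overlay(img, 16, matrix(0, 2, 2)), "must be")
})

test_that("the student least-squares limit is the attention-weighted mean label", {
  crop <- flat_image(20, 20, c(0.5, 0.5, 0.5))
  crops <- rep(list(crop), 10)
  labels <- rep(c(0, 1), 5)   # identical inputs, balanced opposite labels
  st <- train_student(crops, attentions = rep(1, 10), labels = labels,
                      hidden = 0L, epochs = 800L, patience = 800L,
                      val_frac = 0.2, lr = 5e-3, seed = 1)
  expect_equal(predict(st, crop), 0.5, tolerance = 0.1)
})

test_that("zero-attention instances do not influence the student", {
  withr::with_seed(227, {
    crops <- lapply(1:6, function(i) array(runif(20 * 20 * 3), c(20, 20, 3)))
    labs_a <- c(1, 0, 1, 0, 1, 0)
    labs_b <- labs_a; labs_b[6] <- 1   # flip only the zero-attention crop
    att <- c(0.3, 0.2, 0.2, 0.2, 0.1, 0)
    sa <- train_student(crops, att, labs_a, hidden = 0L, epochs = 100L, seed = 2)
    sb <- train_student(crops, att, labs_b, hidden = 0L, epochs = 100L, seed = 2)
    expect_equal(predict(sa, crops[[1]]), predict(sb, crops[[1]]),
                 tolerance = 1e-10)
  })
  expect_error(train_student(list(flat_image(5, 5)), 0, 1), "zero")
})

test_that("a student separates crops carrying a visual marker", {
  withr::with_seed(229, {
    make_crop <- function(marked) {
      img <- array(runif(24 * 24 * 3, 0.6, 0.9), c(24, 24, 3))
      if (marked) for (k in 1:3) img[8:16, 8:16, k] <- img[8:16, 8:16, k] * 0.2
      img
    }
    labs <- rep(c(1, 0), each = 20)
    crops <- lapply(labs == 1, make_crop)
    st <- train_student(crops, attentions = rep(1, 40), labels = labs,
                        hidden = 8L, epochs = 200L, seed = 3)
    test_labs <- rep(c(1, 0), each = 15)
    scores <- vapply(lapply(test_labs == 1, make_crop),
                     function(cr) predict(st, cr), numeric(1))
    d <- tibble::tibble(y = test_labs, s = scores)
    expect_gte(weighted_roc(d, y, s)$auc, 0.9)
  })
})

test_that("occlusion saliency is zero for a constant student and localises a marked square", {
  crop <- flat_image(32, 32)
  sal0 <- occlusion_saliency(function(cr) 1, crop, window = 8, stride = 8)
  expect_equal(max(abs(sal0)), 0)
  # student that reads mean intensity of a known square region; the crop
  # is bright there so grey occlusion produces a drop
  crop2 <- flat_image(32, 32, c(0.2, 0.2, 0.2))
  crop2[9:16, 9:16, ] <- 0.9
  student <- function(cr) mean(cr[9:16, 9:16, 1])
  sal <- occlusion_saliency(student, crop2, window = 8, stride = 4)
  region <- matrix(FALSE, 32, 32); region[9:16, 9:16] <- TRUE
  dil <- region
  idx <- which(region, arr.ind = TRUE)
  for (o in -8:8) {
    dil[pmin(pmax(idx[, 1] + o, 1), 32) + (idx[, 2] - 1) * 32] <- TRUE
    dil[idx[, 1] + (pmin(pmax(idx[, 2] + o, 1), 32) - 1) * 32] <- TRUE
  }
  expect_gte(sum(abs(sal[dil])) / sum(abs(sal)), 0.8)
})

test_that("stride equal to window covers each pixel exactly once", {
  crop <- flat_image(16, 16, c(0.3, 0.3, 0.3))
  student <- function(cr) mean(cr)
  sal <- occlusion_saliency(student, crop, window = 8, stride = 8)
  # drop of occluding any window of a constant image with its own mean is 0
  expect_equal(max(abs(sal)), 0, tolerance = 1e-12)
  # a gradient image: saliency equals the single-window drop per block
  withr::with_seed(233, {
    img <- array(runif(16 * 16 * 3), c(16, 16, 3))
    sal2 <- occlusion_saliency(function(cr) mean(cr[, , 1]), img,
                               window = 8, stride = 8)
    base <- mean(img[, , 1])
    occ <- img
    occ[1:8, 1:8, 1] <- mean(img[, , 1])  # fill is the mean colour per channel
    drop <- base - mean(occ[, , 1])
    expect_equal(unique(as.vector(sal2[1:8, 1:8])), drop, tolerance = 1e-12)
  })
  # saliency confined to a mask sums only over in-mask pixels
  m <- matrix(FALSE, 16, 16); m[1:8, ] <- TRUE
  sal3 <- occlusion_saliency(function(cr) mean(cr[, , 1]), crop,
                             window = 8, stride = 8, mask = m)
  expect_true(all(sal3[!m] == 0))
})
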