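test_that("mirror padding reflects without duplicating the edge voxel", {
  row <- array(c(1, 2, 3), c(3, 1, 1))
  padded <- mirror_pad(row, c(2, 0))
  expect_equal(as.numeric(padded[, 1, 1]), c(3, 2, 1, 2, 3, 2, 1))
  x <- array(rnorm(5 * 6 * 3), c(5, 6, 3))
  expect_identical(mirror_pad(x, 0), x)
  p <- mirror_pad(x, c(2, 3))
  expect_identical(dim(p), c(5L + 4L, 6L + 6L, 3L))
  expect_identical(p[3:7, 4:9, ], x)
  expect_error(mirror_pad(x, 5), "margin")
})

test_that("tile plans obey ceiling coverage arithmetic", {
  p1 <- plan_tiles(c(512, 512), tile_output_shape = 328)
  expect_identical(p1$counts, c(2L, 2L))
  expect_identical(nrow(p1$offsets), 4L)

  # the published 9-patch configuration: output window 172 < 512 / 2
  p2 <- plan_tiles(c(512, 512), tile_output_shape = 172)
  expect_identical(p2$counts, c(3L, 3L))
  expect_identical(nrow(p2$offsets), 9L)
  cnt <- femurseg:::tile_visit_counts(p2)
  expect_gte(min(cnt), 1L)

  # single tile once the output window covers the image
  p3 <- plan_tiles(c(100, 100), tile_output_shape = 128)
  expect_identical(nrow(p3$offsets), 1L)

  # spec-derived plan: windows admissible, offsets inside mirrored support
  spec <- architecture_spec(2, F = 2, L = 2, padding = "unpadded")
  p4 <- plan_tiles(c(96, 96), spec)
  expect_identical(as.integer(output_shape(spec, p4$tile_input)),
                   as.integer(p4$tile_output))
  expect_gte(min(femurseg:::tile_visit_counts(p4)), 1L)
  expect_true(all(p4$offsets$ox + p4$tile_input[1] <= 96 + 2 * p4$margin[1]))
  expect_error(plan_tiles(c(64, 64), architecture_spec(2, padding = "padded")),
               "unpadded")
})

test_that("tiled inference averages overlapping constant stubs exactly", {
  v <- image_volume(array(rnorm(30 * 30 * 3), c(30, 30, 3)))
  plan <- plan_tiles(c(30, 30), tile_input_shape = 20, tile_output_shape = 16)
  # constant stub: averaging is the identity
  pm <- predict_tiled(stub_constant(0.37, margin = 2), v, plan)
  expect_equal(max(abs(pm$data - 0.37)), 0, tolerance = 1e-12)
  expect_identical(dim(pm$data), dim(v$data))

  # tile-index-dependent constants: overlaps equal the arithmetic mean
  consts <- seq(0.1, 0.4, length.out = nrow(plan$offsets))
  counter <- new.env(); counter$i <- 0L
  stub <- structure(list(spec = NULL, norm = NULL,
                         forward_fun = function(x) {
                           counter$i <- counter$i + 1L
                           k <- (counter$i - 1L) %% length(consts) + 1L
                           matrix(consts[k], 16, 16)
                         }),
                    class = "femur_cnn")
  pm2 <- predict_tiled(stub, v, plan)
  # oracle accumulation over the plan's output windows
  acc <- matrix(0, 30, 30); cnt <- matrix(0, 30, 30)
  for (r in seq_len(nrow(plan$offsets))) {
    ix <- plan$offsets$ox[r] + 1:16; iy <- plan$offsets$oy[r] + 1:16
    acc[ix, iy] <- acc[ix, iy] + consts[r]
    cnt[ix, iy] <- cnt[ix, iy] + 1
  }
  expect_gte(min(cnt), 1)
  expect_equal(pm2$data[, , 2], acc / cnt, tolerance = 1e-12)
})

test_that("tiled and whole-image inference agree for invariant stubs", {
  set.seed(19)
  v <- image_volume(array(rnorm(40 * 34 * 4), c(40, 34, 4)))
  stub <- stub_mean3()
  plan <- plan_tiles(c(40, 34), tile_input_shape = c(22, 20),
                     tile_output_shape = c(20, 18))
  tiled <- predict_tiled(stub, v, plan)
  # oracle: one pass over the full mirror-padded stack per slice
  for (k in c(1, 3)) {
    ks <- pmin(pmax((k - 1):(k + 1), 1), 4)
    stack <- mirror_pad(array(v$data[, , ks], c(40, 34, 3)), 1)
    whole <- stub$forward_fun(stack)
    expect_equal(tiled$data[, , k], whole, tolerance = 1e-12)
  }
})

test_that("padded whole-image inference matches shapes and normalization", {
  spec <- architecture_spec(3, F = 1, L = 2, padding = "padded")
  m <- build_network(spec, seed = 2)
  v <- image_volume(array(rnorm(20 * 20 * 10), c(20, 20, 10)))  # not 2^L
  pm <- predict_padded(m, v)
  expect_identical(dim(pm$data), dim(v$data))
  expect_true(all(pm$data >= 0 & pm$data <= 1))

  spec2 <- architecture_spec(2, F = 1, L = 1, padding = "padded")
  m2 <- build_network(spec2, seed = 2)
  pm2 <- predict_padded(m2, v)
  expect_identical(dim(pm2$data), dim(v$data))

  expect_error(
    predict_padded(build_network(architecture_spec(2, F = 1, L = 1,
                                                   padding = "unpadded"),
                                 seed = 1), v),
    "unpadded")
})

test_that("padded and tiled paths agree on a constant-function stub", {
  v <- image_volume(array(rnorm(24 * 24 * 3), c(24, 24, 3)))
  c_pad <- stub_constant(0.6, margin = 0)
  pm_pad <- predict_padded(c_pad, v)
  plan <- plan_tiles(c(24, 24), tile_input_shape = 18, tile_output_shape = 14)
  pm_tile <- predict_tiled(stub_constant(0.6, margin = 2), v, plan)
  expect_equal(pm_pad$data, pm_tile$data, tolerance = 1e-12)
})

test_that("binarize uses a strict threshold with validated input", {
  p <- probability_map(array(c(0.2, 0.5, 0.8, 1), c(4, 1, 1)))
  expect_equal(as.numeric(binarize(p, 0.5)$data), c(0, 0, 1, 1))
  expect_true(all(binarize(probability_map(array(runif(100, 0.01, 1),
                                                 c(10, 10, 1))), 0)$data == 1))
  expect_true(all(binarize(p, 1)$data == 0))
  expect_error(binarize(p, 1.5), "\\[0, 1\\]")

  set.seed(4)
  big <- probability_map(array(runif(1e6), c(100, 100, 100)))
  expect_lt(abs(mean(binarize(big, 0.5)$data) - 0.5), 0.01)
})

test_that("largest_component keeps the biggest cluster and is idempotent", {
  a <- array(0, c(12, 12, 12))
  a[1:3, 1:3, 1:3] <- 1                         # 27 voxels
  a[8:9, 8:9, 8:9] <- 1                         # 8 voxels
  m <- label_mask(a)
  lc <- largest_component(m, 26)
  expect_equal(sum(lc$data), 27)
  expect_equal(sum(lc$data[8:9, 8:9, 8:9]), 0)
  expect_identical(largest_component(lc, 26)$data, lc$data)
  # subset property: never adds foreground
  expect_true(all(lc$data <= m$data))

  single <- label_mask(array(rep(c(0, 1), c(50, 50)), c(10, 10, 1)))
  expect_identical(largest_component(single)$data, single$data)
  expect_warning(largest_component(label_mask(array(0, c(4, 4, 4)))),
                 "empty")
  expect_error(largest_component(m, 10), "connectivity")

  # 6 vs 26 connectivity: diagonal touch is one component only under 26
  d <- array(0, c(6, 6, 2))
  d[1:2, 1:2, 1] <- 1; d[3, 3, 1] <- 1
  expect_equal(sum(largest_component(label_mask(d), 6)$data), 4)
  expect_equal(sum(largest_component(label_mask(d), 26)$data), 5)
})

test_that("post-processing cannot increase false positives", {
  set.seed(6)
  gt <- array(0, c(16, 16, 8)); gt[4:12, 4:12, 3:6] <- 1
  noisy <- gt
  noisy[1, 1, 1] <- 1; noisy[16, 16, 8] <- 1    # satellite errors
  pred <- label_mask(noisy)
  post <- largest_component(pred)
  cc_raw <- confusion(pred, label_mask(gt))
  cc_post <- confusion(post, label_mask(gt))
  expect_lte(cc_post$FP, cc_raw$FP)
  expect_gte(dsc(cc_post), dsc(cc_raw))
})

test_that("predict_subject composes thresholding and post-processing", {
  v <- image_volume(array(rnorm(20 * 20 * 4), c(20, 20, 4)))
  spec3 <- architecture_spec(3, F = 1, L = 1, padding = "padded")
  m3 <- build_network(spec3, seed = 7)
  res <- predict_subject(m3, v, t = 0.5)
  # 3D default: no post-processing; equals binarize of the probability map
  expect_identical(res$mask$data, binarize(res$prob, 0.5)$data)

  # 2D default applies the component filter
  stub2 <- stub_constant(0, margin = 0)
  stub2$spec <- architecture_spec(2, F = 1, L = 1, padding = "padded")
  stub2$forward_fun <- function(x) {
    out <- matrix(0, dim(x)[1], dim(x)[2])
    out[2:8, 2:8] <- 0.9; out[15, 15] <- 0.9    # blob + satellite
    out
  }
  res2 <- predict_subject(stub2, v, t = 0.5)
  expect_equal(sum(res2$mask$data[15, 15, ]), 0)
  res2_raw <- predict_subject(stub2, v, t = 0.5, postprocess = FALSE)
  expect_gt(sum(res2_raw$mask$data[15, 15, ]), 0)

  # upsample-then-threshold of a constant map is threshold-invariant
  stubc <- structure(list(spec = spec3, norm = NULL,
                          forward_fun = function(x) array(0.7, dim(x)[1:3])),
                     class = "femur_cnn")
  resc <- predict_subject(stubc, v, t = 0.5, original_grid = c(40, 40))
  expect_identical(dim(resc$mask$data), c(40L, 40L, 4L))
  expect_true(all(resc$mask$data == 1))
})
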