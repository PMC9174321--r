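test_that("Dice loss matches its closed form on worked cases", {
  eps <- 1e-8
  m <- matrix(0, 20, 20)
  m[1:10, 1:10] <- 1                       # 100 positive pixels
  expect_equal(dice_loss(m, m), 1 - 2 * (100 + eps) / (200 + eps))
  expect_lt(dice_loss(m, m), 1e-9)
  disj <- matrix(0, 20, 20); disj[11:20, 11:20] <- 1
  expect_equal(dice_loss(m, disj), 1 - 2 * eps / (200 + eps))
  expect_gt(dice_loss(m, disj), 1 - 1e-9)
  # half overlap in expectation: pred = [0.5, 0.5], truth = [1, 0]
  expect_equal(dice_loss(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1)),
               1 - 2 * (0.5 + eps) / (2 + eps))
  expect_equal(dice_loss(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1)), 0.5,
               tolerance = 1e-7)
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("Dice loss is bounded and permutation-symmetric", {
  set.seed(4)
  for (i in 1:20) {
    p <- matrix(runif(64), 8, 8)
    y <- matrix(rbinom(64, 1, 0.3), 8, 8)
    l <- dice_loss(p, y)
    expect_gte(l, 0); expect_lte(l, 1)
    perm <- sample(64)
    expect_equal(dice_loss(matrix(p[perm], 8), matrix(y[perm], 8)), l)
  }
})

test_that("U-net construction obeys its shape and determinism contracts", {
  cfg <- seg_train_config(depth = 3, base_channels = 8, seed = 9)
  m1 <- build_unet(cfg)
  m2 <- build_unet(cfg)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_unet(seg_train_config(depth = 3, base_channels = 8, seed = 10))
  expect_false(identical(m1$weights, m3$weights))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  h <- predict_heatmap(m1, img)
  expect_equal(dim(h), c(64, 64))
  expect_true(all(h >= 0 & h <= 1))
  # depth-incompatible input
  expect_error(predict_heatmap(m1, array(0.5, c(60, 60, 3))), "divisible")
  # constant input through convolutions: pixels whose receptive field
  # avoids the zero-padded border are identical (translation equivariance);
  # a shallow net on a large tile keeps the center field border-free
  ms <- build_unet(seg_train_config(depth = 2, base_channels = 4, seed = 9))
  hc <- predict_heatmap(ms, array(0.4, c(128, 128, 3)))
  interior <- hc[57:72, 57:72]
  expect_lt(diff(range(interior)), 1e-10)
})

test_that("zero training epochs return the untouched initialization", {
  cfg <- seg_train_config(depth = 2, base_channels = 4, epochs = 0, seed = 3)
  pairs <- lapply(1:4, function(i)
    generate_nuclei_tile(small_sim_config(seed = i), "low", seed = i))
  m <- train_unet(pairs, cfg)
  expect_identical(m$weights, build_unet(cfg)$weights)
  expect_equal(nrow(m$history), 0)
})

test_that("a single repeated pair is memorized to near-perfect Dice", {
  cfg <- small_sim_config(seed = 6, nuclei_per_tile = 8)
  st <- generate_nuclei_tile(cfg, "low", seed = 12)
  pairs <- rep(list(st), 8)
  m <- train_unet(pairs, seg_train_config(depth = 2, base_channels = 8,
                                          epochs = 16, val_fraction = 0,
                                          augment = FALSE, seed = 2))
  train_dice <- 1 - dice_loss(predict_heatmap(m, st), st$mask)
  expect_gte(train_dice, 0.95)
})

test_that("model weights round-trip through serialization", {
  cfg <- seg_train_config(depth = 2, base_channels = 4, seed = 5)
  m <- build_unet(cfg)
  tmp <- tempfile(fileext = ".rds")
  saveRDS(m, tmp)
  m2 <- readRDS(tmp)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict_heatmap(m, img), predict_heatmap(m2, img))
  unlink(tmp)
})
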