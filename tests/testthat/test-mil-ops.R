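test_that("four-channel assembly round-trips and validates", {
  rgb <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  hm <- matrix(runif(32 * 32), 32)
  t4 <- assemble_four_channel(rgb, hm)
  expect_equal(dim(t4), c(32, 32, 4))
  sp <- split_four_channel(t4)
  expect_equal(sp$rgb[, , 1:3], rgb, tolerance = 1e-12)
  expect_equal(sp$heatmap, hm)
  # zero heatmap leaves RGB untouched and channel 4 all-zero
  z <- assemble_four_channel(rgb, matrix(0, 32, 32))
  expect_true(all(z[, , 4] == 0))
  expect_equal(z[, , 1:3], rgb / 255)
  expect_error(assemble_four_channel(rgb, matrix(0, 16, 16)), "sizes")
  expect_error(assemble_four_channel(rgb, matrix(2, 32, 32)), "0, 1")
})

test_that("generalized-mean aggregation matches worked arithmetic", {
  expect_equal(aggregate_scores(0.37, p = 5), 0.37)       # single element
  expect_equal(aggregate_scores(c(1, 2, 3), p = 3), 36^(1 / 3))
  expect_equal(aggregate_scores(c(0.2, 0.3), p = 1), 0.5) # plain sum
  expect_error(aggregate_scores(numeric(0)), "empty")
  expect_error(aggregate_scores(1, p = 0.5), "'p'")
  # power-mean variant
  expect_equal(aggregate_scores(c(1, 2, 3), p = 3, power_mean = TRUE),
               (36 / 3)^(1 / 3))
})

test_that("aggregation invariants hold on random score sets", {
  set.seed(8)
  for (i in 1:25) {
    s <- runif(sample(2:12, 1), 0, 3)
    p <- sample(c(1, 2, 3, 5), 1)
    S <- aggregate_scores(s, p)
    expect_equal(aggregate_scores(sample(s), p), S)          # permutation
    expect_gte(S + 1e-12, max(s))                            # lower bound
    expect_lte(S, length(s)^(1 / p) * max(s) + 1e-12)        # upper bound
    bump <- s; j <- sample(seq_along(s), 1); bump[j] <- bump[j] + 0.1
    expect_gte(aggregate_scores(bump, p), S)                 # monotone
    # p -> Inf approaches the maximum
    expect_equal(aggregate_scores(s, 50), max(s), tolerance = 0.06)
  }
  # signed behaviour: odd symmetric scores cancel
  expect_equal(aggregate_scores(c(-2, 2), p = 3), 0)
  expect_equal(aggregate_scores(c(-1, -2, -3), p = 3), -(36^(1 / 3)))
})

test_that("classification thresholds the sigmoid with the documented tie rule", {
  r <- classify_bag(0)
  expect_equal(r$activated, 0.5)
  expect_equal(r$predicted_class, 1L)            # 0.5 > 0.4457
  r2 <- classify_bag(-10)
  expect_equal(r2$activated, 1 / (1 + exp(10)), tolerance = 1e-12)
  expect_equal(round(r2$activated, 7), 0.0000454)
  expect_equal(r2$predicted_class, 0L)
  # a tie at exactly t goes to the non-exceeding (low-score) class
  t <- 0.4457
  r3 <- classify_bag(qlogis(t), t)
  expect_equal(r3$activated, t)
  expect_equal(r3$predicted_class, 0L)
})

test_that("probability transform has the stated fixed points and slope", {
  t <- 0.4457
  expect_equal(transform_probability(0, t), 1)
  expect_equal(transform_probability(t, t), 0.5)
  expect_equal(transform_probability(1, t), 0)
  expect_equal(transform_probability(0.2, t),
               ((t - 0.2) / t + 1) * 0.5)
  expect_equal(transform_probability(0.2, t), 0.77563, tolerance = 1e-5)
  # both branches agree at the junction
  expect_equal(transform_probability(t - 1e-12, t),
               transform_probability(t + 1e-12, t), tolerance = 1e-9)
  # continuity and strict monotonicity on a dense grid
  g <- seq(0, 1, length.out = 1000)
  pg <- transform_probability(g, t)
  expect_true(all(diff(pg) < 0))
  expect_lt(max(abs(diff(pg))), 0.01)
  expect_error(transform_probability(1.2, t), "\\[0, 1\\]")
  # classifier and transform agree: p < 0.5 iff activated > t
  set.seed(2)
  a <- runif(200)
  expect_equal(transform_probability(a, t) < 0.5, a > t)
})

test_that("MIL loss reproduces cross-entropy and L2 arithmetic", {
  expect_equal(mil_loss(1, 1, alpha = 0), 0, tolerance = 1e-6)
  expect_equal(mil_loss(0.5, 1, alpha = 0), -log(0.5))
  expect_equal(mil_loss(0.5, 1, alpha = 0), 0.69315, tolerance = 1e-5)
  expect_equal(mil_loss(c(1, 1), c(1, 1), weights = c(1, 2), alpha = 0.02),
               0.02 * 5, tolerance = 1e-5)
  # loss never drops below the regularization floor
  set.seed(1)
  w <- rnorm(10)
  for (i in 1:10) {
    p <- runif(3); y <- rbinom(3, 1, 0.5)
    expect_gte(mil_loss(p, y, w, alpha = 0.02), 0.02 * sum(w^2))
  }
  expect_error(mil_loss(numeric(0), numeric(0)), "empty")
})

test_that("learning-rate schedule follows the halving decay", {
  expect_equal(lr_schedule(0), 1e-4)
  expect_equal(lr_schedule(10), 5e-5)
  expect_equal(lr_schedule(25), 2.5e-5)
  expect_equal(lr_schedule(0:9), rep(1e-4, 10))
})

test_that("backbone construction is deterministic with contractual shapes", {
  b1 <- build_backbone("tiny", 4, seed = 3)
  b2 <- build_backbone("tiny", 4, seed = 3)
  expect_identical(b1$weights, b2$weights)
  expect_false(identical(b1$weights, build_backbone("tiny", 4, 4)$weights))
  tile <- array(runif(64 * 64 * 4), c(64, 64, 4))
  s <- score_tiles(b1, list(tile))
  expect_length(s, 1)
  expect_true(is.finite(s))
  expect_error(build_backbone("huge"), "arg")
})

test_that("standard variant matches the published parameter arithmetic", {
  b <- build_backbone("standard", 4, seed = 1)
  # independent count from the inverted-residual table
  # (t, c, n, s) rows of MobileNetV2, width 1.0, 4-channel stem,
  # conv + bias + per-channel scale/shift after every convolution,
  # 1280-channel head and a single-unit linear readout.
  conv_p <- function(cin, cout, k, groups = 1) cin / groups * k * k * cout
  count <- 0
  add_conv <- function(cin, cout, k, groups = 1)
    conv_p(cin, cout, k, groups) + cout + 2 * cout  # bias + affine
  count <- count + add_conv(4, 32, 3)
  tbl <- rbind(c(1, 16, 1), c(6, 24, 2), c(6, 32, 3), c(6, 64, 4),
               c(6, 96, 3), c(6, 160, 3), c(6, 320, 1))
  prev <- 32
  for (r in seq_len(nrow(tbl))) {
    t <- tbl[r, 1]; c_out <- tbl[r, 2]; n <- tbl[r, 3]
    for (i in seq_len(n)) {
      hid <- prev * t
      if (t != 1) count <- count + add_conv(prev, hid, 1)
      count <- count + add_conv(hid, hid, 3, groups = hid)
      count <- count + add_conv(hid, c_out, 1)
      prev <- c_out
    }
  }
  count <- count + add_conv(320, 1280, 1) + 1280 + 1
  expect_lt(abs(backbone_nparams(b) - count) / count, 0.10)
  expect_equal(backbone_nparams(b), count)  # exact by construction
})

test_that("slide prediction satisfies aggregation identities", {
  b <- build_backbone("tiny", 4, seed = 6)
  cfg <- small_sim_config(seed = 13)
  bag <- generate_bag(cfg, "high", seed = 5)
  one <- predict_slide(b, bag$tiles[1])
  expect_equal(one$aggregate, one$tile_scores[1])
  sc <- predict_slide(b, bag)
  expect_equal(sc$activated, plogis(sc$aggregate))
  expect_equal(sc$prob, transform_probability(sc$activated, 0.4457))
  expect_equal(sc$predicted_class, as.integer(sc$activated > 0.4457))
  # duplicating every tile k times scales S by k^(1/p) when scores share sign
  s <- sc$tile_scores
  if (all(s < 0) || all(s > 0)) {
    S3 <- predict_slide(b, c(bag$tiles, bag$tiles, bag$tiles))$aggregate
    expect_equal(S3, sc$aggregate * 3^(1 / 3), tolerance = 1e-9)
  }
  # inference is bit-stable
  expect_identical(predict_slide(b, bag), predict_slide(b, bag))
  expect_error(predict_slide(b, list()), "tiles|empty")
})

test_that("training rejects degenerate bag sets", {
  cfg <- small_sim_config(seed = 1)
  b1 <- generate_bag(cfg, "low", seed = 1)
  b2 <- generate_bag(cfg, "low", seed = 2)
  expect_error(train_mil(list(b1, b2), mil_config(epochs = 1)),
               "both labels")
  expect_error(train_mil(list(b1), mil_config(epochs = 1)), "2 bags")
  expect_error(mil_config(bag_batch_size = 2), "bag_batch_size")
  expect_error(mil_config(threshold = 1.5), "threshold")
})

test_that("a short MIL run is deterministic and records its schedule", {
  cfg <- small_sim_config(seed = 4)
  bags <- generate_bags(cfg, 3, seed = 20)
  mc <- mil_config(epochs = 2, seed = 11)
  m1 <- train_mil(bags, mc)
  m2 <- train_mil(bags, mc)
  expect_identical(m1$backbone$weights, m2$backbone$weights)
  expect_equal(m1$history$lr, lr_schedule(0:1))
  expect_identical(predict(m1, bags), predict(m2, bags))
})
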