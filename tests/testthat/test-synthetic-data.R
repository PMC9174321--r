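test_that("tile generation is deterministic and respects forced counts", {
  cfg <- slide_sim_config(seed = 11)
  a <- generate_nuclei_tile(cfg, "high", is_signal = TRUE, seed = 5)
  b <- generate_nuclei_tile(cfg, "high", is_signal = TRUE, seed = 5)
  expect_identical(a, b)
  expect_equal(dim(a$image), c(64, 64, 3))
  expect_true(all(a$mask %in% c(0, 1)))
  # empty scene: no nuclei, no immune cells -> mask all zeros
  cfg0 <- slide_sim_config(immune_density = 0, seed = 11)
  e <- generate_nuclei_tile(cfg0, "low", is_signal = FALSE, seed = 2,
                            n_nuclei = 0)
  expect_identical(unique(as.vector(e$mask)), 0)
  expect_equal(nrow(e$nuclei), 0)
})

test_that("invalid simulator parameters are rejected", {
  expect_error(slide_sim_config(tile_size = 16), "tile_size")
  expect_error(slide_sim_config(signal_fraction = 1.2), "signal_fraction")
  expect_error(slide_sim_config(n_tiles = 0), "n_tiles")
})

test_that("signal tiles have larger and darker nuclei than background", {
  cfg <- slide_sim_config(seed = 3)
  specs <- function(sig) do.call(rbind, lapply(1:150, function(i)
    generate_nuclei_tile(cfg, "high", is_signal = sig,
                         seed = 1000 * sig + i)$nuclei))
  s <- specs(TRUE); b <- specs(FALSE)
  area <- function(x) mean(pi * x$r_major * x$r_minor)
  darkness <- function(x) mean(255 - x$intensity)
  expect_gt(area(s), area(b))
  expect_gt(darkness(s), darkness(b))
  # immune infiltration is denser outside signal tiles
  expect_gt(mean(b$type == "immune_cell"), mean(s$type == "immune_cell"))
})

test_that("bags carry one label and the configured signal composition", {
  cfg <- slide_sim_config(n_tiles = 16, signal_fraction = 0.5, seed = 21)
  hi <- generate_bag(cfg, "high", seed = 7)
  lo <- generate_bag(cfg, "low", seed = 7)
  expect_s3_class(hi, "mil_bag")
  expect_length(hi$tiles, 16)
  expect_equal(sum(hi$provenance$is_signal), 8)   # ceiling(0.5 * 16)
  expect_equal(sum(lo$provenance$is_signal), 0)
  expect_equal(hi$label, 0L)  # high risk = bad outcome
  expect_equal(lo$label, 1L)
  # label lives on the bag, never per tile
  expect_null(hi$provenance$label)
  expect_true(all(vapply(hi$tiles, function(t) dim(t)[3], numeric(1)) == 4))
  # fractional signal count rounds up
  cfg2 <- slide_sim_config(n_tiles = 5, signal_fraction = 0.5, seed = 1)
  expect_equal(sum(generate_bag(cfg2, "high")$provenance$is_signal), 3)
})

test_that("null signal fraction yields indistinguishable classes", {
  cfg <- small_sim_config(seed = 5, signal_fraction = 0)
  bags <- generate_bags(cfg, 100, seed = 42)
  labs <- vapply(bags, function(b) b$label, integer(1))
  # any fixed classifier: an untrained backbone at a fixed seed
  bb <- build_backbone("tiny", 4, seed = 77)
  acts <- vapply(bags, function(b) predict_slide(bb, b)$activated,
                 numeric(1))
  auc <- rank_sum_auc(acts[labs == 0], acts[labs == 1])
  expect_lt(abs(auc - 0.5), 0.08)
})

test_that("survival simulator hits its censoring target and hazards", {
  cfg <- survival_sim_config(n_subjects = 1500, censoring_rate = 0.3,
                             seed = 9)
  coh <- generate_survival_cohort(cfg)
  expect_equal(nrow(coh), 1500)
  expect_true(all(coh$time > 0))
  expect_lt(abs(mean(coh$event == 0) - 0.3), 0.05)
  # provenance: true linear predictor recorded for every subject
  expect_true(all(is.finite(coh$true_linear_predictor)))
  expect_equal(coh$true_linear_predictor,
               log(2) * coh$marker + 0.3 * (coh$stage - 1))
  # zero censoring -> every event observed
  c0 <- generate_survival_cohort(survival_sim_config(n_subjects = 100,
                                                     censoring_rate = 0,
                                                     seed = 2))
  expect_true(all(c0$event == 1))
  # determinism
  expect_identical(generate_survival_cohort(cfg),
                   generate_survival_cohort(cfg))
})

test_that("survival simulator rejects invalid configurations", {
  expect_error(survival_sim_config(censoring_rate = 1), "censoring_rate")
  expect_error(survival_sim_config(n_subjects = 1), "n_subjects")
  expect_error(survival_sim_config(baseline_shape = 0), "baseline_shape")
})
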