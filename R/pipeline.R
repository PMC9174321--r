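# End-to-end pipeline: simulate -> train-seg -> segment -> train-mil ->
# predict -> evaluate, with on-disk stage outputs, a run manifest, and
# resumability. Every random draw derives from the single master seed, so
# two runs with an identical configuration produce bit-identical CSV/JSON
# outputs.

stage_done <- function(out_dir, stage) {
  file.exists(file.path(out_dir, stage, ".done"))
}

mark_done <- function(out_dir, stage) {
  writeLines("done", file.path(out_dir, stage, ".done"))
}

stage_dir <- function(out_dir, stage) {
  d <- file.path(out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

pipeline_stages <- c("simulate", "train_seg", "segment", "train_mil",
                     "predict", "evaluate")

read_manifest_csv <- function(out_dir) {
  read.csv(file.path(out_dir, "simulate", "manifest.csv"),
           stringsAsFactors = FALSE)
}

# Reassemble four-channel bags from the on-disk tiles and heatmaps.
load_pipeline_bags <- function(out_dir, split) {
  man <- read_manifest_csv(out_dir)
  sim_d <- file.path(out_dir, "simulate")
  ids <- unique(man$slide_id[man$split == split])
  lapply(ids, function(sid) {
    rows <- man[man$slide_id == sid, ]
    tiles <- lapply(seq_len(nrow(rows)), function(k) {
      img <- read_image(file.path(sim_d, rows$tile_path[k]))
      hm <- luminance(read_image(file.path(out_dir, "segment",
                                           sub("_tile", "_heat",
                                               rows$tile_path[k])))) / 255
      assemble_four_channel(img, pmin(pmax(hm, 0), 1))
    })
    structure(list(slide_id = sid, tiles = tiles,
                   label = rows$bag_label[1],
                   risk_class = if (rows$bag_label[1] == 1) "low" else "high",
                   provenance = data.frame(
                     slide_id = sid, tile_index = seq_len(nrow(rows)),
                     x = rows$x, y = rows$y, is_signal = rows$is_signal,
                     stringsAsFactors = FALSE)),
              class = "mil_bag")
  })
}

#' Run the synthetic pipeline end to end
#'
#' Executes simulate, train-seg, segment, train-mil, predict and evaluate
#' in order, writing each stage's outputs (PNG tiles, masks and heatmaps,
#' CSV manifests and tables, RDS checkpoints, JSON metrics) under
#' \code{out_dir} together with a run manifest. Stages whose outputs
#' already exist are skipped unless \code{force = TRUE}; the manifest
#' notes the reuse.
#'
#' @param config A \code{pipeline_config} (see \code{\link{load_config}},
#'   \code{\link{default_config}}).
#' @param out_dir Output directory (defaults to \code{config$out_dir}).
#' @param force Re-run stages even when their outputs exist.
#' @param quiet Suppress per-stage messages.
#' @param upto Optional name of the last stage to execute (one of
#'   "simulate", "train_seg", "segment", "train_mil", "predict",
#'   "evaluate").
#' @return The run manifest (list), invisibly; the metrics table is at
#'   \code{<out_dir>/evaluate/metrics.csv}.
#' @export
run_pipeline <- function(config = default_config(), out_dir = config$out_dir,
                         force = FALSE, quiet = FALSE, upto = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  config <- validate_config(config)
  if (!is.null(upto)) upto <- match.arg(upto, pipeline_stages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "slidemil", version = "0.1.0",
                   config_hash = config_hash(config), stages = list())
  say <- function(...) if (!quiet) message("[slidemil] ", ...)
  sim <- config$simulation
  scfg <- slide_sim_config(n_tiles = sim$n_tiles, tile_size = sim$tile_size,
                           signal_fraction = sim$signal_fraction,
                           stroma_probability = sim$stroma_probability,
                           immune_density = sim$immune_density,
                           nuclei_per_tile = sim$nuclei_per_tile,
                           seed = derive_seed(config$seed, "simulate"))

  stage_fns <- list(
    simulate = function(d) {
      write_slide_set <- function(split, n_per_class, seed) {
        rows <- list()
        for (cls in c("low", "high")) for (i in seq_len(n_per_class)) {
          sid <- sprintf("%s_%s_%03d", split, cls, i)
          bag <- generate_bag(scfg, cls, slide_id = sid,
                              seed = derive_seed(seed, sid))
          for (k in seq_along(bag$rgb_tiles)) {
            tp <- file.path(d, sprintf("%s_tile%03d.png", sid, k))
            mp <- file.path(d, sprintf("%s_mask%03d.png", sid, k))
            write_image(bag$rgb_tiles[[k]], tp)
            write_image(bag$masks[[k]] * 255, mp)
            rows[[length(rows) + 1L]] <- data.frame(
              split = split, slide_id = sid, tile_path = basename(tp),
              mask_path = basename(mp), x = bag$provenance$x[k],
              y = bag$provenance$y[k],
              is_signal = bag$provenance$is_signal[k],
              bag_label = bag$label, stringsAsFactors = FALSE)
          }
        }
        do.call(rbind, rows)
      }
      man <- rbind(
        write_slide_set("train", sim$n_slides_per_class,
                        derive_seed(config$seed, "sim-train")),
        write_slide_set("test", sim$n_test_slides_per_class,
                        derive_seed(config$seed, "sim-test")))
      write.csv(man, file.path(d, "manifest.csv"), row.names = FALSE)
      seg_rows <- lapply(seq_len(sim$n_seg_pairs), function(i) {
        st <- generate_nuclei_tile(scfg, if (i %% 3 == 0) "high" else "low",
                                   is_signal = i %% 2 == 0,
                                   seed = derive_seed(config$seed,
                                                      paste0("seg", i)))
        tp <- file.path(d, sprintf("seg_%03d_img.png", i))
        mp <- file.path(d, sprintf("seg_%03d_mask.png", i))
        write_image(st$image, tp)
        write_image(st$mask * 255, mp)
        data.frame(image = basename(tp), mask = basename(mp),
                   stringsAsFactors = FALSE)
      })
      write.csv(do.call(rbind, seg_rows), file.path(d, "seg_pairs.csv"),
                row.names = FALSE)
      # survival cohort for the test slides: hazard driven by true class
      test_ids <- unique(man$slide_id[man$split == "test"])
      true_high <- as.integer(grepl("_high_", test_ids))
      svcfg <- survival_sim_config(
        n_subjects = length(test_ids),
        log_hazard_ratios = c(marker = sim$log_hazard_ratio, stage = 0.3),
        censoring_rate = sim$censoring_rate,
        seed = derive_seed(config$seed, "survival"))
      cohort <- generate_survival_cohort(svcfg, marker = true_high)
      cohort$id <- test_ids
      write.csv(cohort, file.path(d, "survival.csv"), row.names = FALSE)
      list(n_tiles = nrow(man), n_seg_pairs = sim$n_seg_pairs,
           n_subjects = nrow(cohort))
    },

    train_seg = function(d) {
      sim_d <- file.path(out_dir, "simulate")
      pairs_df <- read.csv(file.path(sim_d, "seg_pairs.csv"),
                           stringsAsFactors = FALSE)
      pairs <- lapply(seq_len(nrow(pairs_df)), function(i) {
        list(image = read_image(file.path(sim_d, pairs_df$image[i])),
             mask = round(luminance(read_image(
               file.path(sim_d, pairs_df$mask[i]))) / 255))
      })
      seg <- config$segmentation
      um <- train_unet(pairs, seg_train_config(
        depth = seg$depth, base_channels = seg$base_channels,
        epochs = seg$epochs, learning_rate = seg$learning_rate,
        epsilon = seg$epsilon, val_fraction = seg$val_fraction,
        augment = seg$augment,
        seed = derive_seed(config$seed, "train-seg")))
      saveRDS(um, file.path(d, "unet.rds"))
      write.csv(um$history, file.path(d, "history.csv"), row.names = FALSE)
      list(n_pairs = length(pairs),
           val_dice = if (nrow(um$history))
             um$history$val_dice[nrow(um$history)] else NA)
    },

    segment = function(d) {
      um <- readRDS(file.path(out_dir, "train_seg", "unet.rds"))
      man <- read_manifest_csv(out_dir)
      for (i in seq_len(nrow(man))) {
        img <- read_image(file.path(out_dir, "simulate", man$tile_path[i]))
        hm <- predict_heatmap(um, img)
        # heatmaps stored as single-channel PNG, scaled 0-255 on disk
        write_image(hm * 255,
                    file.path(d, sub("_tile", "_heat", man$tile_path[i])))
      }
      list(n_heatmaps = nrow(man))
    },

    train_mil = function(d) {
      bags <- load_pipeline_bags(out_dir, "train")
      mc <- config$mil
      mm <- train_mil(bags, mil_config(
        aggregation_exponent = mc$aggregation_exponent,
        threshold = mc$threshold, l2_alpha = mc$l2_alpha,
        initial_lr = mc$initial_lr,
        lr_halving_epochs = mc$lr_halving_epochs, epochs = mc$epochs,
        backbone_variant = mc$backbone_variant, power_mean = mc$power_mean,
        seed = derive_seed(config$seed, "train-mil")))
      saveRDS(mm, file.path(d, "mil.rds"))
      write.csv(mm$history, file.path(d, "history.csv"), row.names = FALSE)
      list(n_bags = length(bags),
           train_accuracy = if (nrow(mm$history))
             mm$history$accuracy[nrow(mm$history)] else NA)
    },

    predict = function(d) {
      mm <- readRDS(file.path(out_dir, "train_mil", "mil.rds"))
      bags <- load_pipeline_bags(out_dir, "test")
      preds <- predict(mm, bags)
      preds$true_label <- vapply(bags, function(b) b$label, integer(1))
      write.csv(preds, file.path(d, "predictions.csv"), row.names = FALSE)
      jsonlite::write_json(preds, file.path(d, "predictions.json"),
                           digits = NA)
      tile_scores <- do.call(rbind, lapply(bags, function(b)
        cbind(b$provenance, score = predict_slide(mm, b)$tile_scores)))
      write.csv(tile_scores, file.path(d, "tile_scores.csv"),
                row.names = FALSE)
      list(n_slides = nrow(preds),
           test_accuracy = mean((preds$predicted_class == 1) ==
                                (preds$true_label == 0)))
    },

    evaluate = function(d) {
      preds <- read.csv(file.path(out_dir, "predict", "predictions.csv"),
                        stringsAsFactors = FALSE)
      cohort <- read.csv(file.path(out_dir, "simulate", "survival.csv"),
                         stringsAsFactors = FALSE)
      stopifnot(all(preds$slide_id %in% cohort$id))
      cohort <- cohort[match(preds$slide_id, cohort$id), ]
      cohort$risk_score <- preds$activated
      cohort$predicted_class <- preds$predicted_class
      ev <- config$evaluation
      ok_horizon <- function(tau) {
        tau < max(cohort$time) &&
          any(cohort$time <= tau & cohort$event == 1) &&
          any(cohort$time > tau)
      }
      horizons <- Filter(ok_horizon, ev$horizons)
      lr <- tryCatch(logrank_test(cohort, "predicted_class"),
                     error = function(e) list(chisq = NA, df = NA, p = NA))
      cx <- tryCatch(cox_fit(cohort, c("risk_score", "stage")),
                     error = function(e) NULL)
      tab <- if (length(horizons))
        stratify_and_tabulate(cohort,
                              c("risk_score", ev$baseline_covariate),
                              unlist(horizons),
                              n_bootstrap = ev$n_bootstrap,
                              seed = derive_seed(config$seed, "evaluate"))
        else data.frame()
      nri <- tryCatch(continuous_nri(
        cohort, cohort[[ev$baseline_covariate]],
        cohort[[ev$baseline_covariate]] + cohort$risk_score,
        tau = unlist(horizons)[max(1, length(horizons) %/% 2)],
        n_bootstrap = ev$n_bootstrap,
        seed = derive_seed(config$seed, "nri")),
        error = function(e) list(nri = NA, ci = c(NA, NA)))
      write.csv(tab, file.path(d, "metrics.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(logrank = lr,
             cox = if (!is.null(cx)) cx else "not estimable",
             nri = nri[c("nri", "event_component", "nonevent_component",
                         "ci", "tau")],
             table = tab),
        file.path(d, "metrics.json"), digits = NA, auto_unbox = TRUE,
        na = "null")
      list(n_subjects = nrow(cohort), logrank_p = lr$p)
    })

  for (stage in pipeline_stages) {
    t0 <- proc.time()[["elapsed"]]
    if (!force && stage_done(out_dir, stage)) {
      say(stage, ": outputs present, reused")
      manifest$stages[[stage]] <- list(status = "reused")
    } else {
      d <- stage_dir(out_dir, stage)
      info <- tryCatch(stage_fns[[stage]](d), error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
      mark_done(out_dir, stage)
      secs <- round(proc.time()[["elapsed"]] - t0, 2)
      manifest$stages[[stage]] <- c(list(status = "run", seconds = secs),
                                    info)
      say(stage, " done (", secs, "s)")
    }
    if (!is.null(upto) && stage == upto) break
  }
  manifest$files <- sort(list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
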