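# Pipeline configuration: YAML round-trip with strict key validation.

#' Default pipeline configuration
#'
#' Nested sections mirror the pipeline stages; the MIL section defaults to
#' the published operating point (t = 0.4457, p = 3, alpha = 0.02,
#' initial learning rate 1e-4 halving every 10 epochs).
#'
#' @return A nested named list of class \code{pipeline_config}.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "slidemil_run",
    simulation = list(n_slides_per_class = 10L, n_test_slides_per_class = 6L,
                      n_seg_pairs = 40L, n_tiles = 16L, tile_size = 64L,
                      signal_fraction = 0.5, stroma_probability = 0.6,
                      immune_density = 4, nuclei_per_tile = 12,
                      log_hazard_ratio = log(2), censoring_rate = 0.3),
    tiling = list(tile_size = 512L, resize = 224L,
                  tissue_threshold = 0.25, whiteness_cutoff = 220,
                  mpp = 0.25),
    normalization = list(sparsity = 0.1, enabled = TRUE),
    segmentation = list(depth = 3L, base_channels = 8L, epochs = 6L,
                        learning_rate = 1e-3, epsilon = 1e-8,
                        val_fraction = 0.2, augment = TRUE),
    mil = list(aggregation_exponent = 3, threshold = 0.4457,
               l2_alpha = 0.02, initial_lr = 1e-4, lr_halving_epochs = 10L,
               epochs = 10L, backbone_variant = "tiny", power_mean = FALSE),
    evaluation = list(horizons = c(6, 12, 18, 24, 30), n_bootstrap = 200L,
                      baseline_covariate = "stage")),
    class = "pipeline_config")
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop_param("config section '", path, "' must be a map")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_param("unknown config key", if (length(unknown) > 1) "s" else "",
               ": ", paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    kp <- paste0(path, k)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(kp, "."))
    } else {
      v <- user[[k]]
      d <- defaults[[k]]
      if (!is.null(d) && is.numeric(d) && !is.numeric(v))
        stop_param("config key '", kp, "' must be numeric")
      if (!is.null(d) && is.character(d) && !is.character(v))
        stop_param("config key '", kp, "' must be a string")
      defaults[[k]] <- if (is.integer(d) && is.numeric(v)) as.integer(v)
                       else v
    }
  }
  defaults
}

validate_config <- function(cfg) {
  check_number(cfg$mil$threshold, "mil.threshold", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$mil$aggregation_exponent, "mil.aggregation_exponent",
               lower = 1)
  check_number(cfg$mil$l2_alpha, "mil.l2_alpha", lower = 0)
  check_number(cfg$mil$initial_lr, "mil.initial_lr", lower = 0,
               open_lower = TRUE)
  check_number(cfg$tiling$tissue_threshold, "tiling.tissue_threshold",
               lower = 0, upper = 1)
  check_number(cfg$simulation$signal_fraction, "simulation.signal_fraction",
               lower = 0, upper = 1)
  check_number(cfg$simulation$censoring_rate, "simulation.censoring_rate",
               lower = 0, upper = 1, open_upper = TRUE)
  check_number(cfg$segmentation$depth, "segmentation.depth", lower = 2)
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected with the offending key named; missing keys
#' take documented defaults; constraint violations name the key. An empty
#' file yields the all-defaults configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated \code{pipeline_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' Save a pipeline configuration to YAML
#' @param config A \code{pipeline_config}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}
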