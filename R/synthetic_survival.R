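# Synthetic proportional-hazards survival cohorts with known marker effects.

#' Configuration for the survival-cohort simulator
#'
#' Event times follow a Weibull proportional-hazards model:
#' \eqn{T = scale * (-log(U) * exp(-eta))^{1/shape}} with linear predictor
#' \eqn{eta} built from a binary marker and an ordered three-level stage
#' factor. Censoring times are uniform on (0, c_max) with c_max solved by
#' bisection so the expected censoring fraction matches the target.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param log_hazard_ratios Named numeric vector with elements
#'   \code{marker} (binary covariate) and \code{stage} (per-level increment
#'   of the ordered stage factor).
#' @param baseline_shape,baseline_scale Weibull shape/scale (months).
#' @param censoring_rate Target censored fraction in [0, 1).
#' @param seed Integer seed.
#' @return An object of class \code{survival_sim_config}.
#' @export
survival_sim_config <- function(n_subjects = 300,
                                log_hazard_ratios = c(marker = log(2),
                                                      stage = 0.3),
                                baseline_shape = 1.2,
                                baseline_scale = 36,
                                censoring_rate = 0.3,
                                seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 2)
  check_number(baseline_shape, "baseline_shape", lower = 0, open_lower = TRUE)
  check_number(baseline_scale, "baseline_scale", lower = 0, open_lower = TRUE)
  check_number(censoring_rate, "censoring_rate", lower = 0, upper = 1,
               open_upper = TRUE)
  if (!all(c("marker", "stage") %in% names(log_hazard_ratios)))
    stop_param("log_hazard_ratios must have elements 'marker' and 'stage'")
  structure(list(n_subjects = as.integer(n_subjects),
                 log_hazard_ratios = log_hazard_ratios,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Simulate a right-censored survival cohort
#'
#' @param config A \code{\link{survival_sim_config}}.
#' @param marker Optional numeric vector of length \code{n_subjects} to use
#'   as the (possibly continuous) marker covariate; by default a balanced
#'   binary marker is drawn.
#' @return Data frame with columns \code{id}, \code{time}, \code{event}
#'   (1 = event observed), \code{marker}, \code{stage} (1-3) and
#'   \code{true_linear_predictor}.
#' @export
generate_survival_cohort <- function(config, marker = NULL) {
  stopifnot(inherits(config, "survival_sim_config"))
  n <- config$n_subjects
  with_seed(config$seed, {
    if (is.null(marker)) marker <- rbinom(n, 1, 0.5)
    if (length(marker) != n)
      stop_param("'marker' must have length n_subjects")
    stage <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    eta <- config$log_hazard_ratios[["marker"]] * marker +
      config$log_hazard_ratios[["stage"]] * (stage - 1)
    u <- runif(n)
    t_event <- config$baseline_scale *
      (-log(u) * exp(-eta))^(1 / config$baseline_shape)
    t_event <- pmax(t_event, 1e-6)
    if (config$censoring_rate == 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      # Uniform(0, c_max) censoring; expected censored fraction, given the
      # drawn event times, is mean(min(T/c, 1)) -- bisect on c.
      target <- config$censoring_rate
      f <- function(cm) mean(pmin(t_event / cm, 1)) - target
      lo <- min(t_event) * 1e-3
      hi <- max(t_event) * 2
      while (f(hi) > 0 && hi < max(t_event) * 1e8) hi <- hi * 4
      if (f(lo) < 0 || f(hi) > 0)
        stop_param("censoring calibration failed: target rate ", target,
                   " unattainable for these event times (achievable range ",
                   fmt_num(f(hi) + target), "-", fmt_num(f(lo) + target), ")")
      for (it in 1:80) {
        mid <- (lo + hi) / 2
        if (f(mid) > 0) lo <- mid else hi <- mid
      }
      c_max <- (lo + hi) / 2
      cens <- runif(n, 0, c_max)
      time <- pmin(t_event, cens)
      event <- as.integer(t_event <= cens)
    }
    data.frame(id = sprintf("subj_%04d", seq_len(n)),
               time = time, event = event,
               marker = marker, stage = stage,
               true_linear_predictor = as.numeric(eta),
               stringsAsFactors = FALSE)
  })
}
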