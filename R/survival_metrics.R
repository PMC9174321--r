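# Censored-survival evaluation stack: Kaplan-Meier, log-rank, Cox
# proportional hazards (Efron ties), cumulative/dynamic time-dependent
# ROC and accuracy at the best Youden index with inverse-probability-of-
# censoring weighting, and censoring-adjusted category-free NRI with a
# seeded percentile bootstrap. No multiplicity correction is applied
# anywhere; callers comparing many markers/horizons should correct
# externally.

check_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop_param("all follow-up times must be > 0")
  if (!all(records$event %in% c(0, 1)))
    stop_param("event indicator must be 0/1")
  invisible(records)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood standard errors (log-scale CIs),
#' via \code{survival::survfit}.
#'
#' @param records Data frame with columns \code{time} and \code{event}.
#' @return Object of class \code{km_estimate} with the step function's
#'   \code{time}, \code{surv}, \code{lower}, \code{upper}, \code{n_risk},
#'   \code{n_event}.
#' @export
km_estimate <- function(records) {
  check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "log")
  structure(list(time = fit$time, surv = fit$surv, lower = fit$lower,
                 upper = fit$upper, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = fit$n),
            class = "km_estimate")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step function with S(0) = 1.
#' @param km A \code{km_estimate}.
#' @param t Evaluation time(s).
#' @return Survival probabilities.
#' @export
km_survival <- function(km, t) {
  vapply(t, function(tt) {
    i <- findInterval(tt, km$time)
    if (i == 0) 1 else km$surv[i]
  }, numeric(1))
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, %d events, S(max obs) = %.3f\n",
              x$n, sum(x$n_event), x$surv[length(x$surv)]))
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected statistic over the pooled event times
#' (\code{survival::survdiff}).
#'
#' @param records Data frame with \code{time}, \code{event}.
#' @param group Grouping vector (>= 2 levels) or name of a column.
#' @return List with \code{chisq}, \code{df}, \code{p}.
#' @export
logrank_test <- function(records, group) {
  check_records(records)
  if (is.character(group) && length(group) == 1)
    group <- records[[group]]
  g <- factor(group)
  if (nlevels(g) < 2) stop_param("need at least 2 groups")
  if (sum(records$event) < 1) stop_param("need at least one event")
  d <- data.frame(time = records$time, event = records$event, g = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling
#' (\code{survival::coxph}); Wald confidence intervals.
#'
#' @param records Data frame with \code{time}, \code{event} and covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame, one row per covariate: \code{coef}, \code{se},
#'   \code{hr}, \code{lower}, \code{upper}, \code{p}.
#' @export
cox_fit <- function(records, covariates, conf_level = 0.95) {
  check_records(records)
  for (v in covariates) {
    if (!v %in% names(records)) stop_param("unknown covariate '", v, "'")
    x <- records[[v]]
    if (is.numeric(x) && sd(x) == 0)
      stop_param("covariate '", v, "' is constant")
  }
  if (length(unique(records$time[records$event == 1])) < 2)
    stop_param("need at least 2 distinct event times")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  if (any(!is.finite(fit$coefficients)) ||
      any(!is.finite(sqrt(diag(fit$var)))))
    stop_param("Cox fit did not converge (possible separation)")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- fit$coefficients; se <- sqrt(diag(fit$var))
  data.frame(covariate = names(co), coef = unname(co), se = unname(se),
             hr = exp(unname(co)),
             lower = exp(unname(co) - z * se),
             upper = exp(unname(co) + z * se),
             p = 2 * stats::pnorm(-abs(unname(co) / se)),
             stringsAsFactors = FALSE)
}

# Censoring survival function G (KM of the censoring distribution) and
# its left limit, for inverse-probability-of-censoring weights.
censoring_km <- function(records) {
  cens <- data.frame(time = records$time, event = 1 - records$event)
  km_estimate(cens)
}

km_survival_left <- function(km, t) {
  vapply(t, function(tt) {
    i <- findInterval(tt, km$time, left.open = TRUE)  # strictly < tt
    if (i == 0) 1 else km$surv[i]
  }, numeric(1))
}

# Shared case/control construction at horizon tau:
# cases = event observed by tau (cumulative), controls = still at risk
# after tau (dynamic); case weights 1/G(T-), control weights 1/G(tau).
td_case_control <- function(records, marker, tau) {
  check_records(records)
  if (length(marker) == 1 && is.character(marker)) marker <- records[[marker]]
  if (length(marker) != nrow(records))
    stop_param("marker length must match records")
  case <- records$time <= tau & records$event == 1
  ctrl <- records$time > tau
  if (!any(case)) stop_param("no cases (events by tau = ", tau, ")")
  if (!any(ctrl)) stop_param("no controls (subjects beyond tau = ", tau, ")")
  G <- censoring_km(records)
  w_case <- 1 / pmax(km_survival_left(G, records$time[case]), 1e-10)
  list(m_case = marker[case], w_case = w_case,
       m_ctrl = marker[ctrl],
       n_case = sum(case), n_ctrl = sum(ctrl))
}

# Weighted sensitivity/specificity over every cutoff (classify high risk
# when marker > cutoff), ROC points ordered from (1,1) to (0,0).
td_curve <- function(cc) {
  cuts <- sort(unique(c(cc$m_case, cc$m_ctrl)))
  W <- sum(cc$w_case)
  sens <- vapply(cuts, function(c0) sum(cc$w_case[cc$m_case > c0]) / W,
                 numeric(1))
  spec <- vapply(cuts, function(c0) mean(cc$m_ctrl <= c0), numeric(1))
  list(cutoff = c(-Inf, cuts), sens = c(1, sens), spec = c(0, spec))
}

#' Time-dependent ROC curve and AUC at a horizon
#'
#' Cumulative-cases / dynamic-controls definition: cases are subjects
#' with an observed event by \code{tau}, controls those still event-free
#' beyond \code{tau}; censoring is handled by Kaplan-Meier-based inverse
#' probability weights on the cases. The AUC is the trapezoidal area
#' under the (1 - specificity, sensitivity) curve, which equals the
#' weighted case/control rank-sum statistic (ties counted 1/2).
#'
#' @param records Data frame with \code{time}, \code{event}.
#' @param marker Numeric risk marker (vector or column name); higher =
#'   riskier.
#' @param tau Evaluation horizon.
#' @return List with \code{cutoff}, \code{sens}, \code{spec}, \code{auc},
#'   \code{tau}, \code{n_cases}, \code{n_controls}.
#' @export
time_dependent_roc <- function(records, marker, tau) {
  cc <- td_case_control(records, marker, tau)
  cv <- td_curve(cc)
  fpr <- 1 - cv$spec
  ord <- order(fpr, cv$sens)
  x <- fpr[ord]; y <- cv$sens[ord]
  x <- c(0, x, 1); y <- c(0, y, 1)
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  list(cutoff = cv$cutoff, sens = cv$sens, spec = cv$spec, auc = auc,
       tau = tau, n_cases = cc$n_case, n_controls = cc$n_ctrl)
}

#' Time-dependent accuracy at the best Youden index
#'
#' Over all marker cutoffs c, the Youden index
#' \code{J(c) = Se(tau, c) + Sp(tau, c) - 1} is maximized (ties resolved
#' toward the smallest cutoff). The reported accuracy weights sensitivity
#' and specificity by the Kaplan-Meier event probability by \code{tau}
#' (\code{Se * pi + Sp * (1 - pi)}), which is censoring-consistent; the
#' naive complete-case accuracy is also returned since the two differ
#' under censoring.
#'
#' @inheritParams time_dependent_roc
#' @return List with \code{cutoff}, \code{sensitivity},
#'   \code{specificity}, \code{youden}, \code{accuracy},
#'   \code{accuracy_complete_case}, \code{prevalence}, \code{tau}.
#' @export
time_dependent_accuracy <- function(records, marker, tau) {
  if (length(marker) == 1 && is.character(marker)) marker <- records[[marker]]
  cc <- td_case_control(records, marker, tau)
  cv <- td_curve(cc)
  J <- cv$sens + cv$spec - 1
  best <- which(J == max(J))
  best <- best[which.min(cv$cutoff[best])]
  km <- km_estimate(records)
  prev <- 1 - km_survival(km, tau)
  se <- cv$sens[best]; sp <- cv$spec[best]; c0 <- cv$cutoff[best]
  known <- records$time > tau | (records$time <= tau & records$event == 1)
  cls <- marker > c0
  truth <- records$time <= tau & records$event == 1
  acc_cc <- mean((cls == truth)[known])
  list(cutoff = c0, sensitivity = se, specificity = sp,
       youden = J[best], accuracy = se * prev + sp * (1 - prev),
       accuracy_complete_case = acc_cc, prevalence = prev, tau = tau)
}

nri_components <- function(records, base_risk, new_risk, tau) {
  up <- new_risk > base_risk
  down <- new_risk < base_risk
  n <- nrow(records)
  pe_sub <- function(sel) {
    if (!any(sel)) return(0)
    1 - km_survival(km_estimate(records[sel, , drop = FALSE]), tau)
  }
  pe <- 1 - km_survival(km_estimate(records), tau)
  if (pe <= 0 || pe >= 1)
    stop_param("event probability at tau is degenerate (", fmt_num(pe), ")")
  p_up <- mean(up); p_down <- mean(down)
  pe_up <- pe_sub(up); pe_down <- pe_sub(down)
  ev <- (p_up * pe_up - p_down * pe_down) / pe
  ne <- (p_down * (1 - pe_down) - p_up * (1 - pe_up)) / (1 - pe)
  c(event = ev, nonevent = ne)
}

#' Censoring-adjusted category-free (continuous) NRI
#'
#' \code{NRI = [P(up|event) - P(down|event)] +
#' [P(down|non-event) - P(up|non-event)]} at horizon \code{tau}, with
#' event status estimated by Kaplan-Meier within the up/down reclassified
#' groups (censoring-consistent). "Up" means the new risk exceeds the
#' baseline risk. A seeded percentile bootstrap supplies the confidence
#' interval.
#'
#' @param records Data frame with \code{time}, \code{event}.
#' @param base_risk,new_risk Risk vectors (higher = riskier), one value
#'   per subject.
#' @param tau Evaluation horizon.
#' @param n_bootstrap Bootstrap resamples (default 1000).
#' @param conf_level Confidence level.
#' @param seed Integer bootstrap seed.
#' @return List with \code{nri}, \code{event_component},
#'   \code{nonevent_component}, \code{ci}, \code{tau},
#'   \code{n_bootstrap}.
#' @export
continuous_nri <- function(records, base_risk, new_risk, tau,
                           n_bootstrap = 1000, conf_level = 0.95,
                           seed = 1L) {
  check_records(records)
  if (length(base_risk) != nrow(records) ||
      length(new_risk) != nrow(records))
    stop_param("risk vectors must have one value per subject")
  if (all(new_risk == base_risk)) {
    if (max(new_risk) == min(new_risk))
      warning("all risks tied; NRI is 0 by construction")
    return(list(nri = 0, event_component = 0, nonevent_component = 0,
                ci = c(0, 0), tau = tau, n_bootstrap = 0L))
  }
  comp <- nri_components(records, base_risk, new_risk, tau)
  boots <- if (n_bootstrap > 0) with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      i <- sample.int(nrow(records), replace = TRUE)
      tryCatch(sum(nri_components(records[i, , drop = FALSE],
                                  base_risk[i], new_risk[i], tau)),
               error = function(e) NA_real_)
    }, numeric(1))
  }) else numeric(0)
  alpha <- 1 - conf_level
  ci <- if (length(boots))
    quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
             names = FALSE) else c(NA_real_, NA_real_)
  list(nri = unname(sum(comp)), event_component = unname(comp["event"]),
       nonevent_component = unname(comp["nonevent"]),
       ci = ci, tau = tau, n_bootstrap = as.integer(n_bootstrap))
}

#' Tabulate time-dependent accuracy and AUC over markers and horizons
#'
#' The machine-readable analogue of a per-horizon performance table: for
#' every marker and every horizon, the Youden-optimal accuracy and the
#' time-dependent AUC with seeded percentile-bootstrap confidence
#' intervals.
#'
#' @param records Data frame with \code{time}, \code{event} and marker
#'   columns.
#' @param markers Character vector of marker column names.
#' @param horizons Strictly increasing evaluation times.
#' @param n_bootstrap Bootstrap resamples per cell (default 200).
#' @param conf_level Confidence level.
#' @param seed Integer seed.
#' @return Data frame: marker, horizon, accuracy (+ CI), auc (+ CI).
#' @export
stratify_and_tabulate <- function(records, markers, horizons,
                                  n_bootstrap = 200, conf_level = 0.95,
                                  seed = 1L) {
  check_records(records)
  if (is.unsorted(horizons, strictly = TRUE))
    stop_param("horizons must be strictly increasing")
  if (max(horizons) >= max(records$time))
    stop_param("horizons must lie within observed follow-up")
  alpha <- 1 - conf_level
  rows <- list()
  for (mk in markers) {
    for (tau in horizons) {
      acc <- time_dependent_accuracy(records, mk, tau)
      roc <- time_dependent_roc(records, records[[mk]], tau)
      bs <- with_seed(derive_seed(seed, paste(mk, tau)), {
        t(vapply(seq_len(n_bootstrap), function(b) {
          i <- sample.int(nrow(records), replace = TRUE)
          rb <- records[i, , drop = FALSE]
          tryCatch({
            a <- time_dependent_accuracy(rb, rb[[mk]], tau)
            r <- time_dependent_roc(rb, rb[[mk]], tau)
            c(a$accuracy, r$auc)
          }, error = function(e) c(NA_real_, NA_real_))
        }, numeric(2)))
      })
      qs <- function(v) quantile(v, c(alpha / 2, 1 - alpha / 2),
                                 na.rm = TRUE, names = FALSE)
      qa <- qs(bs[, 1]); qu <- qs(bs[, 2])
      rows[[length(rows) + 1L]] <-
        data.frame(marker = mk, horizon = tau,
                   accuracy = acc$accuracy, accuracy_lower = qa[1],
                   accuracy_upper = qa[2],
                   auc = roc$auc, auc_lower = qu[1], auc_upper = qu[2],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
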