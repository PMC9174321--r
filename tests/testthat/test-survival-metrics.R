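test_that("Kaplan-Meier reproduces the hand product-limit computation", {
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(0, 1, 1)))
  expect_equal(km_survival(km, 2), 0.5)
  expect_equal(km_survival(km, 3), 0)
  expect_equal(km_survival(km, 0.5), 1)
  # no events -> flat survival at 1
  km2 <- km_estimate(data.frame(time = 1:5, event = rep(0, 5)))
  expect_true(all(km_survival(km2, 1:5) == 1))
  # all distinct events, no censoring: KM equals the empirical survivor
  tt <- c(2, 5, 7, 11)
  km3 <- km_estimate(data.frame(time = tt, event = rep(1, 4)))
  expect_equal(km_survival(km3, tt), 1 - ecdf(tt)(tt))
  # non-increasing, right-continuous, S(0) = 1
  expect_true(all(diff(km3$surv) <= 0))
  expect_error(km_estimate(data.frame(time = c(0, 1), event = c(1, 1))),
               "> 0")
})

test_that("log-rank agrees with the brute-force O-E oracle", {
  # identical groups: statistic exactly 0
  d0 <- data.frame(time = rep(c(2, 4, 6), 2), event = rep(1, 6),
                   g = rep(c("a", "b"), each = 3))
  expect_equal(logrank_test(d0, "g")$chisq, 0, tolerance = 1e-12)
  # 6-subject worked example
  d <- data.frame(time = c(1, 3, 4, 5, 7, 9),
                  event = c(1, 1, 0, 1, 1, 1),
                  g = c("a", "b", "a", "b", "a", "b"))
  lr <- logrank_test(d, "g")
  expect_equal(lr$chisq, brute_force_logrank(d$time, d$event, d$g),
               tolerance = 1e-9)
  expect_equal(lr$df, 1)
  # invariant to relabeling groups
  d2 <- d; d2$g <- ifelse(d$g == "a", "b", "a")
  expect_equal(logrank_test(d2, "g")$chisq, lr$chisq)
  # random configurations against the oracle
  set.seed(31)
  for (i in 1:10) {
    dd <- data.frame(time = sample(1:20, 14, TRUE) + runif(14),
                     event = rbinom(14, 1, 0.8),
                     g = sample(c("x", "y"), 14, TRUE))
    if (length(unique(dd$g)) < 2 || sum(dd$event) == 0) next
    expect_equal(logrank_test(dd, "g")$chisq,
                 brute_force_logrank(dd$time, dd$event, dd$g),
                 tolerance = 1e-8)
  }
  expect_error(logrank_test(d[d$g == "a", ], "g"), "2 groups")
})

test_that("Cox fit matches a grid-search partial-likelihood maximizer", {
  set.seed(17)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate = 0.1 * exp(0.8 * x)) + runif(n, 0, 1e-4)
  cens <- runif(n, 0, 25)
  d <- data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens),
                  x = x)
  fit <- cox_fit(d, "x")
  opt <- optimize(function(b) -cox_partial_loglik(b, d$time, d$event, d$x),
                  c(-3, 3), tol = 1e-9)
  expect_equal(fit$coef, opt$minimum, tolerance = 1e-4)
  # location shift of the covariate leaves the estimate unchanged;
  # scaling rescales it inversely
  d$xs <- d$x + 10
  expect_equal(cox_fit(d, "xs")$coef, fit$coef, tolerance = 1e-7)
  d$x2 <- 2 * d$x
  expect_equal(cox_fit(d, "x2")$coef, fit$coef / 2, tolerance = 1e-7)
  expect_error(cox_fit(transform(d, k = 1), "k"), "constant")
})

test_that("time-dependent ROC equals the rank-sum oracle without censoring", {
  set.seed(23)
  n <- 150
  d <- data.frame(time = rexp(n, 0.08) + 0.01, event = rep(1L, n))
  m <- d$time * -1 + rnorm(n, 0, 3)       # informative marker with noise
  tau <- median(d$time)
  roc <- time_dependent_roc(d, m, tau)
  oracle <- rank_sum_auc(m[d$time <= tau], m[d$time > tau])
  expect_equal(roc$auc, oracle, tolerance = 1e-9)
  # perfect marker: AUC 1 at any interior horizon
  perfect <- -d$time
  expect_equal(time_dependent_roc(d, perfect, tau)$auc, 1)
  expect_equal(time_dependent_roc(d, perfect, quantile(d$time, 0.25))$auc, 1)
  # invariant under strictly monotone transforms of the marker
  expect_equal(time_dependent_roc(d, qlogis(plogis(m)), tau)$auc, roc$auc,
               tolerance = 1e-9)
  expect_error(time_dependent_roc(d, m, 1e-6), "no cases")
})

test_that("Youden-optimal accuracy matches 2x2 arithmetic for a binary marker", {
  # 10 subjects, no censoring, binary marker, tau = 10:
  # marker 1: 4 events by tau, 1 survivor; marker 0: 1 event, 4 survivors
  d <- data.frame(time = c(2, 3, 4, 5, 20, 6, 21, 22, 23, 24),
                  event = rep(1L, 10),
                  m = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  a <- time_dependent_accuracy(d, "m", 10)
  expect_equal(a$sensitivity, 4 / 5)
  expect_equal(a$specificity, 4 / 5)
  expect_equal(a$prevalence, 0.5)
  expect_equal(a$accuracy, 0.8)
  expect_equal(a$accuracy_complete_case, 0.8)
  expect_equal(a$cutoff, 0)   # classify positive when marker > 0
  # perfect separation -> accuracy 1 at the separating cutoff
  dp <- data.frame(time = c(1, 2, 3, 30, 31, 32), event = rep(1L, 6),
                   m = c(5, 6, 7, 1, 2, 3))
  ap <- time_dependent_accuracy(dp, "m", 10)
  expect_equal(ap$accuracy, 1)
  expect_equal(ap$youden, 1)
})

test_that("continuous NRI reproduces the worked 8-subject example", {
  # no censoring, tau = 12; 4 events (3 up-, 1 down-classified) and
  # 4 non-events (3 down-, 1 up-classified) -> NRI = 0.5 + 0.5 = 1
  d <- data.frame(time = c(5, 5, 5, 5, 20, 20, 20, 20),
                  event = c(1, 1, 1, 1, 1, 1, 1, 1))
  base <- rep(0, 8)
  new <- c(1, 1, 1, -1, -1, -1, -1, 1)
  r <- continuous_nri(d, base, new, tau = 12, n_bootstrap = 0)
  expect_equal(r$event_component, 0.5)
  expect_equal(r$nonevent_component, 0.5)
  expect_equal(r$nri, 1)
  # identical risks: exactly zero
  r0 <- continuous_nri(d, new, new, tau = 12, n_bootstrap = 0)
  expect_equal(r0$nri, 0)
  # antisymmetry under swapping base and new
  swap <- continuous_nri(d, new, base, tau = 12, n_bootstrap = 0)
  expect_equal(swap$nri, -r$nri)
  expect_equal(swap$event_component, -r$event_component)
  # components bounded in [-1, 1]
  expect_true(all(abs(c(r$event_component, r$nonevent_component)) <= 1))
})

test_that("metric tabulation is deterministic with the expected shape", {
  cfg <- survival_sim_config(n_subjects = 160, seed = 41)
  coh <- generate_survival_cohort(cfg)
  coh$noise <- with_seed_noise <- withr::with_seed(5, rnorm(160))
  tab1 <- stratify_and_tabulate(coh, c("true_linear_predictor", "noise"),
                                c(12, 24), n_bootstrap = 30, seed = 7)
  tab2 <- stratify_and_tabulate(coh, c("true_linear_predictor", "noise"),
                                c(12, 24), n_bootstrap = 30, seed = 7)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 4)
  expect_true(all(c("accuracy", "auc", "auc_lower", "auc_upper")
                  %in% names(tab1)))
  # the informative marker dominates noise at every horizon
  for (h in c(12, 24)) {
    expect_gt(tab1$auc[tab1$marker == "true_linear_predictor" &
                         tab1$horizon == h],
              tab1$auc[tab1$marker == "noise" & tab1$horizon == h])
  }
  expect_error(stratify_and_tabulate(coh, "noise", c(24, 12), 10),
               "increasing")
})
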