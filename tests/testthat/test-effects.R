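test_that("inverse sigmoid matches direct evaluation and inverts the sigmoid", {
  expect_equal(inverse_sigmoid(0.5), 0)
  expect_equal(inverse_sigmoid(0.73), log(0.73 / 0.27), tolerance = 1e-12)
  expect_equal(round(inverse_sigmoid(0.73), 4), 0.9946)
  expect_true(is.finite(suppressMessages(inverse_sigmoid(1))))
  expect_equal(suppressMessages(inverse_sigmoid(1)), log((1 - 1e-6) / 1e-6))
  p <- seq(0.001, 0.999, length.out = 101)
  expect_equal(plogis(inverse_sigmoid(p)), p, tolerance = 1e-10)
  expect_equal(inverse_sigmoid(plogis(c(-7, -1, 0, 2, 7))), c(-7, -1, 0, 2, 7),
               tolerance = 1e-10)
  expect_error(inverse_sigmoid(1.2), "\\[0, 1\\]")
})

test_that("per-bin F statistics reproduce the mixed-model ANOVA with df = N - K", {
  d <- make_lme_null_data(8, 36, 3, seed = 21)
  # plant an effect so F values are non-trivial
  d$y <- d$y + 0.4 * (d$loss_probability == "high")
  res <- fit_lme_timecourse(d, factors = c("loss_probability", "choice"))
  expect_equal(sort(unique(res$table$effect)),
               sort(c("loss_probability", "choice", "loss_probability:choice")))

  # independent oracle: lme4's own ANOVA on each bin
  for (b in 1:3) {
    db <- d[d$bin == b, ]
    fit <- lme4::lmer(y ~ loss_probability * choice + (1 | subject), data = db,
                      REML = TRUE)
    an <- anova(fit)
    tab <- res$table[res$table$bin == b, ]
    expect_equal(tab$F[match(rownames(an), tab$effect)], an[["F value"]],
                 tolerance = 1e-6)
  }

  # df = N - K with K counting fixed coefficients plus subject intercepts
  N <- 8 * 36
  K <- 6 + 8
  expect_true(all(res$table$df2 == N - K))
  expect_equal(res$N, N)
  expect_equal(res$K, K)
  expect_error(fit_lme_timecourse(d[d$subject == "s01", ],
                                  factors = c("loss_probability", "choice")),
               "2 subjects")
})

test_that("planted fixed effects are recovered within 2 standard errors", {
  set.seed(22)
  d <- make_lme_null_data(10, 48, 2, sd_subj = 0.6, sd_noise = 0.4, seed = 23)
  slope <- -0.3
  d$y <- d$y + slope * d$loss_magnitude
  res <- fit_lme_timecourse(d, factors = c("loss_magnitude"))
  # the magnitude effect is overwhelming at every bin
  tab <- res$table[res$table$effect == "loss_magnitude", ]
  expect_true(all(tab$p < 1e-10))
  # per-level means recover the planted linear trend
  for (b in 1:2) {
    db <- d[d$bin == b, ]
    db$loss_magnitude <- factor(db$loss_magnitude)
    fit <- lme4::lmer(y ~ loss_magnitude + (1 | subject), data = db, REML = TRUE)
    cf <- lme4::fixef(fit)[-1]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[-1]
    truth <- slope * (1:5)
    expect_true(all(abs(cf - truth) < 2.5 * se))
  }
})

test_that("cluster correction localises a planted effect and respects the threshold", {
  set.seed(24)
  hits <- 0L
  for (s in 1:10) {
    d <- make_lme_null_data(8, 36, 10, sd_subj = 0.4, sd_noise = 1, seed = 300 + s)
    bump <- d$bin %in% 4:6
    d$y <- d$y + ifelse(bump, 0.5 * (as.numeric(d$loss_probability == "high") -
                                       0.5), 0)
    res <- fit_lme_timecourse(d, factors = c("loss_probability", "choice"))
    cc <- cluster_correct_timecourse(res, n_perm = 200, seed = s)
    cl <- cc$loss_probability$clusters
    sig <- cl[cl$significant, , drop = FALSE]
    if (nrow(sig) && any(sig$start_bin <= 6 & sig$end_bin >= 4)) hits <- hits + 1L

    # corrected significance never exceeds the uncorrected suprathreshold set
    tab <- res$table[res$table$effect == "loss_probability", ]
    n_supra <- sum(tab$p < 0.05)
    n_sig_bins <- if (nrow(sig)) sum(sig$end_bin - sig$start_bin + 1) else 0L
    expect_lte(n_sig_bins, n_supra)
  }
  expect_gte(hits, 8)
})

test_that("an effect-free time course yields an empty cluster set", {
  d <- make_lme_null_data(6, 24, 6, seed = 26)
  res <- fit_lme_timecourse(d, factors = c("loss_probability", "choice"))
  cc <- suppressWarnings(cluster_correct_timecourse(res, n_perm = 120, seed = 2))
  for (eff in names(cc)) {
    expect_true(all(!cc[[eff]]$clusters$significant))
  }
  # F statistics are invariant to a consistent permutation of level labels
  d2 <- d
  d2$loss_probability <- c(low = "high", medium = "low", high = "medium")[d2$loss_probability]
  res2 <- fit_lme_timecourse(d2, factors = c("loss_probability", "choice"))
  expect_equal(res2$table$F, res$table$F, tolerance = 1e-9)
})

simulate_behaviour_study <- function(n_subj, trials_per_block, coefs, seed) {
  cfg <- task_config(n_training_trials = 0, n_blocks = 1,
                     trials_per_block = trials_per_block)
  pol <- behaviour_policy(approach_coefs = coefs)
  do.call(rbind, lapply(seq_len(n_subj), function(s) {
    tr <- simulate_task(cfg, pol, seed = seed * 100 + s)
    tr$subject <- sprintf("s%02d", s)
    as.data.frame(tr)
  }))
}

test_that("behavioural mixed models detect planted condition effects", {
  d <- simulate_behaviour_study(
    21, 540, c(intercept = 1.8, loss_prob = -0.35, loss_magnitude = -0.4,
               interaction = 0), seed = 3)
  bl <- behaviour_lme(d)
  app <- bl$approach$table
  expect_lt(app$p[app$effect == "loss_magnitude"], 0.001)
  expect_equal(bl$approach$n_obs, 21 * 540)
  # the latency model sees exactly the approach trials
  expect_equal(bl$latency$n_obs, sum(d$choice == "approach"))
  expect_true(all(bl$latency$table$df2 ==
                    bl$latency$n_obs - (18 + length(unique(d$subject[d$choice == "approach"])))))
})

test_that("behavioural tests stay quiet under a condition-blind policy", {
  null_coefs <- c(intercept = 0.8, loss_prob = 0, loss_magnitude = 0, interaction = 0)
  p_mag <- replicate(50, NA_real_)
  p_prob <- replicate(50, NA_real_)
  for (r in 1:50) {
    d <- simulate_behaviour_study(5, 90, null_coefs, seed = 500 + r)
    bl <- suppressMessages(behaviour_lme(d))
    app <- bl$approach$table
    p_mag[r] <- app$p[app$effect == "loss_magnitude"]
    p_prob[r] <- app$p[app$effect == "loss_probability"]
  }
  expect_gte(mean(p_mag > 0.05), 0.9)
  expect_gte(mean(p_prob > 0.05), 0.9)
})

test_that("the planted dwell bias reaches the decoded baseline-contrast series", {
  cfg <- task_config(n_training_trials = 0, n_blocks = 2, trials_per_block = 108)
  mdl <- sensor_model(n_channels = 32, blink_channels = 1:10,
                      bias = c(intercept = 0, magnitude = -0.5, choice = 0))
  series_P <- list()
  series_N <- list()
  for (s in 1:4) {
    pp <- suppressMessages(
      simulate_participant(cfg, model = mdl, seed = 700 + s, n_keep = 32))
    suite <- build_classifier_suite(pp$outcome, pp$baseline, bin_star = 32,
                                    lambda = 0.025, n_perm = 0, seed = 1)
    series_P[[s]] <- decode(suite$models$P_vs_base, pp$trial_start)
    series_N[[s]] <- decode(suite$models$N_vs_base, pp$trial_start)
  }
  fit_mag <- function(series_list) {
    d <- prob_series_long(series_list)
    d <- d[d$bin <= 5, ]
    fit_lme_timecourse(d, factors = "loss_magnitude")
  }
  res_P <- fit_mag(series_P)
  res_N <- fit_mag(series_N)
  # the magnitude-dependent dwell bias is detected in the P-vs-baseline series
  expect_lt(min(res_P$table$p), 0.01)
  # and pushes the two baseline contrasts in opposite directions
  slope_sign <- function(series_list) {
    d <- prob_series_long(series_list)
    sign(stats::coef(stats::lm(qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)) ~ loss_magnitude,
                               data = d))[2])
  }
  expect_equal(unname(slope_sign(series_P)), -1)
  expect_equal(unname(slope_sign(series_N)), 1)
})

test_that("choice has no variability -> informative error", {
  d <- simulate_behaviour_study(
    3, 36, c(intercept = 50, loss_prob = 0, loss_magnitude = 0, interaction = 0),
    seed = 9)
  d$choice <- "approach"
  expect_error(behaviour_lme(d), "no variability")
})
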