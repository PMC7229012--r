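test_that("balanced accuracy matches hand computation and is symmetric", {
  # 3 of 4 positives and 8 of 10 negatives correct -> (0.75 + 0.8) / 2
  truth <- rep(c("P", "N"), c(4, 10))
  pred <- c("P", "P", "P", "N", rep("N", 8), "P", "P")
  expect_equal(balanced_accuracy(pred, truth, positive = "P"), 0.775)
  expect_equal(balanced_accuracy(truth, truth), 1)
  expect_equal(balanced_accuracy(rep("P", 14), truth), 0.5)
  expect_error(balanced_accuracy(rep("P", 3), rep("P", 3)), "both classes")

  # class-relabeling symmetry on random cases
  set.seed(1)
  for (i in 1:20) {
    tr <- sample(c("A", "B"), 30, replace = TRUE, prob = c(0.8, 0.2))
    if (length(unique(tr)) < 2) next
    pr <- sample(c("A", "B"), 30, replace = TRUE)
    swap <- c(A = "B", B = "A")
    expect_equal(balanced_accuracy(pr, tr, positive = "A"),
                 balanced_accuracy(swap[pr], swap[tr], positive = "B"))
  }
})

l1_objective <- function(w, b, X, y01, lambda) {
  eta <- drop(X %*% w) + b
  mean(log(1 + exp(eta)) - y01 * eta) + lambda * sum(abs(w))
}

test_that("the lasso-logistic fit attains the brute-force grid-search optimum", {
  set.seed(3)
  X <- matrix(rnorm(24 * 3), 24, 3)
  y01 <- rbinom(24, 1, plogis(1.2 * X[, 1] - 0.8 * X[, 3]))
  if (length(unique(y01)) < 2) y01[1:2] <- c(0, 1)
  y <- factor(ifelse(y01 == 1, "P", "N"), levels = c("N", "P"))
  lambda <- 0.05
  m <- train_l1_logistic(X, y, lambda)
  obj_fit <- l1_objective(m$weights, m$intercept, X, y01, lambda)

  # coarse 4-D grid, then a refined local grid around the best cell
  grid_min <- function(centre, half, step) {
    ax <- lapply(centre, function(c0) seq(c0 - half, c0 + half, by = step))
    combos <- as.matrix(expand.grid(ax))
    scores <- X %*% t(combos[, 1:3]) # n x n_combo
    eta <- sweep(scores, 2, combos[, 4], "+")
    obj <- colMeans(log(1 + exp(eta)) - outer(y01, rep(1, nrow(combos))) * eta) +
      lambda * rowSums(abs(combos[, 1:3, drop = FALSE]))
    list(par = combos[which.min(obj), ], val = min(obj))
  }
  g1 <- grid_min(c(0, 0, 0, 0), 2, 0.25)
  g2 <- grid_min(g1$par, 0.25, 0.025)
  g3 <- grid_min(g2$par, 0.025, 0.0025)
  expect_equal(obj_fit, g3$val, tolerance = 1e-4)
  expect_lte(obj_fit, g3$val + 1e-6) # the solver is never beaten by the grid
})

test_that("penalty-dominated and separable limits behave as expected", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- factor(rep(c("N", "P"), c(10, 30)), levels = c("N", "P"))
  m <- train_l1_logistic(X, y, lambda = 50)
  expect_true(all(m$weights == 0))
  # intercept-only model predicts the training class proportion everywhere
  expect_equal(unname(predict(m, matrix(rnorm(6), 2, 3))), rep(0.75, 2),
               tolerance = 1e-6)

  # 1-D linearly separated data: weight sign follows the separation
  x1 <- matrix(c(rnorm(15, -2), rnorm(15, 2)), ncol = 1)
  y1 <- factor(rep(c("N", "P"), each = 15), levels = c("N", "P"))
  m1 <- train_l1_logistic(x1, y1, lambda = 0.01)
  expect_length(m1$weights, 1)
  expect_gt(m1$weights, 0)

  expect_error(train_l1_logistic(X, factor(rep("P", 40)), 0.1), "two classes")
  expect_error(train_l1_logistic(X, y, -1), "non-negative")
})

test_that("the active set shrinks along the penalty path", {
  ep <- make_epochs(120, 16, 1, peak_bin = 1, amp = 2.5, seed = 5)
  X <- ep$data[, , 1]
  y <- factor(ep$meta$outcome, levels = c("N", "P"))
  grid <- c(0.005, 0.01, 0.025, 0.05, 0.1, 0.2, 0.5)
  nz <- vapply(grid, function(l) sum(train_l1_logistic(X, y, l)$weights != 0),
               integer(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("accuracy time courses localise planted signal and sit at chance without it", {
  ep <- make_epochs(150, 16, 25, peak_bin = 12, amp = 2.5, seed = 6)
  curve <- accuracy_timecourse(ep, seed = 1)
  expect_length(curve$accuracy, 25)
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
  expect_lte(abs(which.max(curve$accuracy) - 12), 1)
  expect_gt(max(curve$accuracy), 0.6)
  # off-peak bins carry no label information
  expect_lt(abs(mean(curve$accuracy[-c(11:13)]) - 0.5), 0.05)

  # label-independent features: whole curve at chance
  ep0 <- make_epochs(150, 16, 10, peak_bin = 1, amp = 0, seed = 7)
  c0 <- accuracy_timecourse(ep0, seed = 1)
  expect_lt(abs(mean(c0$accuracy) - 0.5), 0.05)

  # folds reduced with a warning when the rare class is tiny
  ep_small <- make_epochs(40, 8, 2, peak_bin = 1, amp = 1, ratio = 9, seed = 8)
  w <- capture_warnings(accuracy_timecourse(ep_small, folds = 10))
  expect_true(any(grepl("reducing folds", w)))
})

test_that("peak/penalty selection picks the consensus bin and a competitive lambda", {
  ep <- make_epochs(160, 16, 20, peak_bin = 9, amp = 2.5, seed = 9)
  curve <- accuracy_timecourse(ep, seed = 1)

  # single participant, single-lambda grid: returns that lambda
  one <- select_peak_and_lambda(list(curve), list(ep), lambda_grid = 0.07)
  expect_equal(one$lambda_star, 0.07)
  expect_equal(one$bin_star, which.max(curve$accuracy))

  # identical curves across participants: consensus equals each argmax
  three <- select_peak_and_lambda(list(curve, curve, curve), list(ep, ep, ep),
                                  lambda_grid = c(0.01, 0.025, 0.1))
  expect_equal(three$bin_star, which.max(curve$accuracy))

  # optimised lambda does not lose to the fixed 0.025 beyond fold noise
  sel <- select_peak_and_lambda(list(curve), list(ep),
                                lambda_grid = c(0.005, 0.01, 0.025, 0.05, 0.1))
  acc_star <- sel$cv_accuracy[1, sel$lambda_grid == sel$lambda_star]
  acc_fixed <- sel$cv_accuracy[1, sel$lambda_grid == 0.025]
  expect_gte(acc_star, acc_fixed - 0.05)
  expect_error(select_peak_and_lambda(list(curve), list(ep), lambda_grid = numeric(0)),
               "non-empty")
})

test_that("the classifier suite is complete, deterministic, and null-centred", {
  ep <- make_epochs(140, 16, 5, peak_bin = 3, amp = 2.5, seed = 10)
  base <- make_epochs(60, 16, 1, peak_bin = 1, amp = 0, seed = 11)
  base$kind <- "baseline"
  base$meta$outcome <- "baseline"
  suite <- build_classifier_suite(ep, base, bin_star = 3, lambda = 0.025,
                                  n_perm = 100, seed = 2)
  expect_named(suite$models, c("P_vs_N", "P_vs_base", "N_vs_base"))
  expect_length(suite$permuted$P_vs_N, 100)
  expect_length(suite$permuted$N_vs_base, 100)

  again <- build_classifier_suite(ep, base, bin_star = 3, lambda = 0.025,
                                  n_perm = 100, seed = 2)
  expect_identical(lapply(suite$permuted$P_vs_N, `[[`, "weights"),
                   lapply(again$permuted$P_vs_N, `[[`, "weights"))

  # permuted ensemble scores at chance on fresh labelled data
  ep_test <- make_epochs(200, 16, 5, peak_bin = 3, amp = 2.5, seed = 12)
  accs <- vapply(suite$permuted$P_vs_N, function(m) {
    p <- predict(m, ep_test$data[, , 3])
    balanced_accuracy(ifelse(p > 0.5, "P", "N"), ep_test$meta$outcome, "P")
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(length(accs)) + 0.01)
})

test_that("cross-classification generalises a condition-invariant code", {
  ep <- make_epochs(240, 16, 1, peak_bin = 1, amp = 2.5, seed = 13)
  cc <- cross_classification(ep, bin_star = 1, lambda = 0.025)
  expect_equal(nrow(cc), 9)
  expect_setequal(cc$condition, c("loss_prob", "loss_mag"))
  overall <- accuracy_timecourse(ep, seed = 1)$accuracy[1]
  expect_true(all(abs(cc$accuracy - overall) < 0.15, na.rm = TRUE))
})

test_that("the group Wilcoxon on shuffled labels is calibrated", {
  set.seed(14)
  n_sig <- 0L
  for (run in 1:50) {
    accs <- lapply(1:5, function(s) {
      ep <- make_epochs(72, 8, 1, peak_bin = 1, amp = 2.5, seed = 100 * run + s)
      ep$meta$outcome <- sample(ep$meta$outcome) # break the label-feature link
      suppressWarnings(cross_classification(ep, bin_star = 1, lambda = 0.025))
    })
    if (cross_classification_test(accs)$p_value < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 5) # p >= 0.05 in at least 90% of null runs
})

test_that("per-condition curves track the planted signal-to-noise ordering", {
  ep <- make_epochs(300, 16, 8, peak_bin = 4, amp = 2.2, seed = 15,
                    amp_by_level = c(low = 0.35, medium = 1, high = 1.6))
  pc <- per_condition_timecourses(ep, bin_star = 4)
  expect_length(pc$curves, 3)
  b2p <- pc$baseline_to_peak[c("low", "medium", "high")]
  expect_true(b2p["low"] < b2p["medium"] & b2p["medium"] < b2p["high"])

  # identical data replicated across levels gives identical curves
  ep2 <- make_epochs(60, 8, 6, peak_bin = 3, amp = 2.5, seed = 16)
  rep3 <- ep2
  rep3$data <- ep2$data[rep(1:60, 3), , , drop = FALSE]
  rep3$meta <- ep2$meta[rep(1:60, 3), ]
  rep3$meta$loss_prob_level <- rep(c("low", "medium", "high"), each = 60)
  pc2 <- per_condition_timecourses(rep3, bin_star = 3)
  expect_equal(pc2$curves$low$accuracy, pc2$curves$high$accuracy)
})
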