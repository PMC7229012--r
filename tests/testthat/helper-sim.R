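# Shared desk-scale fixtures. Expensive objects are built once per test run
# and cached; sizes are deliberately small (few channels, one short block).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_config <- function(trials_per_block = 54, n_blocks = 1, n_training = 0) {
  task_config(n_training_trials = n_training, n_blocks = n_blocks,
              trials_per_block = trials_per_block)
}

small_model <- function(...) {
  sensor_model(n_channels = 24, blink_channels = 1:8, pattern_seed = 7, ...)
}

# One small simulated participant reused by structural tests.
small_participant <- function() {
  cached("small_participant", suppressMessages(
    simulate_participant(small_config(), model = small_model(), seed = 11,
                         n_keep = 24)
  ))
}

# Synthetic outcome-like epoch set built directly (no recording): two sparse
# class patterns planted at `peak_bin` with per-epoch amplitude `amp`,
# Gaussian noise elsewhere. Fast path for classifier-level tests.
make_epochs <- function(n_epochs, n_channels, n_bins, peak_bin, amp = 2,
                        ratio = 4, seed = 1, kind = "outcome",
                        amp_by_level = NULL) {
  set.seed(seed)
  k <- max(2L, floor(n_channels / 4))
  sup <- sample(n_channels, 2 * k)
  pP <- numeric(n_channels); pP[sup[1:k]] <- rnorm(k); pP <- pP / sqrt(sum(pP^2))
  pN <- numeric(n_channels); pN[sup[(k + 1):(2 * k)]] <- rnorm(k); pN <- pN / sqrt(sum(pN^2))
  nP <- round(n_epochs * ratio / (1 + ratio))
  y <- rep(c("P", "N"), c(nP, n_epochs - nP))[sample.int(n_epochs)]
  lev <- sample(c("low", "medium", "high"), n_epochs, replace = TRUE)
  arr <- array(rnorm(n_epochs * n_channels * n_bins), c(n_epochs, n_channels, n_bins))
  for (i in seq_len(n_epochs)) {
    a <- if (is.null(amp_by_level)) amp else amp * amp_by_level[[lev[i]]]
    arr[i, , peak_bin] <- arr[i, , peak_bin] + a * (if (y[i] == "P") pP else pN)
  }
  meta <- data.frame(
    trial_id = seq_len(n_epochs), outcome = y,
    loss_prob_level = lev,
    loss_magnitude = sample(0:5, n_epochs, replace = TRUE),
    choice = "approach", participant_id = "sim",
    stringsAsFactors = FALSE
  )
  structure(
    list(data = arr, kind = kind, fs = 100, bin_width = 10,
         window = c(0, n_bins * 10), meta = meta,
         channels = seq_len(n_channels), pattern_P = pP, pattern_N = pN),
    class = "epoch_set"
  )
}

# Synthetic decoded-probability series with given values matrix.
make_prob_series <- function(values, participant_id = "sim", contrast = "P_vs_N",
                             meta = NULL) {
  if (is.null(meta)) {
    meta <- data.frame(
      trial_id = seq_len(nrow(values)),
      outcome = NA_character_,
      loss_prob_level = sample(c("low", "medium", "high"), nrow(values), TRUE),
      loss_magnitude = sample(0:5, nrow(values), TRUE),
      choice = sample(c("approach", "avoid"), nrow(values), TRUE),
      participant_id = participant_id,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(values = values, kind = "trial_start", bin_width = 10, meta = meta,
         contrast = contrast, participant_id = participant_id),
    class = "prob_series"
  )
}

# Long-format null LME input: inverse-sigmoid-scale response with subject
# intercepts and no condition effects, complete over bins.
make_lme_null_data <- function(n_subj, n_trials, n_bins, sd_subj = 0.5,
                               sd_noise = 1, seed = 1,
                               factors = c("loss_probability", "choice")) {
  set.seed(seed)
  base <- expand.grid(trial = seq_len(n_trials), subject = sprintf("s%02d", seq_len(n_subj)),
                      stringsAsFactors = FALSE)
  base$loss_probability <- sample(rep_len(c("low", "medium", "high"), n_trials))[
    rep(seq_len(n_trials), n_subj)]
  base$loss_magnitude <- sample(rep_len(0:5, n_trials))[rep(seq_len(n_trials), n_subj)]
  base$choice <- sample(c("avoid", "approach"), nrow(base), TRUE)
  b_subj <- rnorm(n_subj, 0, sd_subj)
  names(b_subj) <- sprintf("s%02d", seq_len(n_subj))
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    d <- base
    d$bin <- b
    d$y <- b_subj[d$subject] + rnorm(nrow(d), 0, sd_noise)
    d
  }))
  out
}
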