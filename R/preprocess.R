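#' Filter and downsample a continuous recording to the analysis rate
#'
#' Recordings sampled at 600 Hz are zero-phase high-pass filtered at 0.5 Hz
#' (4th-order Butterworth, `filtfilt`) to remove slow drifts, notch-filtered
#' at 50 Hz (2nd-order band-stop, 48-52 Hz) to remove mains noise, and
#' decimated to 100 Hz. Recordings already at 100 Hz are returned unchanged.
#' Annotation times are in seconds and are unaffected by resampling.
#'
#' @param rec A `sensor_recording`.
#' @return A `sensor_recording` at 100 Hz.
#' @export
preprocess_continuous <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (!rec$fs %in% c(100, 600)) stopf("fs must be 100 or 600 Hz")
  if (rec$fs == 100) {
    message("recording already at 100 Hz; returned unchanged")
    return(rec)
  }
  n <- ncol(rec$data)
  if (n < 2 * rec$fs) stopf("recording too short for filter warm-up (< 2 s)")
  nyq <- rec$fs / 2
  hp <- signal::butter(4, 0.5 / nyq, type = "high")
  notch <- signal::butter(2, c(48, 52) / nyq, type = "stop")
  q <- rec$fs / 100
  filtered <- t(apply(rec$data, 1L, function(x) {
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(notch, x)
    signal::decimate(x, q)
  }))
  structure(list(data = filtered, fs = 100, annotations = rec$annotations),
            class = "sensor_recording")
}

#' Select the channels least affected by eyeblinks
#'
#' Scores each channel by the mean squared amplitude of its blink-locked
#' average over a 0-400 ms window following each blink annotation, and retains
#' the `n_keep` channels with the lowest scores (ties broken by channel
#' index). With no blink events all scores are zero and the first `n_keep`
#' channels are retained with a warning.
#'
#' @param rec A `sensor_recording` with blink annotations.
#' @param n_keep Number of channels to retain (default 135).
#' @return An object of class `channel_selection`: `retained` (sorted channel
#'   indices), `scores` (per-channel artifact score), `n_keep`.
#' @export
select_channels <- function(rec, n_keep = 135L) {
  stopifnot(inherits(rec, "sensor_recording"))
  n_ch <- nrow(rec$data)
  if (n_keep > n_ch) stopf("n_keep (%d) exceeds channel count (%d)", n_keep, n_ch)
  blink_t <- rec$annotations$time[rec$annotations$type == "blink"]
  win_len <- round(0.4 * rec$fs)
  if (length(blink_t) == 0L) {
    warnf("no blink events: all scores 0, retaining first %d channels by index", n_keep)
    scores <- numeric(n_ch)
  } else {
    avg <- matrix(0, n_ch, win_len)
    used <- 0L
    for (bt in blink_t) {
      i0 <- round(bt * rec$fs) + 1L
      idx <- i0:(i0 + win_len - 1L)
      if (idx[1] >= 1L && idx[length(idx)] <= ncol(rec$data)) {
        avg <- avg + rec$data[, idx, drop = FALSE]
        used <- used + 1L
      }
    }
    if (used == 0L) stopf("no blink window fits inside the recording")
    avg <- avg / used
    scores <- rowMeans(avg^2)
  }
  retained <- sort(order(scores, seq_len(n_ch))[seq_len(n_keep)])
  structure(list(retained = retained, scores = scores, n_keep = as.integer(n_keep)),
            class = "channel_selection")
}

#' @export
print.channel_selection <- function(x, ...) {
  cat(sprintf("<channel_selection> %d of %d channels retained\n",
              length(x$retained), length(x$scores)))
  invisible(x)
}

epoch_windows <- list(
  outcome = c(0, 750),
  trial_start = c(0, 1500),
  token = c(0, 300)
)

#' Extract event-locked epochs from a preprocessed recording
#'
#' Cuts epochs x channels x 10-ms-bin tensors around the locking events of the
#' requested kind, applying the exclusion rules of the analysis:
#' * `trial_start` (0-1500 ms): dropped when the token appeared within
#'   1500 ms of trial start or a movement occurred inside the window;
#' * `token` (0-300 ms): dropped when a movement or the token offset occurred
#'   before 300 ms from token appearance;
#' * `outcome` (0-750 ms, 75 bins): locked to P/N outcome onsets; avoidance
#'   and F trials are excluded.
#'
#' Training trials are never epoched. Windows are half-open `[start, end)` in
#' ms relative to the locking event; bin `t` covers `[10t, 10t + 10)` ms.
#' No baseline correction is applied.
#'
#' @param rec A 100-Hz `sensor_recording`.
#' @param trials The matching `trial_table`.
#' @param kind One of `"outcome"`, `"trial_start"`, `"token"`.
#' @param channels Optional integer vector (or `channel_selection`) of
#'   channels to keep; default all.
#' @param participant_id Label stored in the epoch metadata.
#' @return An object of class `epoch_set`: `data` (epochs x channels x bins),
#'   `kind`, `fs`, `bin_width` (ms), `window` (ms), `meta` (one row per epoch:
#'   `trial_id`, `outcome`, `loss_prob_level`, `loss_magnitude`, `choice`,
#'   `participant_id`), `channels`.
#' @export
extract_epochs <- function(rec, trials, kind = c("outcome", "trial_start", "token"),
                           channels = NULL, participant_id = "s01") {
  stopifnot(inherits(rec, "sensor_recording"), inherits(trials, "trial_table"))
  kind <- match.arg(kind)
  if (rec$fs != 100) stopf("epochs are extracted at the 100 Hz analysis rate; preprocess first")
  if (inherits(channels, "channel_selection")) channels <- channels$retained
  if (is.null(channels)) channels <- seq_len(nrow(rec$data))
  win <- epoch_windows[[kind]]
  n_bins <- as.integer(diff(win) / 10)

  keep <- !trials$is_training
  tt <- trials[keep, , drop = FALSE]
  lock <- switch(kind,
    outcome = tt$outcome_onset,
    trial_start = tt$trial_start,
    token = tt$token_onset
  )
  ok <- switch(kind,
    outcome = tt$outcome %in% c("P", "N"),
    trial_start = (tt$token_onset - tt$trial_start) >= 1.5 &
      (is.na(tt$move_time) | (tt$move_time - tt$trial_start) >= 1.5),
    token = (tt$token_offset - tt$token_onset) >= 0.3 &
      (is.na(tt$move_time) | (tt$move_time - tt$token_onset) >= 0.3)
  )
  ok[is.na(lock)] <- FALSE
  tt <- tt[ok, , drop = FALSE]
  lock <- lock[ok]

  arr <- array(NA_real_, dim = c(nrow(tt), length(channels), n_bins))
  for (i in seq_len(nrow(tt))) {
    i0 <- round(lock[i] * rec$fs) + 1L
    idx <- i0:(i0 + n_bins - 1L)
    if (idx[1] < 1L || idx[length(idx)] > ncol(rec$data)) {
      stopf("epoch window for trial %d falls outside the recording", tt$trial_id[i])
    }
    arr[i, , ] <- rec$data[channels, idx, drop = FALSE]
  }
  meta <- data.frame(
    trial_id = tt$trial_id,
    outcome = tt$outcome,
    loss_prob_level = tt$loss_prob_level,
    loss_magnitude = tt$loss_magnitude,
    choice = tt$choice,
    participant_id = participant_id,
    stringsAsFactors = FALSE
  )
  structure(
    list(data = arr, kind = kind, fs = rec$fs, bin_width = 10,
         window = win, meta = meta, channels = channels),
    class = "epoch_set"
  )
}

#' Draw baseline exemplars from long inter-trial intervals
#'
#' Takes `n` single-bin exemplars at uniformly random 10-ms bins within the
#' 1000 ms preceding trial starts, drawing only from trials whose preceding
#' inter-trial interval exceeded 2000 ms (to avoid interference from the
#' previous trial). The first trial of a session is never eligible.
#'
#' @param rec A 100-Hz `sensor_recording`.
#' @param trials The matching `trial_table`.
#' @param n Number of exemplars (default 100).
#' @param channels Optional channel subset as in [extract_epochs()].
#' @param participant_id Label stored in the metadata.
#' @param seed Integer seed making the draw reproducible.
#' @return An `epoch_set` of kind `"baseline"` with `n` epochs x channels x 1
#'   bin; `meta$time` records each exemplar's bin time in seconds.
#' @export
extract_baseline <- function(rec, trials, n = 100L, channels = NULL,
                             participant_id = "s01", seed = 1L) {
  stopifnot(inherits(rec, "sensor_recording"), inherits(trials, "trial_table"))
  if (rec$fs != 100) stopf("baseline exemplars are extracted at 100 Hz; preprocess first")
  if (inherits(channels, "channel_selection")) channels <- channels$retained
  if (is.null(channels)) channels <- seq_len(nrow(rec$data))

  prev_iti <- c(NA_real_, trials$iti[-nrow(trials)])
  eligible <- which(!trials$is_training & !is.na(prev_iti) & prev_iti > 2)
  if (length(eligible) == 0L) {
    stopf("no inter-trial interval exceeds 2000 ms; simulate a longer session")
  }

  with_rng_seed(seed, {
    pick <- eligible[sample.int(length(eligible), n, replace = TRUE)]
    offs_bin <- sample.int(100L, n, replace = TRUE) - 1L # 100 bins in [-1000, 0) ms
    t_bin <- trials$trial_start[pick] - 1 + offs_bin / 100
    arr <- array(NA_real_, dim = c(n, length(channels), 1L))
    for (i in seq_len(n)) {
      idx <- round(t_bin[i] * rec$fs) + 1L
      if (idx < 1L || idx > ncol(rec$data)) {
        stopf("baseline bin for trial %d falls outside the recording", trials$trial_id[pick[i]])
      }
      arr[i, , 1L] <- rec$data[channels, idx]
    }
    meta <- data.frame(
      trial_id = trials$trial_id[pick],
      outcome = "baseline",
      loss_prob_level = NA_character_,
      loss_magnitude = NA_integer_,
      choice = NA_character_,
      participant_id = participant_id,
      time = t_bin,
      stringsAsFactors = FALSE
    )
    structure(
      list(data = arr, kind = "baseline", fs = rec$fs, bin_width = 10,
           window = c(-1000, 0), meta = meta, channels = channels),
      class = "epoch_set"
    )
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set:%s> %d epochs x %d channels x %d bins (%g-ms bins, window %g..%g ms)\n",
              x$kind, d[1], d[2], d[3], x$bin_width, x$window[1], x$window[2]))
  invisible(x)
}
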