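#' Simulate one participant end to end
#'
#' Convenience wrapper chaining [simulate_task()], [simulate_recording()],
#' [preprocess_continuous()], [select_channels()], [extract_epochs()] and
#' [extract_baseline()] for a single simulated participant, as the analysis
#' examples and tests use it.
#'
#' @param config A [task_config()].
#' @param policy A [behaviour_policy()].
#' @param model A [sensor_model()].
#' @param seed Integer seed (drives task, recording and baseline draws).
#' @param participant_id Label carried into all epoch metadata.
#' @param n_keep Channels to retain (default 135; capped at the channel
#'   count).
#' @param n_baseline Baseline exemplars (default 100).
#' @param kinds Epoch kinds to extract.
#' @return A list: `trials`, `recording`, `truth`, `selection`, and one
#'   `epoch_set` per requested kind (`outcome`, `trial_start`, `token`,
#'   `baseline`).
#' @export
simulate_participant <- function(config = task_config(),
                                 policy = behaviour_policy(),
                                 model = sensor_model(),
                                 seed = 1L,
                                 participant_id = sprintf("s%02d", seed),
                                 n_keep = 135L,
                                 n_baseline = 100L,
                                 kinds = c("outcome", "trial_start", "token")) {
  trials <- simulate_task(config, policy, seed = seed)
  sim <- simulate_recording(trials, model, seed = seed + 10000L)
  rec <- suppressMessages(preprocess_continuous(sim$recording))
  sel <- select_channels(rec, n_keep = min(n_keep, nrow(rec$data)))
  out <- list(trials = trials, recording = rec, truth = sim$truth, selection = sel)
  for (k in kinds) {
    out[[k]] <- extract_epochs(rec, trials, kind = k, channels = sel,
                               participant_id = participant_id)
  }
  out$baseline <- extract_baseline(rec, trials, n = n_baseline, channels = sel,
                                   participant_id = participant_id,
                                   seed = seed + 20000L)
  out
}
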