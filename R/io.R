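#' Read and write trial tables as CSV
#'
#' Trial tables round-trip through plain CSV with a header row so they can be
#' inspected or produced by other tools.
#'
#' @param trials A `trial_table`.
#' @param path File path.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   returns a `trial_table`.
#' @export
write_trial_table <- function(trials, path) {
  stopifnot(inherits(trials, "trial_table"))
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("trial_table", "data.frame")
  d
}

#' Read and write simulation configurations as JSON
#'
#' Serialises [task_config()], [behaviour_policy()] and [sensor_model()]
#' objects (the spatial patterns are stored verbatim so a round trip is
#' exact).
#'
#' @param config A `task_config`, `behaviour_policy` or `sensor_model`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` restores
#'   the object with its original class.
#' @export
write_config <- function(config, path) {
  cls <- class(config)[1L]
  if (!cls %in% c("task_config", "behaviour_policy", "sensor_model")) {
    stopf("unsupported config class: %s", cls)
  }
  fields <- lapply(unclass(config), function(x) {
    # named atomic vectors must become objects, not bare arrays, in JSON
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  payload <- list(class = cls, fields = fields)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- payload$fields
  num_vec <- function(x) stats::setNames(as.numeric(x), names(x))
  obj <- switch(payload$class,
    task_config = task_config(
      n_training_trials = fields$n_training_trials,
      n_blocks = fields$n_blocks,
      trials_per_block = fields$trials_per_block,
      per_bin_catch_prob = num_vec(unlist(fields$per_bin_catch_prob)),
      bin_width_ms = fields$bin_width_ms,
      loss_magnitudes = fields$loss_magnitudes,
      gamma_shape = fields$gamma_shape,
      gamma_scale = fields$gamma_scale,
      token_cap = fields$token_cap,
      iti_cap = fields$iti_cap,
      session_start = fields$session_start
    ),
    behaviour_policy = behaviour_policy(
      approach_coefs = num_vec(unlist(fields$approach_coefs)),
      latency_meanlog = fields$latency_meanlog,
      latency_sdlog = fields$latency_sdlog,
      exposure = fields$exposure,
      travel_frac = fields$travel_frac
    ),
    sensor_model = {
      m <- sensor_model(
        n_channels = fields$n_channels,
        fs = fields$fs,
        evoked_peak_latency_ms = fields$evoked_peak_latency_ms,
        evoked_fwhm_ms = fields$evoked_fwhm_ms,
        evoked_amplitude = fields$evoked_amplitude,
        evoked_amplitude_by_prob = fields$evoked_amplitude_by_prob,
        pattern_sparsity = fields$pattern_sparsity,
        delib_amplitude = fields$delib_amplitude,
        dwell = fields$dwell,
        bias = num_vec(unlist(fields$bias)),
        noise_sd = fields$noise_sd,
        noise_ar = fields$noise_ar,
        blink_rate = fields$blink_rate,
        blink_amplitude = fields$blink_amplitude,
        blink_channels = fields$blink_channels
      )
      m$pattern_P <- as.numeric(fields$pattern_P)
      m$pattern_N <- as.numeric(fields$pattern_N)
      m
    },
    stopf("unsupported config class: %s", payload$class)
  )
  obj
}

#' Save and load recordings and epoch sets
#'
#' Continuous recordings and epoch tensors are runtime containers; they are
#' serialised with R's native RDS format (binary, intended for scratch use,
#' not for versioning). Trial tables and configurations use the plain-text
#' CSV/JSON writers.
#'
#' @param x A `sensor_recording`, `epoch_set`, `ground_truth` or other
#'   pipeline object.
#' @param path File path.
#' @return `save_object` returns `path` invisibly; `load_object` the object.
#' @export
save_object <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_object
#' @export
load_object <- function(path) readRDS(path)
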