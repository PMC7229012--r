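#' Decode representation probabilities from deliberation epochs
#'
#' Applies a trained classifier to every time bin of an epoch set: the channel
#' pattern is multiplied element-wise with the classifier weights, summed with
#' the intercept, and mapped onto `[0, 1]` with the standard logistic sigmoid.
#' For the P-vs-N contrast the value is `p(P)` and `p(N) = 1 - p(P)`.
#'
#' @param model A `classifier_model`.
#' @param epochs An `epoch_set` (trial-start: 150 bins; token: 30 bins).
#' @return An object of class `prob_series`: `values` (trials x bins matrix in
#'   `(0, 1)`), `kind`, `bin_width`, `meta` (per-trial conditions/choice),
#'   `contrast`, `participant_id`.
#' @export
decode <- function(model, epochs) {
  stopifnot(inherits(model, "classifier_model"), inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[2L] != length(model$weights)) {
    stopf("channel mismatch: model has %d weights, epochs %d channels",
          length(model$weights), d[2L])
  }
  vals <- matrix(NA_real_, d[1L], d[3L])
  for (b in seq_len(d[3L])) {
    vals[, b] <- logistic(
      drop(epochs$data[, , b, drop = TRUE] %*% model$weights) + model$intercept
    )
  }
  structure(
    list(values = vals, kind = epochs$kind, bin_width = epochs$bin_width,
         meta = epochs$meta, contrast = model$contrast,
         participant_id = epochs$meta$participant_id[1L]),
    class = "prob_series"
  )
}

#' @export
print.prob_series <- function(x, ...) {
  cat(sprintf("<prob_series:%s> %d trials x %d bins (%s)\n",
              x$kind, nrow(x$values), ncol(x$values),
              ifelse(is.na(x$contrast), "?", x$contrast)))
  invisible(x)
}

#' Mean autocorrelation of decoded probabilities
#'
#' Computes, for each trial, the Pearson autocorrelation of the trial-wise
#' de-meaned probability series at lags of one bin up to `max_lag_ms`, using
#' the biased normalisation (sums divided by the series length), then
#' averages across trials. Zero-variance trials are skipped and counted; an
#' error is raised when no trial survives.
#'
#' @param series A `prob_series` (trial-start epochs, 150 bins, give the most
#'   informative curves).
#' @param max_lag_ms Largest lag in milliseconds (default 500).
#' @param mode `"per_trial"` (default) correlates each trial separately and
#'   averages the coefficients; `"pooled"` pools the de-meaned lagged
#'   cross-products over trials before normalising (never crossing trial
#'   boundaries). The two agree in expectation; per-trial weighting is the
#'   package default.
#' @return An object of class `acf_curve`: `acf` (one value per lag),
#'   `lags_ms`, `n_trials_used`, `n_skipped`, `mode`.
#' @export
autocorrelation_curve <- function(series, max_lag_ms = 500,
                                  mode = c("per_trial", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "prob_series"))
  n_bins <- ncol(series$values)
  max_lag <- min(floor(max_lag_ms / series$bin_width), n_bins - 1L)
  if (max_lag < 1L) stopf("series too short for the requested lags")
  acc <- matrix(NA_real_, nrow(series$values), max_lag)
  denoms <- rep(NA_real_, nrow(series$values))
  skipped <- 0L
  for (i in seq_len(nrow(series$values))) {
    x <- series$values[i, ] - mean(series$values[i, ])
    denom <- sum(x^2) / n_bins
    if (denom == 0) {
      skipped <- skipped + 1L
      next
    }
    denoms[i] <- denom
    acc[i, ] <- vapply(seq_len(max_lag), function(k) {
      sum(x[seq_len(n_bins - k)] * x[(k + 1L):n_bins]) / n_bins / denom
    }, numeric(1))
  }
  used <- nrow(acc) - skipped
  if (used == 0L) stopf("all trials have zero variance; nothing to autocorrelate")
  if (skipped > 0L) message(sprintf("%d zero-variance trials skipped", skipped))
  est <- if (mode == "per_trial") {
    colMeans(acc, na.rm = TRUE)
  } else {
    ok <- !is.na(denoms)
    colSums(acc[ok, , drop = FALSE] * denoms[ok]) / sum(denoms[ok])
  }
  structure(
    list(acf = est, lags_ms = seq_len(max_lag) * series$bin_width,
         n_trials_used = used, n_skipped = skipped, mode = mode),
    class = "acf_curve"
  )
}

ll_curve <- function(observed, null_matrix, centre) {
  dev_obs <- abs(observed - centre)
  r <- vapply(seq_along(observed), function(k) {
    sum(abs(null_matrix[, k] - centre[k]) >= dev_obs[k])
  }, numeric(1))
  p_hat <- (r + 1) / (nrow(null_matrix) + 1)
  list(ll = -log(p_hat), sign = sign(observed - centre))
}

find_clusters <- function(ll, sgn, threshold) {
  above <- ll > threshold
  out <- list()
  k <- 1L
  while (k <= length(ll)) {
    if (above[k]) {
      j <- k
      while (j < length(ll) && above[j + 1L] && sgn[j + 1L] == sgn[k]) j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        start = k, end = j, mass = sum(ll[k:j]), sign = sgn[k]
      )
      k <- j + 1L
    } else {
      k <- k + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), mass = numeric(0), sign = numeric(0))
}

#' Cluster-level permutation test against a permuted-classifier ensemble
#'
#' At each lag the two-sided exceedance probability of the observed value
#' under the null ensemble is estimated with the add-one correction
#' `p = (r + 1) / (n + 1)`, where `r` counts null values at least as far from
#' the null mean; its negative log is the LL statistic. Clusters are maximal
#' runs of consecutive lags with `LL > 3` and a common sign; cluster mass is
#' the summed LL. Each null ensemble member is scored the same way against
#' the remaining members (leave-one-out) and a cluster is significant when
#' its mass exceeds the 95th percentile of the null maximal-cluster masses.
#'
#' @param observed An `acf_curve` (or numeric vector) of observed values.
#' @param null_ensemble Matrix (members x lags) or list of `acf_curve`s from
#'   the permuted classifiers; at least 20 members.
#' @param ll_threshold Cluster-inclusion threshold on LL (default 3).
#' @param alpha Family-wise level of the max-cluster null (default 0.05).
#' @return An object of class `cluster_test_result`: `ll`, `sign`, `clusters`
#'   (with `significant` flags), `null_max`, `mass_threshold`, `lags_ms`.
#' @export
cluster_permutation_test <- function(observed, null_ensemble, ll_threshold = 3,
                                     alpha = 0.05) {
  lags_ms <- NULL
  if (inherits(observed, "acf_curve")) {
    lags_ms <- observed$lags_ms
    observed <- observed$acf
  }
  if (is.list(null_ensemble)) {
    null_ensemble <- do.call(rbind, lapply(null_ensemble, function(x) {
      if (inherits(x, "acf_curve")) x$acf else x
    }))
  }
  n_null <- nrow(null_ensemble)
  if (n_null < 20L) {
    stopf("null ensemble has %d members; at least 20 needed for usable p resolution", n_null)
  }
  if (ncol(null_ensemble) != length(observed)) stopf("lag counts differ")

  centre <- colMeans(null_ensemble)
  obs <- ll_curve(observed, null_ensemble, centre)
  clusters <- find_clusters(obs$ll, obs$sign, ll_threshold)

  null_max <- vapply(seq_len(n_null), function(j) {
    rest <- null_ensemble[-j, , drop = FALSE]
    cj <- colMeans(rest)
    lj <- ll_curve(null_ensemble[j, ], rest, cj)
    cl <- find_clusters(lj$ll, lj$sign, ll_threshold)
    if (nrow(cl)) max(cl$mass) else 0
  }, numeric(1))
  mass_threshold <- stats::quantile(null_max, 1 - alpha, names = FALSE)
  clusters$significant <- clusters$mass > mass_threshold
  structure(
    list(ll = obs$ll, sign = obs$sign, clusters = clusters,
         null_max = null_max, mass_threshold = mass_threshold,
         lags_ms = lags_ms),
    class = "cluster_test_result"
  )
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %d cluster(s), %d significant (mass > %.2f)\n",
              nrow(x$clusters), sum(x$clusters$significant), x$mass_threshold))
  invisible(x)
}

#' Collapse decoded probabilities into most-likely-outcome state sequences
#'
#' Each bin is assigned the positive outcome P when `p(P) > p_chance` and N
#' otherwise, where `p_chance` is the proportion of positive outcomes in the
#' training set (ties go to N, the strict-inequality rule). Maximal constant
#' runs form epochs of steady representation (dwells); the transition count
#' per trial is the number of dwells minus one.
#'
#' @param series A `prob_series` of `p(P)`.
#' @param n_pos,n_neg Positive/negative exemplar counts of the training set,
#'   e.g. `suite$n_labels["P"]` and `["N"]`; alternatively pass `p_chance`.
#' @param p_chance Decision threshold overriding the counts.
#' @return An object of class `state_stats`: `states` (trials x bins character
#'   matrix), `dwell_ms` (pooled dwell durations), `dwell_trial` (trial index
#'   per dwell), `transitions` (per trial), `p_chance`, `bin_width`.
#' @export
map_states <- function(series, n_pos = NULL, n_neg = NULL, p_chance = NULL) {
  stopifnot(inherits(series, "prob_series"))
  if (is.null(p_chance)) {
    if (is.null(n_pos) || is.null(n_neg)) stopf("supply n_pos and n_neg, or p_chance")
    p_chance <- n_pos / (n_pos + n_neg)
  }
  if (p_chance <= 0 || p_chance >= 1) {
    stopf("degenerate training set: p_chance = %g", p_chance)
  }
  states <- ifelse(series$values > p_chance, "P", "N")
  dwell_ms <- list()
  dwell_trial <- list()
  transitions <- integer(nrow(states))
  for (i in seq_len(nrow(states))) {
    r <- rle(states[i, ])
    dwell_ms[[i]] <- r$lengths * series$bin_width
    dwell_trial[[i]] <- rep(i, length(r$lengths))
    transitions[i] <- length(r$lengths) - 1L
  }
  structure(
    list(states = states, dwell_ms = unlist(dwell_ms),
         dwell_trial = unlist(dwell_trial), transitions = transitions,
         p_chance = p_chance, bin_width = series$bin_width),
    class = "state_stats"
  )
}

#' @export
print.state_stats <- function(x, ...) {
  cat(sprintf(
    "<state_stats> %d trials, mean dwell %.0f ms, mean transitions %.2f (p_chance=%.3f)\n",
    nrow(x$states), mean(x$dwell_ms), mean(x$transitions), x$p_chance))
  invisible(x)
}

#' Dwell-duration and transition-count tests against permuted classifiers
#'
#' Compares observed steady-representation epochs with the null ensemble from
#' permuted classifiers: a two-sample Kolmogorov-Smirnov test on the pooled
#' dwell durations, and a lower-tail permutation p-value for the mean number
#' of transitions per trial (`p = r / n` with `r` the number of null members
#' whose mean transition count is at most the observed one; when `r = 0` the
#' result is reported as `< 1/n`).
#'
#' @param observed A `state_stats` from the true classifier.
#' @param null_list List of `state_stats` from the permuted classifiers.
#' @return A list: `ks` (the `htest`), `transition` with `observed_mean`,
#'   `null_means`, `p_value`, `p_ceiling` (`1/n` when `r = 0`, else `NA`) and
#'   a display `label`.
#' @export
dwell_transition_tests <- function(observed, null_list) {
  stopifnot(inherits(observed, "state_stats"))
  if (length(null_list) == 0L) stopf("null ensemble is empty")
  null_dwells <- unlist(lapply(null_list, `[[`, "dwell_ms"))
  if (length(observed$dwell_ms) == 0L || length(null_dwells) == 0L) {
    stopf("dwell samples must be non-empty")
  }
  ks <- suppressWarnings(stats::ks.test(observed$dwell_ms, null_dwells))
  null_means <- vapply(null_list, function(s) mean(s$transitions), numeric(1))
  obs_mean <- mean(observed$transitions)
  r <- sum(null_means <= obs_mean)
  n <- length(null_means)
  list(
    ks = ks,
    transition = list(
      observed_mean = obs_mean,
      null_means = null_means,
      p_value = r / n,
      p_ceiling = if (r == 0L) 1 / n else NA_real_,
      label = if (r == 0L) sprintf("< %.3f", 1 / n) else sprintf("= %.3f", r / n)
    )
  )
}
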