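#' Inverse logistic sigmoid with boundary clipping
#'
#' Maps a probability to the real line, `Y = ln(p' / (1 - p'))`, after
#' clipping `p` into `[eps, 1 - eps]` so boundary values stay finite. The
#' number of clipped values is reported via a message.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param eps Clip margin (default `1e-6`).
#' @return Real-valued transform, same length as `p`.
#' @export
inverse_sigmoid <- function(p, eps = 1e-6) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p must lie in [0, 1]")
  n_clip <- sum(p < eps | p > 1 - eps, na.rm = TRUE)
  if (n_clip > 0) message(sprintf("%d probabilities clipped to [%g, %g]", n_clip, eps, 1 - eps))
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Stack decoded probability series into long model input
#'
#' Converts a list of per-participant `prob_series` into the long data frame
#' consumed by [fit_lme_timecourse()]: one row per participant x trial x bin
#' with the decoded probability and the trial's condition and choice labels.
#'
#' @param series_list List of `prob_series` (one per participant, same epoch
#'   kind and bin count).
#' @return Data frame with columns `subject`, `trial`, `bin`, `p`,
#'   `loss_probability`, `loss_magnitude`, `choice`.
#' @export
prob_series_long <- function(series_list) {
  out <- lapply(series_list, function(s) {
    stopifnot(inherits(s, "prob_series"))
    n_tr <- nrow(s$values)
    n_bin <- ncol(s$values)
    data.frame(
      subject = rep(s$participant_id, n_tr * n_bin),
      trial = rep(s$meta$trial_id, n_bin),
      bin = rep(seq_len(n_bin), each = n_tr),
      p = as.vector(s$values),
      loss_probability = rep(s$meta$loss_prob_level, n_bin),
      loss_magnitude = rep(s$meta$loss_magnitude, n_bin),
      choice = rep(s$meta$choice, n_bin),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# Factor coding used throughout: categorical with low/0/avoid as references.
code_factors <- function(d, factors) {
  if ("loss_probability" %in% factors) {
    d$loss_probability <- factor(d$loss_probability, levels = c("low", "medium", "high"))
  }
  if ("loss_magnitude" %in% factors) {
    d$loss_magnitude <- factor(d$loss_magnitude)
  }
  if ("choice" %in% factors) {
    d$choice <- factor(d$choice, levels = c("avoid", "approach"))
  }
  d
}

# Per-subject-block whitening constants for V0 = I + theta^2 * Z Z'.
# Each block of size m has W = I + c * J with c = ((1 + theta^2 m)^(-1/2) - 1) / m,
# so that W V0 W' = I (up to the residual variance scale).
whiten_constants <- function(theta, block_sizes) {
  ((1 + theta^2 * block_sizes)^(-0.5) - 1) / block_sizes
}

whiten_matrix <- function(Y, block_index, cvec) {
  Y <- as.matrix(Y)
  for (b in seq_along(block_index)) {
    idx <- block_index[[b]]
    Y[idx, ] <- Y[idx, ] + cvec[b] * rep(colSums(Y[idx, , drop = FALSE]),
                                         each = length(idx))
  }
  Y
}

# Sequential (Type I) F statistics from a QR of the whitened design applied
# to (columns of) whitened responses. Reproduces anova() on the REML fit.
whitened_F <- function(qr_Xw, assign, Yw) {
  Yw <- as.matrix(Yw)
  p <- qr_Xw$rank
  n <- nrow(Yw)
  qty <- qr.qty(qr_Xw, Yw)
  terms <- sort(unique(assign[assign > 0]))
  rss <- colSums(qty[(p + 1):n, , drop = FALSE]^2)
  sigma2 <- rss / (n - p)
  F <- matrix(NA_real_, length(terms), ncol(Yw))
  df1 <- integer(length(terms))
  for (j in seq_along(terms)) {
    rows <- which(assign == terms[j])
    df1[j] <- length(rows)
    F[j, ] <- colSums(qty[rows, , drop = FALSE]^2) / df1[j] / sigma2
  }
  list(F = F, df1 = df1, term_id = terms)
}

#' Per-bin linear mixed-effects analysis of decoded probabilities
#'
#' For each time bin, the inverse sigmoid of the decoded probability is
#' modelled with a full-factorial fixed structure over the requested factors
#' plus a random per-subject intercept, fitted by REML. Fixed-effect F
#' statistics are the sequential ANOVA values of the fitted model; p-values
#' use a conservative denominator degrees of freedom `df = N - K`, with `N`
#' the number of observations and `K` the number of all fixed and random
#' effects (fixed coefficients plus subject intercepts). Singular fits
#' (zero subject variance) are flagged.
#'
#' @param data Long data frame from [prob_series_long()] (or with the same
#'   columns); a column `y` may supply a pre-transformed response instead of
#'   `p`. Every subject x trial must appear at every analysed bin.
#' @param factors Character vector of fixed factors, any of
#'   `"loss_probability"`, `"loss_magnitude"`, `"choice"`; full factorial.
#' @param eps Clip margin for [inverse_sigmoid()].
#' @return An object of class `lme_timecourse`: `table` (bin x effect rows
#'   with `F`, `df1`, `df2`, `p`, `singular`), `factors`, `N`, `K`, plus the
#'   internal state reused by [cluster_correct_timecourse()].
#' @export
fit_lme_timecourse <- function(data, factors = c("loss_probability", "loss_magnitude", "choice"),
                               eps = 1e-6) {
  if (length(unique(data$subject)) < 2L) stopf("at least 2 subjects are required")
  d <- code_factors(data, factors)
  d$subject <- factor(d$subject)
  if (!"y" %in% names(d)) d$y <- suppressMessages(inverse_sigmoid(d$p, eps))

  bins <- sort(unique(d$bin))
  d <- d[order(d$bin, d$subject, d$trial), , drop = FALSE]
  per_bin <- split(d, d$bin)
  n_obs <- vapply(per_bin, nrow, integer(1))
  if (length(unique(n_obs)) != 1L) stopf("each bin must contain the same trials")
  d0 <- per_bin[[1L]]
  key0 <- paste(d0$subject, d0$trial)
  for (pb in per_bin) {
    if (!identical(paste(pb$subject, pb$trial), key0)) {
      stopf("subject/trial composition differs across bins")
    }
  }

  fixed_rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(paste("y ~", fixed_rhs, "+ (1 | subject)"))
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)), d0)
  if (qr(X)$rank < ncol(X)) stopf("fixed-effects design is rank deficient; drop empty cells")
  assign <- attr(X, "assign")
  term_labels <- attr(stats::terms(stats::as.formula(paste("~", fixed_rhs))), "term.labels")
  block_index <- split(seq_len(nrow(d0)), d0$subject)
  block_sizes <- lengths(block_index)

  N <- nrow(d0)
  K <- ncol(X) + nlevels(d0$subject)
  if (N - K <= 0) stopf("df = N - K is not positive (N=%d, K=%d)", N, K)

  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  rows <- list()
  thetas <- numeric(length(bins))
  Ymat <- matrix(NA_real_, N, length(bins))
  for (bi in seq_along(bins)) {
    db <- per_bin[[bi]]
    fit <- lme4::lmer(form, data = db, REML = TRUE, control = ctrl)
    theta <- lme4::getME(fit, "theta")[[1L]]
    thetas[bi] <- theta
    singular <- lme4::isSingular(fit)
    cvec <- whiten_constants(theta, block_sizes)
    Yw <- whiten_matrix(cbind(db$y), block_index, cvec)
    Xw <- whiten_matrix(X, block_index, cvec)
    wf <- whitened_F(qr(Xw), assign, Yw)
    Ymat[, bi] <- db$y
    rows[[bi]] <- data.frame(
      bin = bins[bi],
      effect = term_labels[wf$term_id],
      F = wf$F[, 1L],
      df1 = wf$df1,
      df2 = N - K,
      p = stats::pf(wf$F[, 1L], wf$df1, N - K, lower.tail = FALSE),
      singular = singular,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(table = do.call(rbind, rows), factors = factors, N = N, K = K,
         internal = list(X = X, assign = assign, term_labels = term_labels,
                         block_index = block_index, block_sizes = block_sizes,
                         thetas = thetas, Y = Ymat, bins = bins,
                         subject = d0$subject)),
    class = "lme_timecourse"
  )
}

#' @export
print.lme_timecourse <- function(x, ...) {
  cat(sprintf("<lme_timecourse> %d bins x %d effects, N=%d, K=%d (df2=%d)\n",
              length(x$internal$bins), length(x$internal$term_labels),
              x$N, x$K, x$N - x$K))
  invisible(x)
}

#' Cluster-level permutation correction of an LME time course
#'
#' Clusters are maximal runs of bins whose uncorrected fixed-effect p-value
#' falls below the inclusion threshold; cluster mass is the summed F. The
#' null distribution of the maximal cluster mass is built by permuting, for
#' every permutation and within each participant, the assignment of trials to
#' their label tuples — implemented by permuting the responses within
#' participant with one common permutation across bins, so the temporal
#' structure of the null is preserved — and recomputing the F time course by
#' generalised least squares on data whitened with each bin's fitted variance
#' components. A cluster is significant when its mass exceeds the
#' `1 - alpha` quantile of the null maxima. Singular bins are excluded from
#' cluster formation with a warning.
#'
#' @param result An `lme_timecourse` from [fit_lme_timecourse()].
#' @param n_perm Number of permutations (default 1000; fewer than 100 draws a
#'   resolution warning).
#' @param seed Integer seed for the permutations.
#' @param cluster_alpha Per-bin inclusion threshold (default 0.05).
#' @param alpha Family-wise level (default 0.05).
#' @return A list with one element per effect: `clusters` (data frame with
#'   `start_bin`, `end_bin`, `mass`, `significant`), `null_max`,
#'   `mass_threshold`.
#' @export
cluster_correct_timecourse <- function(result, n_perm = 1000L, seed = 1L,
                                       cluster_alpha = 0.05, alpha = 0.05) {
  stopifnot(inherits(result, "lme_timecourse"))
  if (n_perm < 100L) warnf("n_perm = %d gives coarse p resolution; 100+ recommended", n_perm)
  int <- result$internal
  n <- nrow(int$Y)
  n_bins <- length(int$bins)
  terms <- int$term_labels
  if (any(result$table$singular)) {
    warnf("%d singular bin fit(s) excluded from cluster formation",
          length(unique(result$table$bin[result$table$singular])))
  }

  # per-bin whitened designs (shared by all permutations)
  preps <- lapply(seq_len(n_bins), function(bi) {
    cvec <- whiten_constants(int$thetas[bi], int$block_sizes)
    list(cvec = cvec, qr = qr(whiten_matrix(int$X, int$block_index, cvec)))
  })

  with_rng_seed(seed, {
    perm_idx <- matrix(0L, n, n_perm)
    for (r in seq_len(n_perm)) {
      pi_r <- seq_len(n)
      for (idx in int$block_index) pi_r[idx] <- idx[sample.int(length(idx))]
      perm_idx[, r] <- pi_r
    }

    df1 <- vapply(split(int$assign[int$assign > 0], int$assign[int$assign > 0]),
                  length, integer(1))
    Fcrit <- stats::qf(1 - cluster_alpha, df1, result$N - result$K)
    nullF <- array(NA_real_, dim = c(length(terms), n_bins, n_perm))
    for (bi in seq_len(n_bins)) {
      Yb <- int$Y[, bi]
      Yperm <- matrix(Yb[perm_idx], n, n_perm)
      Yw <- whiten_matrix(Yperm, int$block_index, preps[[bi]]$cvec)
      nullF[, bi, ] <- whitened_F(preps[[bi]]$qr, int$assign, Yw)$F
    }

    out <- list()
    for (j in seq_along(terms)) {
      tab <- result$table[result$table$effect == terms[j], , drop = FALSE]
      tab <- tab[order(tab$bin), , drop = FALSE]
      supra <- tab$p < cluster_alpha & !tab$singular
      cl <- find_clusters(ifelse(supra, tab$F, 0), rep(1, nrow(tab)), 0)
      null_max <- vapply(seq_len(n_perm), function(r) {
        fr <- nullF[j, , r]
        fr[result$table$singular[result$table$effect == terms[j]]] <- 0
        sup <- fr > Fcrit[j]
        if (!any(sup)) return(0)
        max(find_clusters(ifelse(sup, fr, 0), rep(1, n_bins), 0)$mass)
      }, numeric(1))
      thr <- stats::quantile(null_max, 1 - alpha, names = FALSE)
      clusters <- if (nrow(cl)) {
        data.frame(start_bin = tab$bin[cl$start], end_bin = tab$bin[cl$end],
                   mass = cl$mass, significant = cl$mass > thr)
      } else {
        data.frame(start_bin = integer(0), end_bin = integer(0),
                   mass = numeric(0), significant = logical(0))
      }
      out[[terms[j]]] <- list(clusters = clusters, null_max = null_max,
                              mass_threshold = thr)
    }
    out
  })
}

wald_F_table <- function(fit, N, K) {
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  asgn <- attr(stats::model.matrix(fit), "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  rows <- lapply(sort(unique(asgn[asgn > 0])), function(tj) {
    idx <- which(asgn == tj)
    W <- drop(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% b[idx])
    df1 <- length(idx)
    F <- W / df1
    data.frame(effect = labels[tj], F = F, df1 = df1, df2 = N - K,
               p = stats::pf(F, df1, N - K, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mixed-effects analysis of task behaviour
#'
#' Fits the two behavioural models on the trial table across participants:
#' a logistic mixed model of the approach action and a linear mixed model of
#' approach latency (approach trials only), both with the full
#' loss-probability x loss-magnitude fixed structure and a random per-subject
#' intercept. F tests use `df = N - K` as in the time-course analysis; the
#' latency table reports the sequential ANOVA F of the REML fit, the
#' approach table a per-term Wald F from the logistic fit.
#'
#' @param trials Data frame with columns `subject`, `loss_prob_level`,
#'   `loss_magnitude`, `choice`, `action_latency` — e.g. per-participant
#'   [simulate_task()] tables row-bound with a `subject` column (training
#'   trials are dropped here).
#' @return A list: `approach` (F table, `n_obs`), `latency` (F table,
#'   `n_obs`), `fits` (the two merMod objects).
#' @export
behaviour_lme <- function(trials) {
  need <- c("subject", "loss_prob_level", "loss_magnitude", "choice", "action_latency")
  if (!all(need %in% names(trials))) {
    stopf("trials must have columns: %s", paste(need, collapse = ", "))
  }
  d <- trials
  if ("is_training" %in% names(d)) d <- d[!d$is_training, , drop = FALSE]
  if (length(unique(d$subject)) < 2L) stopf("at least 2 subjects are required")
  d$loss_probability <- factor(d$loss_prob_level, levels = c("low", "medium", "high"))
  d$loss_magnitude <- factor(d$loss_magnitude)
  d$subject <- factor(d$subject)
  d$approach <- as.integer(d$choice == "approach")
  if (length(unique(d$approach)) < 2L) {
    stopf("choice has no variability (all %s); the logistic model is undefined",
          ifelse(d$approach[1] == 1L, "approach", "avoid"))
  }

  g <- lme4::glmer(approach ~ loss_probability * loss_magnitude + (1 | subject),
                   data = d, family = stats::binomial(),
                   control = lme4::glmerControl(calc.derivs = FALSE))
  N_g <- nrow(d)
  K_g <- length(lme4::fixef(g)) + nlevels(d$subject)
  approach_tab <- wald_F_table(g, N_g, K_g)

  dl <- d[d$choice == "approach" & !is.na(d$action_latency), , drop = FALSE]
  l <- lme4::lmer(action_latency ~ loss_probability * loss_magnitude + (1 | subject),
                  data = dl, REML = TRUE,
                  control = lme4::lmerControl(calc.derivs = FALSE,
                                              check.conv.singular = "ignore"))
  an <- stats::anova(l)
  N_l <- nrow(dl)
  K_l <- length(lme4::fixef(l)) + nlevels(droplevels(dl$subject))
  latency_tab <- data.frame(
    effect = rownames(an), F = an[["F value"]], df1 = an$npar, df2 = N_l - K_l,
    p = stats::pf(an[["F value"]], an$npar, N_l - K_l, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  list(
    approach = list(table = approach_tab, n_obs = N_g),
    latency = list(table = latency_tab, n_obs = N_l),
    fits = list(approach = g, latency = l)
  )
}
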