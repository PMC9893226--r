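#' Four-parameter logistic psychometric function
#'
#' `f(x) = gamma + (1 - gamma - lambda) / (1 + exp(-beta * (x - alpha)))`
#' maps stimulus intensity `x` (here log2 vocoder channels) to expected
#' proportion correct. `alpha` is the threshold location (with `gamma = 0`
#' and `lambda = 0`, `f(alpha) = 0.5`), `beta` the slope, `gamma` the guess
#' rate (fixed at 0 for open-set word report) and `lambda` the lapse rate
#' governing the upper asymptote `1 - lambda`.
#'
#' @param x stimulus intensity (log2 channels); vectorised.
#' @param alpha threshold location.
#' @param beta slope (> 0).
#' @param gamma guess rate in \[0, 1).
#' @param lambda lapse rate in \[0, 1).
#' @return probability in `(gamma, 1 - lambda)`.
#' @examples
#' psychometric(3, alpha = 3, beta = 2)  # 0.5 at threshold
#' @export
psychometric <- function(x, alpha, beta, gamma = 0, lambda = 0) {
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (gamma < 0 || gamma >= 1 || lambda < 0 || lambda >= 1 ||
      gamma + lambda >= 1) {
    stop("gamma and lambda must lie in [0, 1) with gamma + lambda < 1",
         call. = FALSE)
  }
  gamma + (1 - gamma - lambda) * stats::plogis(beta * (x - alpha))
}

# Negative binomial log-likelihood of (alpha, beta) given per-level totals.
# Probabilities are clipped so a fixed lambda that places observations
# outside the achievable range cannot produce log(0).
psych_nll <- function(par, x, k, n, lambda) {
  p <- psychometric(x, par[1], par[2], gamma = 0, lambda = lambda)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' Fit the psychometric function for one participant and phase
#'
#' Maximum-likelihood fit of `(alpha, beta)` with the guess rate fixed at 0
#' and the lapse rate fixed at `1 - clear_accuracy` (the participant's
#' observed proportion correct for clear speech), via bounded multi-start
#' optimisation (5 deterministic starts, L-BFGS-B, bounds
#' `alpha` in \[0, 6\] i.e. 1-64 channels, `beta` in \[0.05, 20\]).
#'
#' Sentence rows are pooled into per-level binomial totals before fitting.
#' Degenerate data (all correct or all wrong at every level) do not raise an
#' error: the fit is returned pinned at a parameter bound with
#' `converged = FALSE`.
#'
#' @param conditions data.frame with columns `channels` (4, 8, 16 or 32;
#'   clear speech is encoded as 32), `k_correct` and `n_words`; an `x`
#'   column (log2 channels) is accepted in place of `channels`.
#' @param clear_accuracy observed proportion correct for clear speech; the
#'   lapse rate is fixed at `1 - clear_accuracy`.
#' @param phase label stored on the fit (`"pre"`, `"post"` or `"pooled"`).
#' @return object of class `psychometric_fit`: `alpha`, `beta`, `gamma`,
#'   `lambda`, `log_likelihood`, `converged`, `phase`, `data`.
#' @export
fit_psychometric <- function(conditions, clear_accuracy, phase = "pooled") {
  stopifnot(is.data.frame(conditions))
  if (!"x" %in% names(conditions)) {
    stopifnot("channels" %in% names(conditions))
    conditions$x <- log2(conditions$channels)
  }
  stopifnot(all(c("k_correct", "n_words") %in% names(conditions)))
  if (any(conditions$k_correct < 0 | conditions$k_correct > conditions$n_words)) {
    stop("k_correct must lie in [0, n_words]", call. = FALSE)
  }
  if (!is.finite(clear_accuracy) || clear_accuracy < 0 || clear_accuracy > 1) {
    stop("clear_accuracy must lie in [0, 1]", call. = FALSE)
  }
  agg <- stats::aggregate(cbind(k_correct, n_words) ~ x, conditions, sum)
  agg <- agg[agg$n_words > 0, , drop = FALSE]
  if (length(unique(agg$x)) < 2L) {
    stop("need >= 2 distinct stimulus levels with observations", call. = FALSE)
  }
  # clear accuracy of 0 would give lambda = 1 and an empty achievable range;
  # clamp just inside so degenerate data yield a pinned fit, not an error
  lambda <- min(1 - clear_accuracy, 0.999)
  lower <- c(0, 0.05)
  upper <- c(6, 20)
  starts <- list(c(2, 1), c(3, 2), c(1.5, 4), c(4, 1), c(2.5, 8))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, psych_nll, x = agg$x, k = agg$k_correct,
                   n = agg$n_words, lambda = lambda,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("psychometric optimisation failed", call. = FALSE)
  at_bound <- any(abs(best$par - lower) < 1e-6) ||
    any(abs(best$par - upper) < 1e-6)
  degenerate <- all(agg$k_correct == agg$n_words) || all(agg$k_correct == 0)
  structure(list(
    alpha = best$par[1], beta = best$par[2], gamma = 0, lambda = lambda,
    log_likelihood = -best$value,
    converged = best$convergence == 0 && !at_bound && !degenerate,
    phase = phase, data = agg
  ), class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit %s> alpha = %.3f (%.2f channels), beta = %.3f, lambda = %.3f%s\n",
              x$phase, x$alpha, 2^x$alpha, x$beta, x$lambda,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Threshold number of channels
#'
#' Converts the fitted threshold location from log2 channels back to
#' channels: the channel count at which the fitted function predicts 50%
#' word report (lower = better perception).
#'
#' @param fit a `psychometric_fit`.
#' @return threshold in channels, `2^alpha`.
#' @export
threshold_channels <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  2^fit$alpha
}

#' Training (adaptation) effect
#'
#' Change in threshold location from pre- to post-training, in log2
#' channels: `alpha_pre - alpha_post`. Positive values mean fewer channels
#' were needed after training (improvement).
#'
#' @param fit_pre,fit_post `psychometric_fit` objects with phases `"pre"`
#'   and `"post"`.
#' @return log2-channel change.
#' @export
adaptation_effect <- function(fit_pre, fit_post) {
  stopifnot(inherits(fit_pre, "psychometric_fit"),
            inherits(fit_post, "psychometric_fit"))
  if (!identical(fit_pre$phase, "pre") || !identical(fit_post$phase, "post")) {
    stop("phase mismatch: expected a 'pre' and a 'post' fit", call. = FALSE)
  }
  fit_pre$alpha - fit_post$alpha
}

#' Fit psychometric functions for a whole word-report table
#'
#' Pools sentence rows to per-level binomial totals for each participant and
#' phase, fixes each lapse rate at 1 minus that participant/phase's clear
#' (32-channel) accuracy, and fits every participant x phase cell.
#'
#' @param trials word-report table from [generate_word_report_trials()] (or
#'   user data with the same columns: `participant`, `phase`, `channels`,
#'   `n_words`, `n_correct`).
#' @return data.frame with one row per participant and phase: `alpha`,
#'   `beta`, `lambda`, `threshold_channels`, `converged`.
#' @export
fit_word_report <- function(trials) {
  need <- c("participant", "phase", "channels", "n_words", "n_correct")
  stopifnot(all(need %in% names(trials)))
  cells <- unique(trials[c("participant", "phase")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$participant == cells$participant[i] &
                    trials$phase == cells$phase[i], ]
    clear <- sub[sub$channels == 32, ]
    clear_acc <- if (nrow(clear)) sum(clear$n_correct) / sum(clear$n_words) else 1
    cond <- data.frame(channels = sub$channels, k_correct = sub$n_correct,
                       n_words = sub$n_words)
    fit <- fit_psychometric(cond, clear_acc, phase = cells$phase[i])
    data.frame(participant = cells$participant[i], phase = cells$phase[i],
               alpha = fit$alpha, beta = fit$beta, lambda = fit$lambda,
               threshold_channels = threshold_channels(fit),
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
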