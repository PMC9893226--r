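#' Apply the coherence-task exclusion rules
#'
#' Two analysis-specific filters, applied with minimal trimming:
#'
#' * `"accuracy"`: drops trials with responses more than 300 ms before
#'   sentence offset (anticipatory presses) and all anomalous-sentence
#'   trials (the false-alarm rate is shared between ambiguity conditions, so
#'   accuracy is analysed on coherent trials only).
#' * `"rt"`: restricts to coherent trials and additionally drops incorrect
#'   judgements, anticipatory responses, and responses more than 4,000 ms
#'   after sentence offset.
#'
#' Both filters are idempotent.
#'
#' @param trials coherence trial table (see [generate_coherence_trials()]).
#' @param analysis `"accuracy"` or `"rt"`.
#' @return list with `trials` (the filtered table) and `report`, a list of
#'   counts (`n_input`, `n_fast`, `n_slow`, `n_incorrect_removed`,
#'   `n_anomalous_removed`, `n_output`) plus per-rule row indices.
#' @export
apply_exclusions <- function(trials, analysis = c("accuracy", "rt")) {
  analysis <- match.arg(analysis)
  need <- c("sentence_type", "correct", "rt_from_offset")
  stopifnot(all(need %in% names(trials)))
  if (anyNA(trials$rt_from_offset)) {
    stop("rt_from_offset must be present for all trials", call. = FALSE)
  }
  fast <- trials$rt_from_offset < -300
  anomalous <- trials$sentence_type == "anomalous"
  if (analysis == "accuracy") {
    drop <- fast | anomalous
    report <- list(
      n_input = nrow(trials),
      n_fast = sum(fast & !anomalous),
      n_slow = 0L,
      n_incorrect_removed = 0L,
      n_anomalous_removed = sum(anomalous),
      n_output = sum(!drop),
      fast_rows = which(fast), anomalous_rows = which(anomalous)
    )
  } else {
    slow <- trials$rt_from_offset > 4000
    incorrect <- !trials$correct
    drop <- anomalous | incorrect | fast | slow
    report <- list(
      n_input = nrow(trials),
      n_fast = sum(fast & !anomalous & !incorrect),
      n_slow = sum(slow & !anomalous & !incorrect & !fast),
      n_incorrect_removed = sum(incorrect & !anomalous),
      n_anomalous_removed = sum(anomalous),
      n_output = sum(!drop),
      fast_rows = which(fast), slow_rows = which(slow),
      incorrect_rows = which(incorrect)
    )
  }
  list(trials = trials[!drop, , drop = FALSE], report = report)
}

#' Sensitivity (d-prime) with boundary corrections
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`, where a hit is a
#' coherent sentence judged coherent and a false alarm an anomalous sentence
#' judged coherent. Boundary rates are moved off 0/1 before the inverse
#' normal transform: a rate of 1 becomes `1 - 1/(2N)` and a rate of 0
#' becomes `1/(2N)` (with N the number of trials behind the rate). With 20
#' coherent and 40 anomalous trials, ceiling performance gives adjusted
#' rates 0.975 and 0.0125 and d' = 4.20.
#'
#' @param n_hits coherent sentences judged coherent.
#' @param n_coherent total coherent sentences (> 0).
#' @param n_fa anomalous sentences judged coherent.
#' @param n_anomalous total anomalous sentences (> 0).
#' @return list with `hit_rate_adj`, `fa_rate_adj`, `dprime`.
#' @examples
#' dprime(20, 20, 0, 40)$dprime  # 4.20 at ceiling
#' @export
dprime <- function(n_hits, n_coherent, n_fa, n_anomalous) {
  if (n_coherent <= 0 || n_anomalous <= 0) {
    stop("totals must be > 0", call. = FALSE)
  }
  if (n_hits < 0 || n_fa < 0 || n_hits > n_coherent || n_fa > n_anomalous) {
    stop("counts must be nonnegative and bounded by their totals",
         call. = FALSE)
  }
  adjust <- function(k, n) {
    r <- k / n
    if (r == 1) r <- 1 - 1 / (2 * n)
    if (r == 0) r <- 1 / (2 * n)
    r
  }
  hit <- adjust(n_hits, n_coherent)
  fa <- adjust(n_fa, n_anomalous)
  list(hit_rate_adj = hit, fa_rate_adj = fa,
       dprime = stats::qnorm(hit) - stats::qnorm(fa))
}

#' Per-participant d-prime table
#'
#' Computes d' separately for each ambiguity condition against the shared
#' anomalous-sentence false alarms, after removing anticipatory responses.
#'
#' @param trials coherence trial table.
#' @return data.frame with `participant`, `condition`, `dprime`,
#'   `hit_rate_adj`, `fa_rate_adj`.
#' @export
dprime_by_participant <- function(trials) {
  keep <- trials[trials$rt_from_offset >= -300, , drop = FALSE]
  out <- list()
  for (pid in unique(keep$participant)) {
    sub <- keep[keep$participant == pid, ]
    anom <- sub[sub$sentence_type == "anomalous", ]
    n_fa <- sum(anom$judged_coherent)
    for (cond in c("high_ambiguity", "low_ambiguity")) {
      coh <- sub[sub$sentence_type == cond, ]
      if (!nrow(coh) || !nrow(anom)) next
      d <- dprime(sum(coh$judged_coherent), nrow(coh), n_fa, nrow(anom))
      out[[length(out) + 1L]] <- data.frame(
        participant = pid, condition = cond, dprime = d$dprime,
        hit_rate_adj = d$hit_rate_adj, fa_rate_adj = d$fa_rate_adj,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Shared fitting engine for the two-condition mixed models. The module owns
# the deviation coding (+1/2 vs -1/2), the response definition and the
# response-scale residuals; the random-effects engine is pluggable, with a
# fixed-intercept GLM fallback for simulation loops where per-fit cost
# matters.
fit_two_condition <- function(data, response, condition_col, level_hi,
                              level_lo, item_col, family, engine,
                              extra_fixed = NULL) {
  data$.cond <- ifelse(data[[condition_col]] == level_hi, 0.5,
                       ifelse(data[[condition_col]] == level_lo, -0.5, NA))
  if (anyNA(data$.cond)) stop("unknown condition level present", call. = FALSE)
  if (length(unique(data$.cond)) < 2L) {
    stop("both conditions must be present", call. = FALSE)
  }
  if (length(unique(data$participant)) < 2L) {
    stop("need >= 2 participants", call. = FALSE)
  }
  fixed <- paste(c(".cond", extra_fixed), collapse = " + ")
  if (engine == "lmer") {
    form <- stats::as.formula(paste(
      response, "~", fixed,
      "+ (1 | participant) + (1 |", item_col, ")"))
    model <- if (family == "binomial") {
      lme4::glmer(form, data = data, family = stats::binomial())
    } else {
      lme4::lmer(form, data = data, REML = FALSE)
    }
    fitted_vals <- stats::fitted(model)
    coefs <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
  } else {
    form <- stats::as.formula(paste(response, "~", fixed))
    model <- if (family == "binomial") {
      stats::glm(form, data = data, family = stats::binomial())
    } else {
      stats::lm(form, data = data)
    }
    fitted_vals <- stats::fitted(model)
    coefs <- stats::coef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
  }
  observed <- data[[response]]
  structure(list(
    coefficients = coefs, se = se, model = model,
    fitted = as.numeric(fitted_vals),
    residuals = as.numeric(observed) - as.numeric(fitted_vals),
    data = data, family = family, engine = engine,
    condition_col = condition_col
  ), class = "condition_fit")
}

#' @export
print.condition_fit <- function(x, ...) {
  cat("<condition_fit>", x$family, "via", x$engine, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit the ambiguity condition model
#'
#' Accuracy is modelled with a logistic mixed model and log10 response time
#' with a linear mixed model, each with a single deviation-coded fixed
#' effect for sentence type (high-ambiguity = +1/2, low-ambiguity = -1/2)
#' and random intercepts for participants and sentences. Residuals are
#' returned on the response scale (observed 0/1 minus fitted probability;
#' observed minus fitted log10 RT in seconds).
#'
#' @param trials coherent-sentence trials *after* [apply_exclusions()] for
#'   the matching analysis.
#' @param family `"binomial"` (accuracy) or `"gaussian"` (log10 RT).
#' @param engine `"lmer"` (default; random intercepts via lme4) or `"glm"`
#'   (fixed-intercept fallback).
#' @return object of class `condition_fit` with elements `coefficients`
#'   (including the `.cond` contrast), `se`, `fitted`, `residuals`, `data`.
#' @export
fit_condition_model <- function(trials, family = c("binomial", "gaussian"),
                                engine = c("lmer", "glm")) {
  family <- match.arg(family)
  engine <- match.arg(engine)
  trials <- trials[trials$sentence_type != "anomalous", , drop = FALSE]
  if (family == "binomial") {
    trials$.resp <- as.integer(trials$correct)
    fit_two_condition(trials, ".resp", "sentence_type",
                      "high_ambiguity", "low_ambiguity",
                      "sentence_id", "binomial", engine)
  } else {
    if (any(trials$rt_from_offset <= 0)) {
      stop("nonpositive response times survive exclusions; cannot take log10",
           call. = FALSE)
    }
    trials$.resp <- log10(trials$rt_from_offset / 1000)
    fit_two_condition(trials, ".resp", "sentence_type",
                      "high_ambiguity", "low_ambiguity",
                      "sentence_id", "gaussian", engine)
  }
}

#' Per-participant residual condition effect
#'
#' Mean model residual (response scale) over a participant's `cond_a`
#' trials minus the mean over their `cond_b` trials. A positive value means
#' the participant's condition effect was larger than the group model
#' predicts.
#'
#' @param fit a `condition_fit`.
#' @param participant participant id.
#' @param cond_a,cond_b condition levels (defaults: high- vs low-ambiguity).
#' @return signed effect in response-scale units.
#' @export
residual_effect <- function(fit, participant,
                            cond_a = "high_ambiguity",
                            cond_b = "low_ambiguity") {
  stopifnot(inherits(fit, "condition_fit"))
  d <- fit$data
  ra <- fit$residuals[d$participant == participant &
                        d[[fit$condition_col]] == cond_a]
  rb <- fit$residuals[d$participant == participant &
                        d[[fit$condition_col]] == cond_b]
  if (!length(ra) || !length(rb)) {
    stop("participant '", participant, "' lacks trials in one condition",
         call. = FALSE)
  }
  mean(ra) - mean(rb)
}

#' Residual condition effects for every participant
#'
#' @inheritParams residual_effect
#' @return data.frame with `participant` and `effect`.
#' @export
residual_effects_table <- function(fit, cond_a = "high_ambiguity",
                                   cond_b = "low_ambiguity") {
  ids <- unique(fit$data$participant)
  data.frame(
    participant = ids,
    effect = vapply(ids, function(p) residual_effect(fit, p, cond_a, cond_b),
                    numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
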