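## Absolute-risk prediction and evaluation: Breslow baseline hazard,
## survival-curve prediction, entry-adjusted Kaplan-Meier, Harrell's C,
## and decile calibration tables.

#' Breslow estimate of the cumulative baseline hazard
#'
#' Given fitted coefficients, estimates
#' \deqn{\hat H_0(t) = \sum_{t_k \le t} \frac{d_k}{\sum_{j \in R^*_k}
#'   e^{x_j^\top \beta}}}
#' with entry-adjusted risk sets when `adjust = TRUE`.
#'
#' @inheritParams partial_loglik
#' @return An object of class `breslow_hazard`: list with `time` (unique
#'   event times, increasing), `cumhaz` (nondecreasing), `adjust`.
#' @export
breslow_hazard <- function(data, beta, adjust = TRUE) {
  stopifnot(inherits(data, "ltrc_data"))
  beta <- as.numeric(beta)
  if (length(beta) != ncol(data$x))
    stop("beta must have length ", ncol(data$x))
  if (!all(is.finite(beta))) stop("beta must be finite")
  enc <- risk_encoding(data, adjust)
  eta <- if (length(beta)) drop(data$x %*% beta) else numeric(nobs(data))
  inc <- cox_breslow_increments(eta, data$event, enc$cy, enc$cv, enc$d)
  structure(list(time = enc$times, cumhaz = cumsum(inc), adjust = adjust),
            class = "breslow_hazard")
}

#' @export
print.breslow_hazard <- function(x, ...) {
  cat(sprintf("Breslow cumulative baseline hazard (%s): %d event times, H0 up to %.4g\n",
              if (x$adjust) "entry-adjusted" else "unadjusted",
              length(x$time), max(x$cumhaz)))
  invisible(x)
}

## right-continuous step interpolation of the cumulative hazard
cumhaz_at <- function(baseline, times) {
  idx <- findInterval(times, baseline$time)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' Predicted survival probabilities
#'
#' Under the proportional-hazards model, \eqn{S(t \mid x) = \exp\{-\hat
#' H_0(t) e^{x^\top\beta}\}} with the Breslow baseline held constant between
#' event times (right-continuous step interpolation).
#'
#' @param baseline a `breslow_hazard` object.
#' @param beta coefficient vector used to fit `baseline`.
#' @param newx matrix of predictor rows for the subjects to predict.
#' @param times nonnegative evaluation times.
#' @return An `nrow(newx)` x `length(times)` matrix of probabilities in
#'   \[0, 1\], nonincreasing along each row.
#' @export
predict_survival <- function(baseline, beta, newx, times) {
  stopifnot(inherits(baseline, "breslow_hazard"))
  if (any(times < 0)) stop("evaluation times must be nonnegative")
  newx <- as.matrix(newx)
  risk <- exp(drop(newx %*% as.numeric(beta)))
  H <- cumhaz_at(baseline, times)
  out <- exp(-outer(risk, H))
  dimnames(out) <- list(NULL, paste0("t=", format(times)))
  out
}

#' Kaplan-Meier estimator with optional delayed entry
#'
#' Product-limit estimate of the survival function. When `entry` is
#' supplied, subjects count as at risk at time t only after their entry time
#' (at-risk set \{j : entry_j < t <= time_j\}), the standard risk-set
#' correction for left truncation. Computation is delegated to
#' [survival::survfit()].
#'
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param entry optional entry times (`time > entry` required).
#' @return An object of class `ltrc_km`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `survival` (one row per unique event time).
#' @export
km_ltrc <- function(time, event, entry = NULL) {
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (is.null(entry)) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                            se.fit = FALSE)
  } else {
    if (any(time <= entry)) stop("time must exceed entry")
    sf <- survival::survfit(survival::Surv(entry, time, event) ~ 1,
                            se.fit = FALSE, id = seq_along(time))
  }
  keep <- sf$n.event > 0
  out <- data.frame(time = sf$time[keep], n_risk = sf$n.risk[keep],
                    n_event = sf$n.event[keep], survival = sf$surv[keep])
  class(out) <- c("ltrc_km", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km an `ltrc_km` object.
#' @param times evaluation times.
#' @return Survival probabilities (1 before the first event time; the last
#'   step value beyond the final event time).
#' @export
km_survival_at <- function(km, times) {
  idx <- findInterval(times, km$time)
  c(1, km$survival)[idx + 1L]
}

#' Harrell's concordance index
#'
#' Among subject pairs comparable under right censoring (the shorter
#' observed time ends in an event), the fraction in which the higher risk
#' score belongs to the shorter time; risk-score ties count 1/2.
#' Computation is delegated to [survival::concordance()]. Entry times play
#' no role in pair formation: which subjects are scored is the caller's
#' choice (observed versus complete samples in a simulation), not part of
#' the pair rule.
#'
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param score risk scores (higher = worse prognosis), e.g. the linear
#'   predictor of a Cox model.
#' @return A number in \[0, 1\].
#' @export
concordance_index <- function(time, event, score) {
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  cf <- survival::concordance(survival::Surv(time, event) ~ score,
                              reverse = TRUE)
  counts <- cf$count
  comparable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (comparable == 0) stop("no comparable pairs")
  unname(cf$concordance)
}

#' Decile calibration of predicted survival probabilities
#'
#' At each evaluation time, subjects are ranked by predicted survival
#' probability and cut into `n_bins` equal-count bins (ties broken by stable
#' sort order; bin 1 = lowest predicted survival). Each bin reports the mean
#' predicted probability and the Kaplan-Meier estimate — entry-adjusted iff
#' `entry` is supplied — of the proportion surviving to the evaluation time.
#' Points on the 45-degree line indicate perfect calibration.
#'
#' @param pred n x length(eval_times) matrix of predicted survival
#'   probabilities (such as from [predict_survival()]).
#' @param time,event observed follow-up of the same n subjects.
#' @param eval_times evaluation times (columns of `pred`).
#' @param n_bins number of equal-count bins (>= 2, and n >= n_bins).
#' @param entry optional entry times for truncation-adjusted observed
#'   survival.
#' @return A data frame of class `calibration_table` with columns
#'   `eval_time`, `bin`, `mean_predicted`, `km_observed`, `n_bin`,
#'   `small_bin` (fewer than 10 subjects) and `beyond_followup` (evaluation
#'   time past the bin's last observed time; the KM value at its last step
#'   is reported).
#' @export
calibration_curve <- function(pred, time, event, eval_times, n_bins = 10,
                              entry = NULL) {
  pred <- as.matrix(pred)
  n <- length(time)
  stopifnot(nrow(pred) == n, ncol(pred) == length(eval_times))
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (n < n_bins) stop("need at least n_bins subjects")
  rows <- list()
  for (j in seq_along(eval_times)) {
    ord <- order(pred[, j])  # stable; ascending predicted survival
    bin_sizes <- diff(floor(seq(0, n, length.out = n_bins + 1)))
    bin_of <- rep(seq_len(n_bins), bin_sizes)
    for (b in seq_len(n_bins)) {
      idx <- ord[bin_of == b]
      km <- km_ltrc(time[idx], event[idx],
                    entry = if (!is.null(entry)) entry[idx] else NULL)
      beyond <- eval_times[j] > max(time[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        eval_time = eval_times[j], bin = b,
        mean_predicted = mean(pred[idx, j]),
        km_observed = km_survival_at(km, eval_times[j]),
        n_bin = length(idx), small_bin = length(idx) < 10,
        beyond_followup = beyond)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Plot a calibration table
#'
#' Predicted-versus-observed scatter with a 45-degree reference line, one
#' panel symbol per evaluation time.
#'
#' @param x a `calibration_table`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.calibration_table <- function(x, ...) {
  times <- unique(x$eval_time)
  graphics::plot(x$mean_predicted, x$km_observed, xlim = c(0, 1),
                 ylim = c(0, 1), pch = as.integer(factor(x$eval_time)),
                 xlab = "Predicted survival probability",
                 ylab = "Observed survival probability (KM)", ...)
  graphics::abline(0, 1)
  graphics::legend("topleft", legend = paste("t =", format(times)),
                   pch = seq_along(times), bty = "n")
  invisible(x)
}

#' Write a calibration table or concordance results as delimited text
#' @param x a data frame (e.g. `calibration_table`).
#' @param path output file.
#' @param sep delimiter.
#' @export
write_eval <- function(x, path, sep = ",") {
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
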