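## Brute-force oracles: every quantity below is computed by explicit
## enumeration over materialized risk sets / subject pairs, independently of
## the package's sweep-based implementations.

## explicit risk sets per unique event time
bf_risk_sets <- function(entry, time, event, adjust = TRUE) {
  ts <- sort(unique(time[event == 1]))
  lapply(ts, function(t) {
    if (adjust) which(time >= t & t > entry) else which(time >= t)
  })
}

bf_partial_loglik <- function(entry, time, event, x, beta, adjust = TRUE) {
  eta <- drop(as.matrix(x) %*% beta)
  ts <- sort(unique(time[event == 1]))
  sets <- bf_risk_sets(entry, time, event, adjust)
  ll <- 0
  for (k in seq_along(ts)) {
    ev <- which(time == ts[k] & event == 1)
    ll <- ll + sum(eta[ev]) - length(ev) * log(sum(exp(eta[sets[[k]]])))
  }
  ll
}

bf_breslow <- function(entry, time, event, x, beta, adjust = TRUE) {
  eta <- drop(as.matrix(x) %*% beta)
  ts <- sort(unique(time[event == 1]))
  sets <- bf_risk_sets(entry, time, event, adjust)
  inc <- vapply(seq_along(ts), function(k) {
    d <- sum(time == ts[k] & event == 1)
    d / sum(exp(eta[sets[[k]]]))
  }, 0)
  list(time = ts, cumhaz = cumsum(inc))
}

## product-limit estimate with optional delayed entry
bf_km <- function(time, event, entry = NULL) {
  if (is.null(entry)) entry <- rep(0, length(time))
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(entry < ts[k] & ts[k] <= time)
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ts, survival = surv)
}

## Harrell's C by exhaustive pair enumeration; a pair is comparable when the
## shorter observed time ends in an event (a death tied with a censoring
## time counts the censored subject as the survivor)
bf_concordance <- function(time, event, score) {
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j] && event[i] == 1 && event[j] == 1) next
    shorter <- if (time[i] < time[j]) i else if (time[j] < time[i]) j
               else if (event[i] == 1) i else j
    longer <- setdiff(c(i, j), shorter)
    if (event[shorter] != 1) next
    den <- den + 1
    if (score[shorter] > score[longer]) num <- num + 1
    else if (score[shorter] == score[longer]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

## random tiny LTRC dataset with ties and entry times hitting event times
rand_ltrc <- function(seed, n = NULL, p = 2, tie_grid = TRUE) {
  set.seed(seed)
  if (is.null(n)) n <- sample(3:8, 1)
  repeat {
    time <- if (tie_grid) sample(seq(0.5, 4, by = 0.5), n, replace = TRUE)
            else round(rexp(n, 0.5) + 0.1, 3)
    entry <- ifelse(runif(n) < 0.4, 0,
                    sample(c(0.5, 1, 1.5, runif(1, 0, 2)), n, replace = TRUE))
    keep <- entry < time
    event <- rbinom(n, 1, 0.7)
    if (sum(keep) >= 2 && sum(event[keep]) >= 1) {
      x <- matrix(round(rnorm(n * p), 2), n)
      return(ltrc_data(entry[keep], time[keep], event[keep],
                       x[keep, , drop = FALSE]))
    }
  }
}
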