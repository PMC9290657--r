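## Penalized Cox partial likelihood with entry-adjusted risk sets.
##
## The at-risk structure is encoded once per dataset against the sorted
## unique event times t_1 < ... < t_m:
##   cy[i] = #(t_k <= y_i), cv[i] = #(t_k <= v_i)
## so subject i belongs to the entry-adjusted risk set at t_k iff
## cv[i] < k <= cy[i] (strictly t_k > v_i, and y_i >= t_k). All risk-set
## sums are computed by sweeps over this encoding in O(n + m) per pass.

risk_encoding <- function(data, adjust = TRUE) {
  ev_times <- sort(unique(data$time[data$event == 1L]))
  if (!length(ev_times)) stop("dataset contains no events")
  d <- as.numeric(tabulate(match(data$time[data$event == 1L], ev_times),
                           nbins = length(ev_times)))
  cy <- findInterval(data$time, ev_times)
  cv <- if (adjust) findInterval(data$entry, ev_times) else integer(length(data$time))
  list(times = ev_times, d = d, cy = as.integer(cy), cv = as.integer(cv),
       adjust = adjust)
}

#' Risk sets at the event times of an LTRC dataset
#'
#' Computes, for each unique event time \eqn{t_k}, the risk set — with
#' `adjust = TRUE` the entry-adjusted set \eqn{R^*_k = \{j : y_j \ge t_k >
#' v_j\}}, otherwise the standard right-censoring set \eqn{R_k = \{j : y_j
#' \ge t_k\}}. The sets are returned as a compact interval encoding (each
#' subject is at risk for a contiguous run of event-time indices), computed
#' in O(n log n); `risk_set_members()` materializes a single set on demand.
#'
#' @param data an `ltrc_data` object with at least one event.
#' @param adjust logical; use entry-adjusted risk sets?
#' @return An object of class `ltrc_risk_sets` with elements `times` (unique
#'   event times), `n_events` (tie multiplicities), `size` (risk-set sizes),
#'   and the interval encoding `first_index`/`last_index` per subject.
#' @examples
#' d <- ltrc_data(entry = c(0, 3, 1), time = c(2, 4, 6), event = c(1, 1, 1))
#' rs <- risk_sets(d)
#' risk_set_members(rs, 1)  # subject 2 not yet entered at t = 2
#' @export
risk_sets <- function(data, adjust = TRUE) {
  stopifnot(inherits(data, "ltrc_data"))
  enc <- risk_encoding(data, adjust)
  m <- length(enc$times)
  sz <- integer(m)
  # difference-array count of members per event time
  inc <- tabulate(pmin(enc$cv + 1L, m + 1L), nbins = m + 1L) -
    tabulate(pmin(enc$cy + 1L, m + 1L), nbins = m + 1L)
  sz <- cumsum(inc[seq_len(m)])
  structure(list(times = enc$times, n_events = enc$d, size = as.integer(sz),
                 first_index = enc$cv + 1L, last_index = enc$cy,
                 adjust = adjust),
            class = "ltrc_risk_sets")
}

#' @param sets an `ltrc_risk_sets` object.
#' @param k event-time index (1-based, ordered by time).
#' @rdname risk_sets
#' @export
risk_set_members <- function(sets, k) {
  stopifnot(inherits(sets, "ltrc_risk_sets"),
            k >= 1L, k <= length(sets$times))
  which(sets$first_index <= k & k <= sets$last_index)
}

#' @export
print.ltrc_risk_sets <- function(x, ...) {
  cat(sprintf("%s risk sets at %d event time(s); sizes %d..%d\n",
              if (x$adjust) "Entry-adjusted" else "Standard",
              length(x$times), min(x$size), max(x$size)))
  invisible(x)
}

#' Breslow partial log-likelihood for LTRC data
#'
#' Evaluates the log partial likelihood
#' \deqn{\ell(\beta) = \sum_k \left[ s_k^\top\beta - d_k \log \sum_{j \in
#'   R^*_k} e^{x_j^\top\beta} \right]}
#' where the sum runs over unique event times, \eqn{d_k} is the number of
#' tied events and \eqn{s_k} the sum of their predictor rows (Breslow tie
#' handling), and \eqn{R^*_k} is the entry-adjusted risk set when
#' `adjust = TRUE`.
#'
#' @inheritParams risk_sets
#' @param beta numeric coefficient vector, length `ncol(data$x)`.
#' @return A single finite number.
#' @export
partial_loglik <- function(data, beta, adjust = TRUE) {
  stopifnot(inherits(data, "ltrc_data"))
  beta <- as.numeric(beta)
  if (length(beta) != ncol(data$x))
    stop("beta must have length ", ncol(data$x))
  if (!all(is.finite(beta))) stop("beta must be finite")
  enc <- risk_encoding(data, adjust)
  eta <- if (length(beta)) drop(data$x %*% beta) else numeric(nobs(data))
  cox_irls_quants(eta, data$event, enc$cy, enc$cv, enc$d)$loglik
}

#' Penalized Cox objective
#'
#' The objective maximized by [ltrcnet()]:
#' \eqn{(2/n)\,\ell(\beta) - \lambda P_\alpha(\beta)} with
#' \eqn{P_\alpha(\beta) = \sum_k \alpha|\beta_k| + \frac{1}{2}(1 -
#' \alpha)\beta_k^2}.
#'
#' @inheritParams partial_loglik
#' @param lambda nonnegative penalty strength.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (1 = lasso).
#' @return A single number.
#' @export
penalized_objective <- function(data, beta, lambda, alpha = 1, adjust = TRUE) {
  if (lambda < 0) stop("lambda must be nonnegative")
  stopifnot(alpha >= 0, alpha <= 1)
  ll <- partial_loglik(data, beta, adjust)
  pen <- sum(alpha * abs(beta) + 0.5 * (1 - alpha) * beta^2)
  (2 / nobs(data)) * ll - lambda * pen
}

## center/scale columns; sd uses denominator n (elastic-net convention).
standardize_x <- function(x) {
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, "-")
  scl <- sqrt(colSums(xc^2) / n)
  degen <- scl <= 0
  if (any(degen)) {
    warning(sum(degen), " zero-variance predictor(s) excluded from the ",
            "penalty scaling: ", paste(utils::head(colnames(x)[degen], 5L),
                                       collapse = ", "))
    scl[degen] <- 1
  }
  list(x = sweep(xc, 2L, scl, "/"), center = ctr, scale = scl, degenerate = degen)
}

#' Penalty bound and default lambda sequence
#'
#' `lambda_max()` is the smallest penalty at which every coefficient of the
#' elastic-net Cox fit is zero: \eqn{\max_k |g_k(0)| / \alpha} with
#' \eqn{g(0)} the gradient of \eqn{(2/n)\ell} at \eqn{\beta = 0} on
#' internally standardized predictors. `lambda_path()` returns `nlambda`
#' values log-spaced from \eqn{\lambda_{max}} down to
#' `lambda_min_ratio * lambda_max` (default ratio 0.01 when n > p, 0.05
#' otherwise).
#'
#' For pure ridge (`alpha = 0`) the bound is infinite; the conventional
#' surrogate `alpha = 0.001` anchors the path.
#'
#' @inheritParams penalized_objective
#' @param nlambda number of path points.
#' @param lambda_min_ratio ratio of smallest to largest path value.
#' @return `lambda_max()` a single positive number; `lambda_path()` a
#'   strictly decreasing vector.
#' @export
lambda_max <- function(data, alpha = 1, adjust = TRUE) {
  stopifnot(inherits(data, "ltrc_data"), ncol(data$x) >= 1L)
  std <- standardize_x(data$x)
  enc <- risk_encoding(data, adjust)
  n <- nobs(data)
  u0 <- cox_irls_quants(numeric(n), data$event, enc$cy, enc$cv, enc$d)$u
  g <- abs(drop(crossprod(std$x, u0))) * (2 / n)
  g[std$degenerate] <- 0
  # hair above the exact bound so the returned value itself yields the null
  # model even when the KKT condition is tied to the last floating-point bit
  max(g) / max(alpha, 0.001) * (1 + 1e-9)
}

#' @rdname lambda_max
#' @export
lambda_path <- function(data, alpha = 1, nlambda = 100,
                        lambda_min_ratio = NULL, adjust = TRUE) {
  lmax <- lambda_max(data, alpha, adjust)
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (nobs(data) > ncol(data$x)) 0.01 else 0.05
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Elastic-net Cox regression for left-truncated right-censored data
#'
#' Fits the penalized Cox partial likelihood
#' \deqn{\hat\beta(\lambda) = \arg\max_\beta \frac{2}{n}\ell(\beta) -
#'   \lambda P_\alpha(\beta)}
#' over a decreasing \eqn{\lambda} sequence, where \eqn{\ell} is the Breslow
#' partial log-likelihood with entry-adjusted risk sets
#' \eqn{R^*_k = \{j : y_j \ge t_k > v_j\}} when `adjust = TRUE` (the standard
#' right-censoring risk sets otherwise). Each solution is warm-started from
#' the previous path point and computed by outer iteratively reweighted
#' least squares — a quadratic expansion of \eqn{(2/n)\ell} at the current
#' linear predictor with diagonal-Hessian observation weights — and inner
#' cyclical coordinate descent with soft-thresholding, sequential
#' strong-rule screening and a Karush-Kuhn-Tucker check over screened-out
#' predictors. Predictors are standardized internally; coefficients are
#' reported on the original scale.
#'
#' @inheritParams lambda_max
#' @param lambda optional user sequence (sorted decreasing internally). By
#'   default [lambda_path()] is used, and the path stops early once the
#'   fraction of null deviance explained saturates (relative improvement
#'   below `1e-5`, or 0.999 of the null deviance explained); a user-supplied
#'   sequence is fit in full.
#' @param tol convergence threshold on the maximum curvature-weighted
#'   squared coefficient change \eqn{\max_k \hat v_k (\Delta\beta_k)^2}
#'   (standardized scale), applied to both the inner coordinate-descent
#'   sweeps and the outer IRLS update.
#' @param maxit maximum outer IRLS iterations per lambda value.
#' @return An object of class `ltrcnet`: list with `lambda`, `alpha`,
#'   `beta` (p x nlambda matrix, original scale, predictors in rows), `df`
#'   (nonzero count per lambda), `loglik`, `deviance` (training
#'   partial-likelihood deviance \eqn{2(\ell_{sat} - \ell)}), `converged`,
#'   `iterations`, `adjust`, `center`, `scale`, `nobs`.
#' @seealso [cv_ltrcnet()] to tune `lambda`, [breslow_hazard()] and
#'   [predict_survival()] for absolute-risk prediction.
#' @examples
#' cfg <- sim_config(n = 300, p_binary = 5, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' fit <- ltrcnet(observed_data(cohort), alpha = 1, nlambda = 30)
#' fit
#' @export
ltrcnet <- function(data, alpha = 1, lambda = NULL, nlambda = 100,
                    lambda_min_ratio = NULL, adjust = TRUE,
                    tol = 1e-7, maxit = 100) {
  stopifnot(inherits(data, "ltrc_data"), alpha >= 0, alpha <= 1,
            ncol(data$x) >= 1L)
  auto_lambda <- is.null(lambda)
  if (auto_lambda) {
    lambda <- lambda_path(data, alpha, nlambda, lambda_min_ratio, adjust)
  } else {
    if (any(lambda < 0)) stop("lambda values must be nonnegative")
    lambda <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  }
  std <- standardize_x(data$x)
  enc <- risk_encoding(data, adjust)
  fit <- cox_fit_path(std$x, data$event, enc$cy, enc$cv, enc$d,
                      lambda, alpha, tol, as.integer(maxit), 10000L)
  beta <- fit$beta / std$scale   # back to original predictor scale
  rownames(beta) <- colnames(data$x)
  ll_sat <- -sum(enc$d * log(enc$d))
  if (auto_lambda && length(lambda) > 1L) {
    # stop the path once the deviance explained saturates
    ll0 <- cox_irls_quants(numeric(nobs(data)), data$event, enc$cy, enc$cv,
                           enc$d)$loglik
    dev_null <- 2 * (ll_sat - ll0)
    dev_ratio <- (as.numeric(fit$loglik) - ll0) / (ll_sat - ll0)
    stop_at <- length(lambda)
    for (l in 2:length(lambda)) {
      if (dev_ratio[l] > 0.999 ||
          (dev_ratio[l] - dev_ratio[l - 1]) < 1e-5 * dev_ratio[l]) {
        stop_at <- l
        break
      }
    }
    keep <- seq_len(stop_at)
    lambda <- lambda[keep]
    beta <- beta[, keep, drop = FALSE]
    fit$nnz <- fit$nnz[keep]; fit$loglik <- fit$loglik[keep]
    fit$converged <- fit$converged[keep]; fit$iterations <- fit$iterations[keep]
  }
  structure(list(lambda = lambda, alpha = alpha, beta = beta,
                 df = as.integer(fit$nnz), loglik = as.numeric(fit$loglik),
                 deviance = 2 * (ll_sat - as.numeric(fit$loglik)),
                 converged = as.logical(fit$converged),
                 iterations = as.integer(fit$iterations),
                 adjust = adjust, center = std$center, scale = std$scale,
                 nobs = nobs(data), call = match.call()),
            class = "ltrcnet")
}

#' @export
print.ltrcnet <- function(x, ...) {
  cat(sprintf("Penalized LTRC Cox path (%s, alpha = %g, %s risk sets)\n",
              if (x$alpha == 1) "lasso" else if (x$alpha == 0) "ridge" else "elastic net",
              x$alpha, if (x$adjust) "entry-adjusted" else "unadjusted"))
  cat(sprintf("  %d lambda values in [%.4g, %.4g]; df %d..%d; %d not converged\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              min(x$df), max(x$df), sum(!x$converged)))
  invisible(x)
}

## nearest-lambda column lookup (no interpolation; documented behavior)
lambda_index <- function(object, s) {
  if (is.null(s)) return(seq_along(object$lambda))
  vapply(s, function(si) which.min(abs(object$lambda - si)), 1L)
}

#' @export
coef.ltrcnet <- function(object, s = NULL, ...) {
  object$beta[, lambda_index(object, s), drop = FALSE]
}

#' Linear predictors from a fitted path
#' @param object an `ltrcnet` fit.
#' @param newx matrix of predictor rows.
#' @param s lambda value(s); nearest path point is used. Default: whole path.
#' @param type `"link"` for the linear predictor x'beta.
#' @param ... ignored.
#' @export
predict.ltrcnet <- function(object, newx, s = NULL, type = "link", ...) {
  type <- match.arg(type, "link")
  b <- coef(object, s)
  if (ncol(newx) != nrow(b)) stop("newx must have ", nrow(b), " columns")
  newx %*% b
}

#' K-fold cross-validation for the penalized LTRC Cox model
#'
#' Tunes `lambda` by the Verweij-Van Houwelingen cross-validated
#' partial-likelihood deviance: the lambda path is computed once on the full
#' data; for each fold k the model is refit without fold k and scored by
#' \deqn{D_k(\lambda) = -2\left[\ell_{full}(\hat\beta_{-k}) -
#'   \ell_{-k}(\hat\beta_{-k})\right],}
#' the held-out contribution to the partial log-likelihood (evaluated with
#' the same `adjust` flag as fitting; per-fold partial likelihoods do not
#' decompose, which is why the difference form is used). `lambda.min`
#' minimizes the mean curve; `lambda.1se` is the largest lambda within one
#' standard error of that minimum.
#'
#' @inheritParams ltrcnet
#' @param nfolds number of folds (>= 2); every fold's training portion must
#'   contain at least one event.
#' @param seed integer seed controlling the fold assignment.
#' @param ... further arguments passed to [ltrcnet()].
#' @return An object of class `cv_ltrcnet`: `lambda`, `cvm`, `cvsd`,
#'   `lambda.min`, `lambda.1se`, `foldid`, `nzero`, and the full-data `fit`.
#' @export
cv_ltrcnet <- function(data, alpha = 1, nfolds = 10, adjust = TRUE, seed,
                       lambda = NULL, ...) {
  stopifnot(inherits(data, "ltrc_data"), nfolds >= 2)
  n <- nobs(data)
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  for (k in seq_len(nfolds)) {
    if (sum(data$event[foldid != k]) < 1L)
      stop("fold ", k, " leaves no events for training; use fewer folds")
  }
  fit <- ltrcnet(data, alpha = alpha, lambda = lambda, adjust = adjust, ...)
  lambda <- fit$lambda
  dev <- matrix(NA_real_, nfolds, length(lambda))
  for (k in seq_len(nfolds)) {
    sub <- data[foldid != k]
    fk <- ltrcnet(sub, alpha = alpha, lambda = lambda, adjust = adjust, ...)
    ll_sub <- fk$loglik
    eta_full <- data$x %*% fk$beta
    enc <- risk_encoding(data, adjust)
    ll_full <- vapply(seq_along(lambda), function(l)
      cox_irls_quants(eta_full[, l], data$event, enc$cy, enc$cv, enc$d)$loglik,
      0)
    dev[k, ] <- -2 * (ll_full - ll_sub)
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2L, stats::sd) / sqrt(nfolds)
  imin <- which.min(cvm)
  i1se <- which(cvm <= cvm[imin] + cvsd[imin])[1L]
  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda.min = lambda[imin], lambda.1se = lambda[i1se],
                 index.min = imin, foldid = foldid, nzero = fit$df,
                 fit = fit, adjust = adjust),
            class = "cv_ltrcnet")
}

#' @export
print.cv_ltrcnet <- function(x, ...) {
  cat(sprintf("Cross-validated LTRC Cox path (%d folds, %s risk sets)\n",
              max(x$foldid), if (x$adjust) "entry-adjusted" else "unadjusted"))
  cat(sprintf("  lambda.min = %.5g (df %d), lambda.1se = %.5g\n",
              x$lambda.min, x$nzero[x$index.min], x$lambda.1se))
  invisible(x)
}

#' @export
coef.cv_ltrcnet <- function(object, s = "lambda.min", ...) {
  s <- if (identical(s, "lambda.min")) object$lambda.min
       else if (identical(s, "lambda.1se")) object$lambda.1se
       else s
  coef(object$fit, s = s)
}

#' @export
predict.cv_ltrcnet <- function(object, newx, s = "lambda.min", ...) {
  s <- if (identical(s, "lambda.min")) object$lambda.min
       else if (identical(s, "lambda.1se")) object$lambda.1se
       else s
  predict(object$fit, newx, s = s, ...)
}

## ---- JSON serialization (documented layout for CLI round-tripping) --------

#' Serialize fitted models to JSON
#'
#' Writes a fitted path (or cross-validation result) as a JSON object with
#' keys `type`, `lambda`, `alpha`, `adjust`, `predictors`, `beta` (array of
#' per-lambda coefficient vectors), `df`, `converged`, and for CV fits
#' `cvm`, `cvsd`, `lambda_min`, `lambda_1se`. `model_from_json()` restores
#' an object usable with `coef()` and `predict()`.
#'
#' @param object an `ltrcnet` or `cv_ltrcnet` object.
#' @param path output file.
#' @return `model_to_json()` returns `path` invisibly; `model_from_json()`
#'   the restored object.
#' @export
model_to_json <- function(object, path) {
  if (inherits(object, "cv_ltrcnet")) {
    fit <- object$fit
    extra <- list(cvm = object$cvm, cvsd = object$cvsd,
                  lambda_min = object$lambda.min,
                  lambda_1se = object$lambda.1se)
    type <- "cv_ltrcnet"
  } else if (inherits(object, "ltrcnet")) {
    fit <- object
    extra <- NULL
    type <- "ltrcnet"
  } else stop("object must be an ltrcnet or cv_ltrcnet fit")
  payload <- c(list(type = type, lambda = fit$lambda, alpha = fit$alpha,
                    adjust = fit$adjust,
                    predictors = rownames(fit$beta) %||% character(0),
                    beta = unname(t(fit$beta)), df = fit$df,
                    converged = fit$converged), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- t(matrix(j$beta, nrow = length(j$lambda)))
  rownames(beta) <- j$predictors
  fit <- structure(list(lambda = j$lambda, alpha = j$alpha, beta = beta,
                        df = j$df, converged = j$converged,
                        adjust = j$adjust),
                   class = "ltrcnet")
  if (identical(j$type, "cv_ltrcnet")) {
    structure(list(lambda = j$lambda, cvm = j$cvm, cvsd = j$cvsd,
                   lambda.min = j$lambda_min, lambda.1se = j$lambda_1se,
                   index.min = which.min(j$cvm),
                   foldid = NULL, nzero = j$df, fit = fit, adjust = j$adjust),
              class = "cv_ltrcnet")
  } else fit
}
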