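#' @keywords internal
#' Expand categorical covariates into the participation design
#'
#' One-hot main effects (reference level dropped) plus all two-way
#' interactions, i.e. `model.matrix(~ .^2, data)` without the intercept
#' column.
participation_design <- function(covariates, xlev = NULL) {
  covariates <- as.data.frame(covariates)
  for (col in names(covariates)) {
    if (is.character(covariates[[col]])) {
      covariates[[col]] <- factor(covariates[[col]])
    }
  }
  if (!is.null(xlev)) {
    for (col in names(xlev)) {
      bad <- setdiff(unique(as.character(covariates[[col]])), xlev[[col]])
      if (length(bad) > 0) {
        stop("unseen category in column '", col, "': ",
             paste(bad, collapse = ", "))
      }
      covariates[[col]] <- factor(covariates[[col]], levels = xlev[[col]])
    }
  }
  mm <- stats::model.matrix(~ .^2, data = covariates)
  list(x = mm[, -1, drop = FALSE],
       xlev = lapply(Filter(is.factor, covariates), levels))
}

# Derivative of the per-observation log-likelihood wrt the linear predictor.
link_score <- function(eta, y, link) {
  if (link == "probit") {
    # stable inverse-Mills ratios via log densities
    up <- exp(stats::dnorm(eta, log = TRUE) -
                stats::pnorm(eta, log.p = TRUE))
    dn <- exp(stats::dnorm(eta, log = TRUE) -
                stats::pnorm(-eta, log.p = TRUE))
    y * up - (1 - y) * dn
  } else {
    y - stats::plogis(eta)
  }
}

link_loglik <- function(eta, y, link) {
  if (link == "probit") {
    y * stats::pnorm(eta, log.p = TRUE) +
      (1 - y) * stats::pnorm(-eta, log.p = TRUE)
  } else {
    y * stats::plogis(eta, log.p = TRUE) +
      (1 - y) * stats::plogis(-eta, log.p = TRUE)
  }
}

# FISTA proximal-gradient fit of the L1-penalised probit/logit likelihood.
# The intercept is unpenalised. Objective: -loglik/n + lambda * sum(|beta|).
l1_binary_fit <- function(x, y, lambda, link, init = NULL, maxit = 500,
                          tol = 1e-9, lip = NULL) {
  n <- nrow(x)
  if (is.null(lip)) {
    # largest eigenvalue of [1 X]'[1 X]/n by power iteration
    v <- stats::rnorm(ncol(x) + 1)
    v <- v / sqrt(sum(v^2))
    nv <- 1
    for (i in 1:30) {
      t_vec <- v[1] + as.numeric(x %*% v[-1])
      u <- c(sum(t_vec) / n, as.numeric(crossprod(x, t_vec)) / n)
      nv <- sqrt(sum(u^2))
      if (nv == 0) break
      v <- u / nv
    }
    lip <- max(nv, 1e-8)
  }
  step <- 1 / lip
  a <- if (is.null(init)) stats::qnorm(max(min(mean(y), 1 - 1e-6), 1e-6))
       else init$a
  b <- if (is.null(init)) numeric(ncol(x)) else init$b
  az <- a; bz <- b; t_k <- 1
  obj_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- as.numeric(az + x %*% bz)
    r <- link_score(eta, y, link)
    ga <- -mean(r)
    gb <- -as.numeric(crossprod(x, r)) / n
    a_new <- az - step * ga
    z <- bz - step * gb
    b_new <- sign(z) * pmax(abs(z) - step * lambda, 0)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    az <- a_new + ((t_k - 1) / t_new) * (a_new - a)
    bz <- b_new + ((t_k - 1) / t_new) * (b_new - b)
    a <- a_new; b <- b_new; t_k <- t_new
    if (it %% 10 == 0 || it == maxit) {
      eta <- as.numeric(a + x %*% b)
      obj <- -mean(link_loglik(eta, y, link)) + lambda * sum(abs(b))
      if (is.finite(obj_old) && abs(obj_old - obj) <
          tol * (abs(obj_old) + 1e-12)) break
      obj_old <- obj
    }
  }
  list(a = a, b = b, lip = lip)
}

#' Fit the participation (propensity) model
#'
#' Probit regression of a participation indicator on categorical predictors
#' with L1 (lasso) penalisation, fitted on the pooled
#' reference-population + cohort table. The design expands all categorical
#' main effects plus all pairwise interactions (one-hot, reference level
#' dropped). The penalty is chosen by k-fold cross-validated deviance; the
#' model is then refitted on the full table at the selected penalty.
#'
#' @param covariates Data frame of categorical predictors (>= 2 columns).
#' @param participated Participation indicator (0/1 or logical), both
#'   classes present.
#' @param penalty_grid Decreasing vector of L1 strengths on the
#'   mean-log-likelihood scale. Default: 15 log-spaced values from the
#'   smallest penalty that zeroes every slope down to 1e-4 of it.
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param link `"probit"` (default, matching the participation model the
#'   weights are defined under) or `"logit"`.
#' @param maxit,tol Optimiser controls for the proximal-gradient solver.
#' @return An object of class `participation_model` with the fitted
#'   intercept and coefficients, the selected penalty, the CV deviance
#'   table, and the term names with nonzero coefficients
#'   (`selected_terms`).
#' @export
fit_participation_model <- function(covariates, participated,
                                    penalty_grid = NULL, n_folds = 5,
                                    seed = 1L,
                                    link = c("probit", "logit"),
                                    maxit = 500, tol = 1e-9) {
  link <- match.arg(link)
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2) stop("need at least two covariate columns")
  y <- as.numeric(participated)
  if (!all(y %in% c(0, 1))) stop("`participated` must be a 0/1 indicator")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  if (nrow(covariates) != length(y)) stop("covariates/indicator mismatch")

  des <- participation_design(covariates)
  x <- des$x
  n <- nrow(x)
  if (is.null(penalty_grid)) {
    lmax <- max(abs(as.numeric(crossprod(x, y - mean(y)))) / n)
    penalty_grid <- lmax * 10^seq(0, -3, length.out = 10)
  }
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)

  set.seed(as.integer(((as.double(seed) %% 2147483647) * 48271 + 49937) %%
                        2147483647))
  fold <- sample(rep_len(seq_len(n_folds), n))
  cv_maxit <- min(maxit, 150)   # penalty selection needs less precision
  cv_dev <- matrix(NA_real_, length(penalty_grid), n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    fit <- NULL
    lip <- NULL
    for (li in seq_along(penalty_grid)) {
      fit <- l1_binary_fit(x[tr, , drop = FALSE], y[tr], penalty_grid[li],
                           link, init = fit, maxit = cv_maxit, tol = tol,
                           lip = lip)
      lip <- fit$lip
      eta <- as.numeric(fit$a + x[!tr, , drop = FALSE] %*% fit$b)
      cv_dev[li, k] <- -2 * sum(link_loglik(eta, y[!tr], link))
    }
  }
  dev_mean <- rowSums(cv_dev) / n
  best <- which.min(dev_mean)

  fit <- NULL; lip <- NULL
  for (li in seq_len(best)) {
    fit <- l1_binary_fit(x, y, penalty_grid[li], link, init = fit,
                         maxit = maxit, tol = tol, lip = lip)
    lip <- fit$lip
  }
  if (penalty_grid[best] == 0) {
    eta <- as.numeric(fit$a + x %*% fit$b)
    p <- if (link == "probit") stats::pnorm(eta) else stats::plogis(eta)
    if (all((p > 0.5) == (y == 1)) && max(abs(fit$b)) > 15) {
      stop("perfect separation at zero penalty; supply penalty > 0")
    }
  }
  beta <- stats::setNames(fit$b, colnames(x))
  structure(list(
    intercept = fit$a, coefficients = beta,
    lambda = penalty_grid[best],
    cv = data.frame(lambda = penalty_grid, deviance = dev_mean),
    link = link, xlev = des$xlev, design_spec = colnames(x),
    selected_terms = names(beta)[beta != 0]
  ), class = "participation_model")
}

#' @export
print.participation_model <- function(x, ...) {
  cat(sprintf(
    "<participation_model> link = %s, lambda = %.3g, %d/%d terms selected\n",
    x$link, x$lambda, length(x$selected_terms), length(x$coefficients)))
  invisible(x)
}

#' Predict participation probabilities
#'
#' @param object A fitted [fit_participation_model()] result.
#' @param newdata Data frame with the training covariate columns; an unseen
#'   category raises an error naming the offending column.
#' @param ... Unused.
#' @return Probabilities strictly inside (0, 1).
#' @export
predict.participation_model <- function(object, newdata, ...) {
  miss <- setdiff(names(object$xlev), names(newdata))
  if (length(miss) > 0) {
    stop("newdata lacks covariate column(s): ", paste(miss, collapse = ", "))
  }
  des <- participation_design(newdata[, names(object$xlev), drop = FALSE],
                              xlev = object$xlev)
  eta <- as.numeric(object$intercept +
                      des$x[, names(object$coefficients), drop = FALSE] %*%
                      object$coefficients)
  p <- if (object$link == "probit") stats::pnorm(eta) else stats::plogis(eta)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Construct winsorised inverse-probability weights
#'
#' Raw weights are `1 / p_hat`; values below the `lo_pct` percentile and
#' above the `hi_pct` percentile of the raw weights are set to those
#' percentile values, and the winsorised weights are then rescaled to mean
#' one. Percentiles use linear interpolation between order statistics
#' (`quantile type 7`); every downstream statistic (weighted scans, robust
#' standard errors, effective sample size) is invariant to the positive
#' rescaling, which is applied only for interpretability.
#'
#' @param p_hat Estimated participation probabilities, strictly in (0, 1).
#' @param ids Optional individual identifiers.
#' @param lo_pct,hi_pct Winsorisation percentiles (defaults 1 and 99).
#' @param normalize Rescale winsorised weights to mean one (default `TRUE`).
#' @return An object of class `ip_weight_set` with fields `ids`, `p_hat`,
#'   `w` and `winsor_bounds` (on the same scale as `w`).
#' @export
compute_ip_weights <- function(p_hat, ids = NULL, lo_pct = 1, hi_pct = 99,
                               normalize = TRUE) {
  p_hat <- as.numeric(p_hat)
  if (length(p_hat) == 0) stop("empty probability vector")
  if (any(!is.finite(p_hat)) || any(p_hat <= 0) || any(p_hat >= 1)) {
    stop("all p_hat must lie strictly in (0, 1)")
  }
  if (!(lo_pct >= 0 && lo_pct <= hi_pct && hi_pct <= 100)) {
    stop("require 0 <= lo_pct <= hi_pct <= 100")
  }
  if (is.null(ids)) ids <- as.character(seq_along(p_hat))
  raw <- 1 / p_hat
  bounds <- stats::quantile(raw, c(lo_pct, hi_pct) / 100, type = 7,
                            names = FALSE)
  w <- pmin(pmax(raw, bounds[1]), bounds[2])
  if (normalize) {
    s <- mean(w)
    w <- w / s
    bounds <- bounds / s
  }
  structure(list(ids = as.character(ids), p_hat = p_hat, w = w,
                 winsor_bounds = c(lo = bounds[1], hi = bounds[2]),
                 normalized = normalize),
            class = "ip_weight_set")
}

#' @export
print.ip_weight_set <- function(x, ...) {
  cat(sprintf(
    "<ip_weight_set> n = %d, w in [%.3g, %.3g], mean = %.4f\n",
    length(x$w), min(x$w), max(x$w), mean(x$w)))
  invisible(x)
}

#' Oracle inverse-probability weights
#'
#' Weights participants by the reciprocal of their *true* participation
#' probability from a simulated selection outcome — the benchmark the
#' estimated weights are validated against.
#'
#' @param outcome A `selection_outcome` from [simulate_participation()].
#' @param lo_pct,hi_pct Winsorisation percentiles; defaults 0/100 leave the
#'   oracle weights untouched.
#' @param normalize Rescale to mean one.
#' @return An `ip_weight_set` over the participants only.
#' @export
oracle_ip_weights <- function(outcome, lo_pct = 0, hi_pct = 100,
                              normalize = TRUE) {
  stopifnot(inherits(outcome, "selection_outcome"))
  keep <- outcome$participated
  compute_ip_weights(outcome$p_true[keep], ids = outcome$ids[keep],
                     lo_pct = lo_pct, hi_pct = hi_pct,
                     normalize = normalize)
}

#' Weighted mean, SD and standard error
#'
#' Mean is `sum(w v) / sum(w)`; the SD comes from the weighted second
#' central moment with an `n/(n-1)` small-sample factor so that unit
#' weights reproduce [stats::sd()] exactly; the SE of the mean uses the
#' ratio-estimator linearisation `sqrt(sum(w^2 (v - m)^2)) / sum(w)`.
#'
#' @param values Numeric vector.
#' @param w Positive weights, or an [compute_ip_weights()] result.
#' @return Named numeric vector `c(mean, sd, se)`.
#' @export
weighted_summary <- function(values, w) {
  if (inherits(w, "ip_weight_set")) w <- w$w
  if (length(values) == 0) stop("empty input")
  if (length(values) != length(w)) stop("values/weights length mismatch")
  if (any(w <= 0)) stop("weights must be positive")
  n <- length(values)
  sw <- sum(w)
  m <- sum(w * values) / sw
  v2 <- sum(w * (values - m)^2) / sw
  sd_w <- if (n > 1) sqrt(v2 * n / (n - 1)) else NA_real_
  se_w <- sqrt(sum((w * (values - m))^2)) / sw
  c(mean = m, sd = sd_w, se = se_w)
}
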