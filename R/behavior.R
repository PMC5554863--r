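# Double-exponential movement-time model of motor learning:
#
#   MT(t) = D1 * exp(-t * kappa) + D2 * exp(-t * lambda),   t = trial 1, 2, ...
#
# kappa (the fast decay, kappa >= lambda by convention) is "the learning
# rate": a sharper early drop-off in movement time means faster learning;
# kappa near 0 means no behavioural change. The fit minimizes the sum of
# absolute residuals (LAR), which is robust to the occasional aberrant trial,
# implemented as iteratively reweighted nonlinear least squares around
# minpack.lm::nlsLM with a deterministic multistart grid.

.dexp_model <- function(t, d1, kappa, d2, lambda) {
  d1 * exp(-t * kappa) + d2 * exp(-t * lambda)
}

# Given decay rates, the model is linear in (D1, D2): closed-form start.
.dexp_linear_start <- function(t, mt, kappa, lambda) {
  x1 <- exp(-t * kappa)
  x2 <- exp(-t * lambda)
  fit <- tryCatch(stats::lm.fit(cbind(x1, x2), mt)$coefficients,
                  error = function(e) c(NA, NA))
  d <- pmax(ifelse(is.finite(fit), fit, 0), 0)
  if (sum(d) == 0) d <- c(mean(mt) / 2, mean(mt) / 2)
  unname(d)
}

.dexp_fit_once <- function(t, mt, start, robust, single = FALSE,
                           max_irls = 12, irls_tol = 1e-8) {
  df <- data.frame(t = t, mt = mt)
  weights <- rep(1, length(t))
  coef_prev <- unlist(start)
  if (single) coef_prev <- coef_prev[c("d1", "kappa", "d2")]
  fit <- NULL
  n_iter <- if (robust) max_irls else 1L
  for (iter in seq_len(n_iter)) {
    fit <- tryCatch(
      if (single) {
        minpack.lm::nlsLM(mt ~ d1 * exp(-t * kappa) + d2,
                          data = df, start = as.list(coef_prev),
                          lower = c(0, 0, 0), upper = c(Inf, 5, Inf),
                          weights = weights,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(mt ~ d1 * exp(-t * kappa) + d2 * exp(-t * lambda),
                          data = df, start = as.list(coef_prev),
                          lower = c(0, 0, 0, 0), upper = c(Inf, 5, Inf, 5),
                          weights = weights,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      },
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    lam <- if (single) 0 else cf["lambda"]
    res <- mt - .dexp_model(t, cf["d1"], cf["kappa"], cf["d2"], lam)
    if (!robust) break
    scale <- stats::median(abs(res))
    delta <- max(1e-6 * max(abs(mt)), 1e-12)
    weights <- 1 / pmax(abs(res), if (scale > 0) 1e-4 * scale else delta)
    if (max(abs(cf - coef_prev)) < irls_tol * (1 + max(abs(cf)))) {
      coef_prev <- cf
      break
    }
    coef_prev <- cf
  }
  cf <- stats::coef(fit)
  if (single) cf <- c(cf, lambda = 0)
  if (robust) {
    # IRLS lands near the LAR optimum; a derivative-free polish on the exact
    # L1 objective removes the residual gap left by the smooth reweighting
    np <- if (single) 3L else 4L
    l1_obj <- function(p) {
      if (any(p < 0) || any(p[c(2, 4)[seq_len(np - 2)]] > 5)) return(Inf)
      full <- if (single) c(p, 0) else p
      sum(abs(mt - .dexp_model(t, full[1], full[2], full[3], full[4])))
    }
    op <- stats::optim(unname(cf[seq_len(np)]), l1_obj,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    cur <- sum(abs(mt - .dexp_model(t, cf["d1"], cf["kappa"], cf["d2"],
                                    cf["lambda"])))
    if (is.finite(op$value) && op$value < cur) {
      full <- if (single) c(op$par, 0) else op$par
      cf <- stats::setNames(full, c("d1", "kappa", "d2", "lambda"))
    }
  }
  res <- mt - .dexp_model(t, cf["d1"], cf["kappa"], cf["d2"], cf["lambda"])
  list(coef = cf, l1 = sum(abs(res)), l2 = sum(res^2))
}

#' Fit the double-exponential movement-time model
#'
#' Estimates `(D1, kappa, D2, lambda)` of
#' `MT = D1 exp(-t kappa) + D2 exp(-t lambda)` from a learning curve by
#' least-absolute-residual (robust) or least-squares fitting, multistarting
#' from a deterministic grid of decay rates (`kappa` in 0.01/0.05/0.1/0.3,
#' `lambda` in 0.001/0.01; amplitudes start at their conditional
#' least-squares values, which are closed-form given the rates). The returned
#' solution is normalized so `kappa >= lambda >= 0`.
#'
#' @param mt positive movement times, one per trial.
#' @param trials trial numbers (default `1:length(mt)`).
#' @param robust `TRUE` (default) for the least-absolute-residual fit via
#'   iteratively reweighted least squares; `FALSE` for plain least squares.
#' @param model `"double"` (default) fits both exponential terms; `"single"`
#'   fits the collapsed model `MT = D1 exp(-t kappa) + D2` (constant floor),
#'   useful when the two decay rates are not separately identifiable.
#' @return an object of class `learning_fit`: a list with `d1`, `kappa`,
#'   `d2`, `lambda`, `residual` (sum of absolute residuals), `no_learning`
#'   (`TRUE` when the fitted fast rate is indistinguishable from 0, i.e. no
#'   behavioural change), `fitted`, and the data. Supports [tidy()],
#'   [glance()], and [autoplot()].
#' @export
fit_double_exponential <- function(mt, trials = seq_along(mt),
                                   robust = TRUE,
                                   model = c("double", "single")) {
  model <- match.arg(model)
  stopifnot(length(mt) == length(trials))
  if (length(mt) < 8) stop("need at least 8 trials to fit 4 parameters",
                           call. = FALSE)
  if (any(!is.finite(mt)) || any(mt <= 0)) {
    stop("movement times must be positive and finite", call. = FALSE)
  }
  if (any(diff(trials) <= 0)) stop("trials must be strictly increasing",
                                   call. = FALSE)
  t <- as.numeric(trials)
  if (stats::sd(mt) == 0) {
    # exactly constant movement times: the model degenerates to its floor
    return(structure(list(d1 = 0, kappa = 0, d2 = mt[1], lambda = 0,
                          residual = 0, no_learning = TRUE, robust = robust,
                          model = model, trials = t, mt = mt,
                          fitted = rep(mt[1], length(mt))),
                     class = "learning_fit"))
  }
  # fit on unit-mean data so the procedure is exactly scale-equivariant:
  # amplitudes are rescaled on the way out, decay rates are scale-free
  mt_scale <- mean(mt)
  mt_raw <- mt
  mt <- mt / mt_scale
  kappa_grid <- c(0.01, 0.05, 0.1, 0.3)
  # collapsed model: lambda pinned at 0, second term is a constant floor
  lambda_grid <- if (model == "single") 0 else c(0.001, 0.01)
  best <- NULL
  for (k0 in kappa_grid) {
    for (l0 in lambda_grid) {
      d0 <- .dexp_linear_start(t, mt, k0, l0)
      cand <- .dexp_fit_once(t, mt,
                             list(d1 = d0[1], kappa = k0, d2 = d0[2],
                                  lambda = l0),
                             robust = robust, single = model == "single")
      if (is.null(cand)) next
      crit <- if (robust) cand$l1 else cand$l2
      if (is.null(best) || crit < best$crit - 1e-12) {
        best <- cand
        best$crit <- crit
      }
    }
  }
  if (is.null(best)) {
    stop("double-exponential fit failed to converge from every start",
         call. = FALSE)
  }
  cf <- best$coef
  # identifiability: the model is symmetric under swapping the two terms
  if (cf["kappa"] < cf["lambda"]) {
    cf <- c(d1 = unname(cf["d2"]), kappa = unname(cf["lambda"]),
            d2 = unname(cf["d1"]), lambda = unname(cf["kappa"]))
  }
  # a fast term whose amplitude vanishes, or whose total drop across the
  # observed trials is numerically nil, leaves kappa unidentified: the curve
  # carries no fast decay, so the learning rate is reported as 0
  fast_drop <- cf["d1"] * (exp(-cf["kappa"] * t[1]) -
                             exp(-cf["kappa"] * t[length(t)]))
  if (cf["d1"] < 1e-6 || fast_drop < 1e-6) {
    cf["kappa"] <- 0
    if (cf["d1"] < 1e-6) cf["d1"] <- 0
    if (cf["kappa"] < cf["lambda"]) {
      cf <- c(d1 = unname(cf["d2"]), kappa = unname(cf["lambda"]),
              d2 = unname(cf["d1"]), lambda = 0)
    }
  }
  cf[c("d1", "d2")] <- cf[c("d1", "d2")] * mt_scale
  fitted <- .dexp_model(t, cf["d1"], cf["kappa"], cf["d2"], cf["lambda"])
  structure(list(d1 = unname(cf["d1"]), kappa = unname(cf["kappa"]),
                 d2 = unname(cf["d2"]), lambda = unname(cf["lambda"]),
                 residual = best$l1 * mt_scale,
                 no_learning = unname(cf["kappa"]) < 1e-4,
                 robust = robust, model = model, trials = t, mt = mt_raw,
                 fitted = fitted),
            class = "learning_fit")
}

#' @export
print.learning_fit <- function(x, ...) {
  cat("<learning_fit> MT = D1 exp(-t kappa) + D2 exp(-t lambda)\n",
      "  D1 = ", format(x$d1, digits = 4),
      ", kappa = ", format(x$kappa, digits = 4),
      ", D2 = ", format(x$d2, digits = 4),
      ", lambda = ", format(x$lambda, digits = 4), "\n",
      "  sum |resid| = ", format(x$residual, digits = 4),
      if (x$no_learning) "  [no-learning: kappa ~ 0]" else "", "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.learning_fit <- function(x, ...) {
  tibble::tibble(term = c("d1", "kappa", "d2", "lambda"),
                 estimate = c(x$d1, x$kappa, x$d2, x$lambda))
}

#' @export
glance.learning_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, lambda = x$lambda, residual = x$residual,
                 no_learning = x$no_learning, robust = x$robust,
                 n_trials = length(x$mt))
}

#' Correlate a per-subject network metric with learning rate
#'
#' Pearson correlation between a per-subject dynamic community metric (e.g.
#' Day-1 average cohesion strength) and the per-subject learning rate
#' `kappa`.
#'
#' @param metric,kappa paired numeric vectors, one value per subject
#'   (`n >= 3`).
#' @return a one-row tibble: `estimate` (r), `r.squared`, `statistic`, `df`,
#'   `p.value` (see [pearson_cor()]).
#' @export
correlate_learning <- function(metric, kappa) {
  pearson_cor(metric, kappa)
}
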