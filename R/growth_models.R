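## Nonlinear growth-model library.
##
## Eight candidate models for longitudinal shoot size M(t):
##
##   exponential  M = M0 * exp(r t)
##   power_law    M = (M0^(1-b) + r t (1-b))^(1/(1-b)),  b != 1
##   logistic3    M = Asym / (1 + exp((tmid - t)/k))
##   logistic4    M = A + (B - A) / (1 + exp((tmid - t)/k))
##   gompertz     M = Asym * exp(-b2 * b3^t),  0 < b3 < 1
##   weibull      M = Asym - Drop * exp(-exp(lrc) * t^pwr)
##   richards     M = Asym * (1 + nu * exp((tmid - t)/k))^(-1/nu)
##   beta         M = Mmax * (1 + (te - t)/(te - tm)) * (t/te)^(te/(te - tm))
##                for t in [0, te], M = Mmax beyond te  (Yin's beta growth)
##
## The power-law exponent b tunes how fast relative growth rate declines
## with size (b = 0 is linear growth, b -> 1 recovers the exponential);
## the three-parameter logistic has carrying capacity Asym, inflection time
## tmid and time-scale k. Analytic growth rates: power law AGR = r M^b and
## RGR = r M^(b-1); logistic3 AGR = (M/k)(1 - M/Asym) and
## RGR = (1/k)(1 - M/Asym). Other models use a central difference.
##
## Fitting is Gaussian nonlinear least squares (Levenberg-Marquardt) from
## heuristic self-start values; non-convergence is a recorded state, never
## an exception, because model selection screens candidates on convergence
## robustness across groups before ranking survivors by AIC.

# ---------------------------------------------------------------------------
# model registry

growth_model_registry <- local({
  reg <- list(
    exponential = list(
      pnames = c("M0", "r"),
      lower = c(M0 = 1e-12, r = -Inf),
      eval = function(p, t) p$M0 * exp(p$r * t),
      check = function(p) if (p$M0 <= 0) "M0 must be > 0",
      sigmoidal = FALSE),
    power_law = list(
      pnames = c("M0", "r", "beta"),
      lower = c(M0 = 1e-12, r = -Inf, beta = -Inf),
      eval = function(p, t) {
        b <- p$beta
        base <- p$M0^(1 - b) + p$r * t * (1 - b)
        bad <- base <= 0
        if (any(bad))
          stopf("power-law curve undefined (nonpositive base) at t = %s",
                paste(signif(t[bad], 4), collapse = ", "))
        base^(1 / (1 - b))
      },
      check = function(p) {
        if (p$M0 <= 0) return("M0 must be > 0")
        if (abs(p$beta - 1) < 1e-12) return("beta must differ from 1")
        NULL
      },
      sigmoidal = FALSE),
    logistic3 = list(
      pnames = c("Asym", "tmid", "k"),
      lower = c(Asym = 1e-12, tmid = -Inf, k = 1e-9),
      eval = function(p, t) p$Asym / (1 + exp((p$tmid - t) / p$k)),
      check = function(p) {
        if (p$Asym <= 0) return("Asym must be > 0")
        if (p$k <= 0) return("k must be > 0")
        NULL
      },
      sigmoidal = TRUE),
    logistic4 = list(
      pnames = c("A", "B", "tmid", "k"),
      lower = c(A = -Inf, B = 1e-12, tmid = -Inf, k = 1e-9),
      eval = function(p, t) p$A + (p$B - p$A) / (1 + exp((p$tmid - t) / p$k)),
      check = function(p) {
        if (p$k <= 0) return("k must be > 0")
        if (p$B <= p$A) return("upper asymptote B must exceed A")
        NULL
      },
      sigmoidal = TRUE),
    gompertz = list(
      pnames = c("Asym", "b2", "b3"),
      lower = c(Asym = 1e-12, b2 = 1e-12, b3 = 1e-9),
      upper = c(Asym = Inf, b2 = Inf, b3 = 1 - 1e-9),
      eval = function(p, t) p$Asym * exp(-p$b2 * p$b3^t),
      check = function(p) {
        if (p$Asym <= 0) return("Asym must be > 0")
        if (p$b2 <= 0) return("b2 must be > 0")
        if (p$b3 <= 0 || p$b3 >= 1) return("b3 must lie in (0, 1)")
        NULL
      },
      sigmoidal = TRUE),
    weibull = list(
      pnames = c("Asym", "Drop", "lrc", "pwr"),
      lower = c(Asym = 1e-12, Drop = 1e-12, lrc = -Inf, pwr = 1e-9),
      eval = function(p, t) {
        if (any(t < 0)) stopf("weibull curve defined for t >= 0")
        p$Asym - p$Drop * exp(-exp(p$lrc) * t^p$pwr)
      },
      check = function(p) {
        if (p$Asym <= 0) return("Asym must be > 0")
        if (p$Drop <= 0) return("Drop must be > 0")
        if (p$pwr <= 0) return("pwr must be > 0")
        NULL
      },
      sigmoidal = TRUE),
    richards = list(
      pnames = c("Asym", "tmid", "k", "nu"),
      lower = c(Asym = 1e-12, tmid = -Inf, k = 1e-9, nu = 1e-6),
      eval = function(p, t)
        p$Asym * (1 + p$nu * exp((p$tmid - t) / p$k))^(-1 / p$nu),
      check = function(p) {
        if (p$Asym <= 0) return("Asym must be > 0")
        if (p$k <= 0) return("k must be > 0")
        if (p$nu <= 0) return("nu must be > 0")
        NULL
      },
      sigmoidal = TRUE),
    beta = list(
      pnames = c("Mmax", "te", "tm"),
      lower = c(Mmax = 1e-12, te = 1e-9, tm = 1e-9),
      eval = function(p, t) {
        if (any(t < 0)) stopf("beta growth curve defined for t >= 0")
        tt <- pmin(t, p$te)
        expo <- p$te / (p$te - p$tm)
        p$Mmax * (1 + (p$te - tt) / (p$te - p$tm)) * (tt / p$te)^expo
      },
      check = function(p) {
        if (p$Mmax <= 0) return("Mmax must be > 0")
        if (!(p$tm > 0 && p$tm < p$te)) return("need 0 < tm < te")
        NULL
      },
      sigmoidal = TRUE))
  reg
})

#' Names of the candidate growth models
#'
#' @return character vector of the eight model names.
#' @export
growth_model_names <- function() names(growth_model_registry)

n_growth_params <- function(model_name)
  length(growth_model_registry[[model_name]]$pnames)

check_growth_params <- function(model_name, params) {
  reg <- growth_model_registry[[model_name]]
  if (is.null(reg)) stopf("unknown growth model '%s'", model_name)
  missing <- setdiff(reg$pnames, names(params))
  if (length(missing) > 0L)
    stopf("%s: missing parameter(s) %s", model_name,
          paste(missing, collapse = ", "))
  msg <- reg$check(as.list(params))
  if (!is.null(msg)) stopf("%s: %s", model_name, msg)
  invisible(TRUE)
}

#' Evaluate a growth model
#'
#' @param model_name one of [growth_model_names()].
#' @param params named list or vector of parameters.
#' @param t times (days after sowing).
#' @return model sizes `M(t)`.
#' @export
evaluate_growth <- function(model_name, params, t) {
  model_name <- match.arg(model_name, growth_model_names())
  check_growth_params(model_name, params)
  growth_model_registry[[model_name]]$eval(as.list(params), t)
}

#' Absolute growth rate dM/dt
#'
#' Analytic for the power law (`r * M^beta`) and the three-parameter
#' logistic (`(M/k) * (1 - M/Asym)`); a central difference with step
#' `h = 1e-4 * max(1, |t|)` for the other models.
#'
#' @inheritParams evaluate_growth
#' @return AGR in size units per day.
#' @export
agr <- function(model_name, params, t) {
  model_name <- match.arg(model_name, growth_model_names())
  check_growth_params(model_name, params)
  p <- as.list(params)
  M <- evaluate_growth(model_name, p, t)
  if (any(M <= 0)) stopf("AGR undefined where M <= 0")
  if (model_name == "power_law") return(p$r * M^p$beta)
  if (model_name == "logistic3") return((M / p$k) * (1 - M / p$Asym))
  if (model_name == "exponential") return(p$r * M)
  h <- 1e-4 * pmax(1, abs(t))
  (evaluate_growth(model_name, p, t + h) -
     evaluate_growth(model_name, p, pmax(0, t - h))) / (t + h - pmax(0, t - h))
}

#' Relative growth rate (1/M) dM/dt
#'
#' @inheritParams evaluate_growth
#' @return RGR in 1/day. Equals `agr(...) / M` pointwise; the power law has
#'   the closed form `r * M^(beta - 1)` and the exponential model a constant
#'   RGR of `r`.
#' @export
rgr <- function(model_name, params, t) {
  M <- evaluate_growth(model_name, as.list(params), t)
  if (any(M <= 0)) stopf("RGR undefined where M <= 0")
  agr(model_name, params, t) / M
}

# ---------------------------------------------------------------------------
# self-start heuristics

#' Heuristic initial parameter values for a growth model
#'
#' Self-start rules: the logistic family anchors the asymptote at 1.05x the
#' maximum observation, takes the inflection time from interpolated
#' half-maximum crossing, and the time-scale from a logit-linearisation
#' slope; the power law profiles a grid of shape exponents, for each of
#' which `M^(1-beta)` is linear in time; the exponential uses a log-linear
#' fit; Gompertz and Weibull use their standard double-log linearisations.
#'
#' @param model_name one of [growth_model_names()].
#' @param series data.frame with columns `time` and `value`.
#' @return named list of initial parameter values; a constant series is
#'   accepted and flagged with attribute `degenerate`.
#' @export
self_start_growth <- function(model_name, series) {
  model_name <- match.arg(model_name, growth_model_names())
  tt <- series$time; y <- series$value
  if (anyNA(tt) || anyNA(y)) stopf("series contains missing values")
  p <- n_growth_params(model_name)
  if (length(y) < p + 1L)
    stopf("%s needs at least %d observations", model_name, p + 1L)
  if (any(y <= 0)) stopf("growth series values must be positive")
  o <- order(tt); tt <- tt[o]; y <- y[o]
  degenerate <- diff(range(y)) < 1e-12 * max(abs(y))
  if (!degenerate && cor(tt, y) < 0)
    stopf("series trends downward: growth models assume a nondecreasing trend")
  ymax <- max(y)
  smooth_half_cross <- function() {
    half <- ymax / 2
    above <- which(y >= half)
    i <- above[1]
    if (i == 1L) return(tt[1])
    tt[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (tt[i] - tt[i - 1])
  }
  init <- switch(model_name,
    exponential = {
      f <- lm(log(y) ~ tt)
      list(M0 = exp(unname(coef(f)[1])), r = unname(coef(f)[2]))
    },
    power_law = {
      if (degenerate)
        list(M0 = y[1], r = 1e-6, beta = 0.5)
      else {
        grid <- c(-0.5, 0, 0.25, 0.5, 0.67, 0.8, 0.9, 1.2, 1.5)
        best <- NULL
        for (b in grid) {
          z <- y^(1 - b)
          f <- lm(z ~ tt)
          rss <- sum(residuals(f)^2) / max(var(z), 1e-300)
          if (is.null(best) || rss < best$rss) {
            m0 <- unname(coef(f)[1])^(1 / (1 - b))
            r <- unname(coef(f)[2]) / (1 - b)
            if (is.finite(m0) && m0 > 0)
              best <- list(rss = rss, init = list(M0 = m0, r = r, beta = b))
          }
        }
        if (is.null(best)) list(M0 = y[1], r = (y[length(y)] - y[1]) /
                                  diff(range(tt)), beta = 0.5)
        else best$init
      }
    },
    logistic3 = {
      asym <- 1.05 * ymax
      if (degenerate)
        list(Asym = asym, tmid = mean(tt), k = diff(range(tt)) / 4 + 1e-6)
      else {
        tmid <- smooth_half_cross()
        z <- pmin(pmax(y / asym, 1e-6), 1 - 1e-6)
        f <- lm(log(z / (1 - z)) ~ tt)
        slope <- unname(coef(f)[2])
        k <- if (is.finite(slope) && slope > 0) 1 / slope else
          diff(range(tt)) / 4
        list(Asym = asym, tmid = tmid, k = k)
      }
    },
    logistic4 = {
      l3 <- self_start_growth("logistic3", series)
      list(A = 0.5 * min(y), B = l3$Asym, tmid = l3$tmid, k = l3$k)
    },
    gompertz = {
      asym <- 1.05 * ymax
      z <- log(-log(pmin(pmax(y / asym, 1e-6), 1 - 1e-6)))
      f <- lm(z ~ tt)
      b3 <- exp(unname(coef(f)[2]))
      b3 <- min(max(b3, 1e-6), 1 - 1e-6)
      b2 <- exp(unname(coef(f)[1]))
      list(Asym = asym, b2 = max(b2, 1e-6), b3 = b3)
    },
    weibull = {
      asym <- 1.05 * ymax
      drop0 <- max(asym - min(y), 1e-6)
      pos <- tt > 0
      if (sum(pos) >= 3) {
        z <- log(-log(pmin(pmax((asym - y[pos]) / drop0, 1e-6), 1 - 1e-6)))
        f <- lm(z ~ log(tt[pos]))
        pwr <- max(unname(coef(f)[2]), 0.1)
        lrc <- unname(coef(f)[1])
      } else { pwr <- 1; lrc <- log(1 / max(diff(range(tt)), 1)) }
      list(Asym = asym, Drop = drop0, lrc = lrc, pwr = pwr)
    },
    richards = {
      l3 <- self_start_growth("logistic3", series)
      c(l3, list(nu = 1))
    },
    beta = {
      te <- 1.1 * max(tt)
      dy <- diff(y) / diff(tt)
      tm <- tt[which.max(dy)]
      tm <- min(max(tm, 0.05 * te), 0.9 * te)
      list(Mmax = 1.05 * ymax, te = te, tm = tm)
    })
  if (degenerate) attr(init, "degenerate") <- TRUE
  init
}

# ---------------------------------------------------------------------------
# fitting

numeric_jacobian <- function(model_name, est, tt) {
  p <- length(est)
  J <- matrix(NA_real_, length(tt), p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(1, abs(est[j]))
    up <- est; up[j] <- up[j] + h
    dn <- est; dn[j] <- dn[j] - h
    mu_up <- tryCatch(evaluate_growth(model_name, as.list(up), tt),
                      error = function(e) NULL)
    mu_dn <- tryCatch(evaluate_growth(model_name, as.list(dn), tt),
                      error = function(e) NULL)
    if (is.null(mu_up) || is.null(mu_dn)) return(NULL)
    J[, j] <- (mu_up - mu_dn) / (2 * h)
  }
  J
}

#' Fit a growth model by nonlinear least squares
#'
#' Levenberg-Marquardt minimisation of squared residuals from the
#' [self_start_growth()] values, with box constraints keeping parameters in
#' their model domain. Non-convergence (optimizer failure, singular
#' information matrix, undefined curve) is recorded in the `converged` flag
#' rather than raised, so that model-selection robustness screening can
#' proceed. Fit statistics follow the Gaussian likelihood:
#' `AIC = n log(RSS/n) + 2 (p + 1)` and `R2 = 1 - RSS/TSS`.
#'
#' @param model_name one of [growth_model_names()].
#' @param series data.frame with columns `time` and `value` (multiple plants
#'   may be pooled; rows are treated as independent observations).
#' @param weights optional observation weights.
#' @param start optional named list of starting values overriding the
#'   self-start.
#' @param variance residual variance model: `"constant"` (homoscedastic,
#'   the default) or `"power_of_mean"`, under which the residual standard
#'   deviation is proportional to the fitted mean (the natural model for
#'   multiplicative, CV-stable noise such as leaf-area measurements that
#'   scatter proportionally to plant size). The power option iteratively
#'   reweights observations by the current fitted mean.
#' @return an object of class `growth_fit` with elements `model_name`,
#'   `estimates`, `covariance`, `rss`, `sigma2`, `aic`, `r2`, `converged`,
#'   `n_obs`, `times` (the data time range) and `message`.
#' @export
fit_growth <- function(model_name, series, weights = NULL, start = NULL,
                       variance = c("constant", "power_of_mean")) {
  variance <- match.arg(variance)
  if (variance == "power_of_mean") {
    ## iteratively reweighted least squares: w = 1 / mu^2
    f <- fit_growth(model_name, series, weights = weights, start = start)
    for (it in 1:3) {
      if (!f$converged) return(f)
      mu <- evaluate_growth(model_name, as.list(f$estimates), series$time)
      w <- 1 / pmax(mu, .Machine$double.eps)^2
      if (!is.null(weights)) w <- w * weights
      f <- fit_growth(model_name, series, weights = w,
                      start = as.list(f$estimates))
    }
    return(f)
  }
  fit_growth_ols(model_name, series, weights, start)
}

fit_growth_ols <- function(model_name, series, weights = NULL, start = NULL) {
  model_name <- match.arg(model_name, growth_model_names())
  tt <- series$time; y <- series$value
  n <- length(y)
  w <- if (is.null(weights)) rep(1, n) else weights
  failed <- function(msg) structure(
    list(model_name = model_name, estimates = NULL, covariance = NULL,
         rss = NA_real_, sigma2 = NA_real_, aic = NA_real_, r2 = NA_real_,
         converged = FALSE, n_obs = n, times = range(tt), message = msg),
    class = "growth_fit")
  init <- tryCatch(
    if (is.null(start)) self_start_growth(model_name, series) else start,
    error = function(e) e)
  if (inherits(init, "error")) stop(init)
  reg <- growth_model_registry[[model_name]]
  pn <- reg$pnames
  par0 <- unlist(init[pn])
  lower <- reg$lower[pn]
  upper <- if (!is.null(reg$upper)) reg$upper[pn] else
    rep(Inf, length(pn))
  resid_fn <- function(par) {
    p <- as.list(setNames(par, pn))
    mu <- tryCatch(reg$eval(p, tt), error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu))) return(rep(1e8, n))
    sqrt(w) * (y - mu)
  }
  opt <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = unname(lower),
                       upper = unname(upper), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 400, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || !(opt$info %in% 1:4))
    return(failed(if (is.null(opt)) "optimizer error" else opt$message))
  est <- setNames(opt$par, pn)
  mu <- tryCatch(evaluate_growth(model_name, as.list(est), tt),
                 error = function(e) NULL)
  if (is.null(mu) || any(!is.finite(mu)))
    return(failed("fitted curve undefined on the data grid"))
  rss <- sum(w * (y - mu)^2)
  if (!is.finite(rss) || rss >= 1e15 * n)
    return(failed("residuals did not decrease to a valid optimum"))
  p <- length(pn)
  sigma2 <- rss / max(n - p, 1L)
  J <- numeric_jacobian(model_name, est, tt)
  cov <- NULL
  if (!is.null(J) && all(is.finite(J))) {
    JtJ <- crossprod(sqrt(w) * J)
    cov <- tryCatch(sigma2 * solve(JtJ), error = function(e) NULL)
  }
  if (is.null(cov))
    return(failed("singular information matrix"))
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(pn, pn)
  tss <- sum(w * (y - sum(w * y) / sum(w))^2)
  structure(list(
    model_name = model_name, estimates = est, covariance = cov,
    rss = rss, sigma2 = sigma2,
    ## floor keeps the criterion finite for numerically perfect fits
    aic = n * log(max(rss, 1e-300) / n) + 2 * (p + 1),
    r2 = 1 - rss / tss, converged = TRUE, n_obs = n,
    times = range(tt), message = "converged"),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit %s> %s\n", x$model_name,
              if (x$converged) "converged" else
                paste0("NOT converged (", x$message, ")")))
  if (x$converged) {
    est <- data.frame(estimate = x$estimates,
                      se = sqrt(diag(x$covariance)))
    print(signif(est, 5))
    cat(sprintf("  n = %d, RSS = %.4g, AIC = %.2f, R2 = %.4f\n",
                x$n_obs, x$rss, x$aic, x$r2))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# prediction bands and model selection

## Clip negative eigenvalues to restore positive semidefiniteness.
nearest_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= -1e-12)) return(S)
  warnf("covariance not positive semidefinite; nearest-PSD repair applied")
  v <- pmax(e$values, 0)
  S2 <- e$vectors %*% diag(v, length(v)) %*% t(e$vectors)
  (S2 + t(S2)) / 2
}

#' Population prediction interval for a fitted growth curve
#'
#' Draws parameter vectors from a multivariate normal centred on the
#' estimates with the fit covariance, evaluates the growth curve for each
#' draw, and takes pointwise quantiles. This propagates parameter
#' uncertainty into a curve band without requiring a closed-form delta
#' method.
#'
#' @param fit a converged [fit_growth()] result.
#' @param times evaluation times.
#' @param n_draws number of parameter draws.
#' @param level band coverage level (default 0.95).
#' @param seed integer seed making the band deterministic.
#' @return data.frame with columns `time`, `fit`, `lower`, `upper`.
#' @export
prediction_band <- function(fit, times, n_draws = 1000, level = 0.95,
                            seed = 20110301) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!fit$converged) stopf("prediction band requires a converged fit")
  S <- nearest_psd(fit$covariance)
  draws <- with_seed(seed,
    MASS::mvrnorm(n_draws, mu = fit$estimates, Sigma = S))
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_draws)
  curves <- matrix(NA_real_, n_draws, length(times))
  for (i in seq_len(n_draws)) {
    p <- as.list(setNames(draws[i, ], names(fit$estimates)))
    curves[i, ] <- tryCatch({
      ok <- is.null(growth_model_registry[[fit$model_name]]$check(p))
      if (!ok) NA_real_ else evaluate_growth(fit$model_name, p, times)
    }, error = function(e) NA_real_)
  }
  a <- (1 - level) / 2
  data.frame(
    time = times,
    fit = evaluate_growth(fit$model_name, as.list(fit$estimates), times),
    lower = apply(curves, 2, quantile, probs = a, na.rm = TRUE),
    upper = apply(curves, 2, quantile, probs = 1 - a, na.rm = TRUE))
}

#' Rank candidate growth models across groups
#'
#' Implements the robustness-then-parsimony selection rule: a candidate that
#' fails to converge on any group is disqualified outright; survivors are
#' ranked by mean AIC across groups; candidates within 2 AIC units of the
#' best are treated as statistically tied and reordered by parameter count
#' (parsimony) and then by narrower mean prediction-band width.
#'
#' @param series_by_group named list of data.frames (`time`, `value`), one
#'   per experimental group (e.g. variety x treatment).
#' @param candidates character vector of model names.
#' @param band_times,band_draws,seed controls for the tie-breaking band
#'   width computation.
#' @return an object of class `model_selection`: list with `report` (one row
#'   per candidate: convergence count, mean AIC, mean R2, mean band width,
#'   rank) and `selected` (the winning model name).
#' @export
select_growth_model <- function(series_by_group, candidates =
                                  growth_model_names(),
                                band_times = NULL, band_draws = 300,
                                seed = 20110301) {
  stopifnot(length(series_by_group) >= 1L)
  candidates <- match.arg(candidates, growth_model_names(),
                          several.ok = TRUE)
  if (is.null(names(series_by_group)))
    names(series_by_group) <- sprintf("group_%d", seq_along(series_by_group))
  fits <- lapply(candidates, function(m)
    lapply(series_by_group, function(s)
      tryCatch(fit_growth(m, s), error = function(e) {
        f <- list(model_name = m, converged = FALSE, aic = NA_real_,
                  r2 = NA_real_, message = conditionMessage(e))
        class(f) <- "growth_fit"
        f
      })))
  names(fits) <- candidates
  if (is.null(band_times)) {
    rng <- range(unlist(lapply(series_by_group, function(s) s$time)))
    band_times <- seq(rng[1], rng[2], length.out = 25)
  }
  report <- do.call(rbind, lapply(candidates, function(m) {
    conv <- vapply(fits[[m]], function(f) isTRUE(f$converged), logical(1))
    aics <- vapply(fits[[m]], function(f) f$aic, numeric(1))
    r2s <- vapply(fits[[m]], function(f) f$r2, numeric(1))
    bw <- if (all(conv)) {
      mean(vapply(fits[[m]], function(f) {
        b <- tryCatch(prediction_band(f, band_times, n_draws = band_draws,
                                      seed = seed),
                      error = function(e) NULL)
        if (is.null(b)) Inf else mean(b$upper - b$lower)
      }, numeric(1)))
    } else NA_real_
    data.frame(model = m, n_params = n_growth_params(m),
               n_groups = length(series_by_group), n_converged = sum(conv),
               robust = all(conv), mean_aic = mean(aics),
               mean_r2 = mean(r2s), mean_band_width = bw)
  }))
  surv <- report[report$robust, , drop = FALSE]
  if (nrow(surv) == 0L) {
    diag_txt <- paste(vapply(candidates, function(m) {
      bad <- names(which(!vapply(fits[[m]], function(f)
        isTRUE(f$converged), logical(1))))
      sprintf("%s failed on: %s", m, paste(bad, collapse = ", "))
    }, character(1)), collapse = "; ")
    stopf("no candidate converged on every group (%s)", diag_txt)
  }
  surv <- surv[order(surv$mean_aic), , drop = FALSE]
  tied <- surv$mean_aic - surv$mean_aic[1] < 2
  if (sum(tied) > 1L) {
    tie_blk <- surv[tied, , drop = FALSE]
    tie_blk <- tie_blk[order(tie_blk$n_params, tie_blk$mean_band_width,
                             tie_blk$mean_aic), , drop = FALSE]
    surv <- rbind(tie_blk, surv[!tied, , drop = FALSE])
  }
  report$rank <- NA_integer_
  report$rank[match(surv$model, report$model)] <- seq_len(nrow(surv))
  report <- report[order(report$rank, report$mean_aic, na.last = TRUE), ]
  rownames(report) <- NULL
  structure(list(report = report, selected = surv$model[1], fits = fits),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> selected:", x$selected, "\n")
  print(x$report[, c("model", "n_params", "n_converged", "mean_aic",
                     "mean_r2", "rank")], digits = 4)
  invisible(x)
}

#' Inflection time of a sigmoidal growth curve
#'
#' The time at which the absolute growth rate peaks (the transition toward
#' the plateau phase, a developmental trait). Exact (`tmid`) for the
#' three-parameter logistic; golden-section maximisation of the AGR for the
#' other sigmoidal models; an error for non-asymptotic models, whose AGR
#' has no interior maximum.
#'
#' @param fit a converged [fit_growth()] result, or a list with
#'   `model_name`, `estimates` and `times` (search range).
#' @return inflection time in days.
#' @export
inflection_time <- function(fit) {
  m <- fit$model_name
  if (!growth_model_registry[[m]]$sigmoidal)
    stopf("'%s' is non-asymptotic: AGR has no interior maximum", m)
  est <- as.list(fit$estimates)
  if (m == "logistic3") return(unname(fit$estimates["tmid"]))
  rng <- if (!is.null(fit$times)) fit$times else c(0, 100)
  span <- diff(rng)
  lo <- max(1e-6, rng[1] - 0.5 * span)
  hi <- rng[2] + 2 * span
  optimize(function(t) agr(m, est, t), c(lo, hi), maximum = TRUE,
           tol = 1e-6)$maximum
}
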