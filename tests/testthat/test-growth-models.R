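test_that("model evaluation matches closed forms and limits", {
  # power law with beta = 0 is linear growth
  expect_equal(evaluate_growth("power_law", list(M0 = 1, r = 2, beta = 0), 3),
               7)
  # three-parameter logistic at its midpoint
  expect_equal(evaluate_growth("logistic3",
                               list(Asym = 3000, tmid = 35, k = 5), 35), 1500)
  # beta -> 1 limit of the power law approaches the exponential
  tt <- seq(0, 5, 0.5)
  pl <- evaluate_growth("power_law", list(M0 = 1, r = 0.2, beta = 0.999), tt)
  ex <- evaluate_growth("exponential", list(M0 = 1, r = 0.2), tt)
  expect_lt(max(abs(pl / ex - 1)), 1e-3)
  # domain violations identify the offending time
  expect_error(evaluate_growth("power_law",
                               list(M0 = 1, r = -2, beta = 0.5), 10),
               "undefined.*t = 10")
  expect_error(evaluate_growth("nonsense", list(), 1))
})

test_that("growth-rate identities hold", {
  p3 <- list(Asym = 3000, tmid = 35, k = 5)
  # AGR peaks at the inflection with value Asym / (4k)
  expect_equal(agr("logistic3", p3, 35), 3000 / (4 * 5))
  tt <- seq(20, 50, 1)
  expect_lte(max(agr("logistic3", p3, tt)), 3000 / (4 * 5) + 1e-12)
  # RGR decays to zero at the asymptote
  expect_lt(rgr("logistic3", p3, 200), 1e-8)
  # analytic power-law AGR equals a numerical derivative
  pp <- list(M0 = 10, r = 0.5, beta = 0.6)
  for (t0 in c(1, 5, 20)) {
    h <- 1e-6 * t0
    num <- (evaluate_growth("power_law", pp, t0 + h) -
              evaluate_growth("power_law", pp, t0 - h)) / (2 * h)
    expect_equal(agr("power_law", pp, t0), num, tolerance = 1e-6)
  }
  # exponential RGR is the constant rate
  expect_equal(rgr("exponential", list(M0 = 3, r = 0.13), c(0, 10, 30)),
               rep(0.13, 3))
})

test_that("RGR equals AGR/M for every model", {
  tt <- seq(2, 40, 2)
  cases <- list(
    exponential = list(M0 = 5, r = 0.1),
    power_law = list(M0 = 5, r = 0.4, beta = 0.7),
    logistic3 = list(Asym = 2000, tmid = 20, k = 4),
    logistic4 = list(A = 50, B = 2000, tmid = 20, k = 4),
    gompertz = list(Asym = 2000, b2 = 5, b3 = 0.85),
    weibull = list(Asym = 2000, Drop = 1900, lrc = -6, pwr = 2),
    richards = list(Asym = 2000, tmid = 20, k = 4, nu = 0.7),
    beta = list(Mmax = 2000, te = 45, tm = 22))
  for (m in names(cases)) {
    M <- evaluate_growth(m, cases[[m]], tt)
    expect_equal(rgr(m, cases[[m]], tt), agr(m, cases[[m]], tt) / M,
                 tolerance = 1e-12, label = m)
  }
  # power-law RGR is monotone in M with the sign of (beta - 1)
  Ms <- evaluate_growth("power_law", list(M0 = 5, r = 0.4, beta = 0.7), tt)
  rs <- rgr("power_law", list(M0 = 5, r = 0.4, beta = 0.7), tt)
  expect_true(all(diff(rs)[diff(Ms) > 0] < 0))
})

test_that("self-start values land near the truth on clean data", {
  tt <- seq(14, 56, 3)
  truth <- list(Asym = 3000, tmid = 35, k = 5)
  ser <- make_series("logistic3", truth, tt)
  init <- self_start_growth("logistic3", ser)
  for (p in names(truth))
    expect_lt(abs(init[[p]] - truth[[p]]) / abs(truth[[p]]), 0.2)
  # decreasing series rejected
  expect_error(self_start_growth("logistic3",
                                 data.frame(time = 1:10, value = 10:1)),
               "nondecreasing")
  # constant series: degenerate flag, Asym anchored at 1.05x
  const <- data.frame(time = 1:10, value = rep(7, 10))
  ic <- self_start_growth("logistic3", const)
  expect_equal(ic$Asym, 1.05 * 7)
  expect_true(isTRUE(attr(ic, "degenerate")))
  expect_error(self_start_growth("logistic3",
                                 data.frame(time = 1:3, value = 1:3)),
               "at least")
})

test_that("noise-free fits recover parameters to numerical precision", {
  tt <- seq(14, 56, 2)
  truth <- list(Asym = 3000, tmid = 35, k = 5)
  f <- fit_growth("logistic3", make_series("logistic3", truth, tt))
  expect_true(f$converged)
  for (p in names(truth))
    expect_equal(unname(f$estimates[p]), truth[[p]], tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_true(is.finite(f$aic))
  # covariance is symmetric PSD
  ev <- eigen(f$covariance, symmetric = TRUE)$values
  expect_true(all(ev > -1e-12))
})

test_that("non-convergence is recorded, never raised", {
  # 5-point near-linear data cannot identify a 4-parameter Richards curve
  ser <- data.frame(time = 1:5, value = c(10, 20.1, 29.8, 40.3, 50.1))
  f <- fit_growth("richards", ser)
  expect_s3_class(f, "growth_fit")
  if (!f$converged) expect_true(is.na(f$aic)) # aic finite iff converged
  # a model undefined on the data always records failure gracefully
  f2 <- fit_growth("power_law",
                   make_series("logistic3", list(Asym = 100, tmid = 5, k = 1),
                               seq(1, 20, 1)))
  expect_true(is.logical(f2$converged))
})

test_that("logistic3 fits are invariant to a time-origin shift", {
  tt <- seq(14, 56, 2)
  truth <- list(Asym = 3000, tmid = 35, k = 5)
  ser <- make_series("logistic3", truth, tt, noise_cv = 0.05, n_plants = 4,
                     seed = 5)
  f0 <- fit_growth("logistic3", ser)
  sh <- transform(ser, time = time + 100)
  f1 <- fit_growth("logistic3", sh)
  expect_equal(unname(f1$estimates["tmid"] - f0$estimates["tmid"]), 100,
               tolerance = 1e-4)
  expect_equal(unname(f1$estimates["Asym"]), unname(f0$estimates["Asym"]),
               tolerance = 1e-5)
  expect_equal(unname(f1$estimates["k"]), unname(f0$estimates["k"]),
               tolerance = 1e-5)
})

test_that("prediction bands collapse with zero covariance and stay nested", {
  tt <- seq(14, 56, 2)
  f <- fit_growth("logistic3",
                  make_series("logistic3", list(Asym = 3000, tmid = 35, k = 5),
                              tt))
  f0 <- f
  f0$covariance <- matrix(0, 3, 3, dimnames = dimnames(f$covariance))
  b0 <- prediction_band(f0, tt, n_draws = 50, seed = 1)
  expect_equal(b0$lower, b0$fit, tolerance = 1e-12)
  expect_equal(b0$upper, b0$fit, tolerance = 1e-12)
  # Monte-Carlo stability: a large-draw band contains most of a small one
  fn <- fit_growth("logistic3",
                   make_series("logistic3", list(Asym = 3000, tmid = 35, k = 5),
                               tt, noise_cv = 0.05, n_plants = 6, seed = 2))
  b_small <- prediction_band(fn, tt, n_draws = 10, seed = 3)
  b_big <- prediction_band(fn, tt, n_draws = 10000, seed = 4)
  frac <- mean(b_big$lower <= b_small$lower & b_small$upper <= b_big$upper)
  expect_gte(frac, 0.9)
  # determinism under seed
  expect_identical(prediction_band(fn, tt, n_draws = 100, seed = 9),
                   prediction_band(fn, tt, n_draws = 100, seed = 9))
})

test_that("model selection disqualifies non-robust candidates", {
  tt <- seq(14, 42, 1)
  g1 <- make_series("logistic3", list(Asym = 3000, tmid = 35, k = 5), tt,
                    noise_cv = 0.05, n_plants = 8, seed = 11)
  sel <- select_growth_model(list(g1 = g1),
                             candidates = c("exponential", "power_law",
                                            "logistic3", "gompertz"),
                             band_draws = 100)
  expect_s3_class(sel, "model_selection")
  expect_true(sel$selected %in% c("logistic3", "gompertz"))
  # disqualified candidates carry no rank
  expect_true(all(is.na(sel$report$rank[!sel$report$robust])))
  # ranking covers exactly the robust survivors
  expect_equal(sort(sel$report$rank[sel$report$robust]),
               seq_len(sum(sel$report$robust)))
})

test_that("inflection time is exact for logistic3 and matched by grid search", {
  f3 <- list(model_name = "logistic3",
             estimates = c(Asym = 3000, tmid = 35.9, k = 5), times = c(14, 56))
  expect_equal(inflection_time(f3), 35.9)
  fg <- list(model_name = "gompertz",
             estimates = c(Asym = 2000, b2 = 8, b3 = 0.88), times = c(5, 60))
  tgrid <- seq(5, 60, 0.001)
  a <- agr("gompertz", as.list(fg$estimates), tgrid)
  expect_lt(abs(inflection_time(fg) - tgrid[which.max(a)]), 0.01)
  fe <- list(model_name = "exponential", estimates = c(M0 = 1, r = 0.1),
             times = c(0, 10))
  expect_error(inflection_time(fe), "non-asymptotic")
})
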