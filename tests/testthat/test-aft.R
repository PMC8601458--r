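test_that("interval contributions match closed forms and quadrature", {
  one <- tibble::tibble(left = 10, right = 11, censor_type = "interval")
  ll <- interval_gaussian_loglik(10.5, 1, one, matrix(1, 1, 1))
  expect_equal(ll, log(pnorm(0.5) - pnorm(-0.5)), tolerance = 1e-12)

  # quadrature oracle (peak-rescaled integrand) on random cases
  quad_log <- function(L, R, mu, s) {
    m <- dnorm(min(max(mu, L), R), mu, s, log = TRUE)
    m + log(integrate(function(x) exp(dnorm(x, mu, s, log = TRUE) - m),
                      L, R, rel.tol = 1e-12)$value)
  }
  set.seed(41)
  for (i in 1:10) {
    L <- runif(1, 6, 14); R <- L + runif(1, 0.05, 3)
    mu <- runif(1, 4, 16); s <- runif(1, 0.2, 2)
    ours <- interval_gaussian_loglik(
      mu, s, tibble::tibble(left = L, right = R, censor_type = "interval"),
      matrix(1, 1, 1)
    )
    expect_equal(ours, quad_log(L, R, mu, s), tolerance = 1e-8)
  }

  # degenerate-width limit approaches density + log(width)
  for (w in 10^(-c(4, 6, 8))) {
    ll_w <- interval_gaussian_loglik(
      10.5, 1, tibble::tibble(left = 10.2, right = 10.2 + w,
                              censor_type = "interval"), matrix(1, 1, 1)
    )
    expect_equal(ll_w, dnorm(10.2, 10.5, 1, log = TRUE) + log(w),
                 tolerance = 1e-4)
  }

  expect_error(interval_gaussian_loglik(
    10, 1, tibble::tibble(left = 11, right = 10, censor_type = "interval"),
    matrix(1, 1, 1)
  ), "left > right")
})

test_that("degenerate intervals reduce the fit to ordinary least squares", {
  d <- make_onset_data(150, seed = 43)
  ex <- dplyr::mutate(d, left = onset, right = onset,
                      censor_type = "interval")
  fit <- fit_aft(ex, c("aphv", "phv", "overweight"))
  ols <- lm(onset ~ aphv + phv + overweight, data = ex)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-6)
  # ML sigma uses denominator n
  expect_equal(fit$sigma, sqrt(mean(resid(ols)^2)), tolerance = 1e-6)
})

test_that("the fit agrees with survreg under mixed censoring", {
  skip_if_not_installed("survival")
  d <- make_onset_data(250, seed = 47, right_cens_age = 13.5)
  fit <- fit_aft(d, c("aphv", "phv", "overweight"))
  t1 <- ifelse(d$censor_type == "left", NA, d$left)
  t2 <- ifelse(d$censor_type == "right", NA, d$right)
  sv <- survival::survreg(
    survival::Surv(t1, t2, type = "interval2") ~ aphv + phv + overweight,
    data = d, dist = "gaussian"
  )
  expect_equal(unname(fit$coefficients), unname(coef(sv)), tolerance = 1e-4)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-4)
  expect_equal(fit$logLik, sv$loglik[2], tolerance = 1e-6)
})

test_that("a 20-child fixture matches an independently coded ML oracle", {
  d <- make_onset_data(20, seed = 53)
  fit <- fit_aft(d, "aphv")
  # independent oracle: plain (unstabilized) likelihood + Nelder-Mead
  oracle_nll <- function(par) {
    mu <- par[1] + par[2] * d$aphv; s <- exp(par[3])
    li <- numeric(nrow(d))
    for (i in seq_len(nrow(d))) {
      li[i] <- switch(d$censor_type[i],
        interval = log(pnorm((d$right[i] - mu[i]) / s) -
                         pnorm((d$left[i] - mu[i]) / s)),
        right = log(1 - pnorm((d$left[i] - mu[i]) / s)),
        left = log(pnorm((d$right[i] - mu[i]) / s))
      )
    }
    -sum(li)
  }
  o <- optim(c(mean(d$left[is.finite(d$left)]), 0, 0), oracle_nll,
             method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(unname(fit$coefficients), o$par[1:2], tolerance = 1e-3)
  expect_equal(fit$sigma, exp(o$par[3]), tolerance = 1e-3)
})

test_that("onset summaries behave like mean and SD with location equivariance", {
  d <- make_onset_data(120, seed = 59)
  d$cohort <- "X"
  ex <- dplyr::mutate(d, left = onset, right = onset, censor_type = "interval")
  s <- summarize_onset(ex, "cohort")
  expect_equal(s$mean_onset, mean(ex$onset), tolerance = 1e-6)
  expect_equal(s$sd_onset, sqrt(mean((ex$onset - mean(ex$onset))^2)),
               tolerance = 1e-6)

  shifted <- dplyr::mutate(d, left = left + 1, right = right + 1)
  s0 <- summarize_onset(d, "cohort")
  s1 <- summarize_onset(shifted, "cohort")
  expect_equal(s1$mean_onset, s0$mean_onset + 1, tolerance = 1e-5)
  expect_equal(s1$sd_onset, s0$sd_onset, tolerance = 1e-5)

  rc <- dplyr::mutate(d, censor_type = "right", right = Inf)
  expect_error(summarize_onset(rc, "cohort"), "right-censored")
  expect_error(summarize_onset(d[1:5, ], "cohort"), "fewer than")
})

test_that("prediction intervals use normal quantiles and nest properly", {
  d <- make_onset_data(100, seed = 61)
  fit <- fit_aft(d, c("aphv", "phv"))
  nd <- tibble::tibble(aphv = 11.7, phv = 7.8)
  pr <- predict_onset(fit, nd)
  expect_equal(pr$hi95 - pr$.pred, qnorm(0.975) * fit$sigma, tolerance = 1e-9)
  # explicit half-width value at sigma = 1
  fit1 <- fit
  fit1$sigma <- 1
  pr1 <- predict_onset(fit1, nd)
  expect_equal(unname(pr1$hi95 - pr1$.pred), 1.959964, tolerance = 1e-6)
  # nesting 50% within 75% within 95%
  expect_true(pr$lo95 < pr$lo75 & pr$lo75 < pr$lo50)
  expect_true(pr$hi50 < pr$hi75 & pr$hi75 < pr$hi95)
  expect_error(predict_onset(fit, tibble::tibble(aphv = 11)), "phv")
})

test_that("adding an informative covariate shrinks the residual SD", {
  d <- make_onset_data(300, seed = 67)
  f0 <- fit_aft(d, "phv")
  f1 <- fit_aft(d, c("phv", "aphv"))
  expect_lt(f1$sigma, f0$sigma)
})

test_that("interval endpoints' open/closed reading does not change the likelihood", {
  d <- make_onset_data(50, seed = 71)
  X <- cbind(1, d$aphv)
  ll1 <- interval_gaussian_loglik(c(2.5, 0.9), 1, d, X)
  nudged <- dplyr::mutate(d,
    left = ifelse(censor_type == "interval", left + 1e-12, left),
    right = ifelse(censor_type == "interval", right - 1e-12, right)
  )
  ll2 <- interval_gaussian_loglik(c(2.5, 0.9), 1, nudged, X)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})
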