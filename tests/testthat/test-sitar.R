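test_that("noiseless data from a known curve is recovered almost exactly", {
  tpl <- growth_template("F")
  ages <- seq(7, 19, 0.75)
  dat <- dplyr::bind_rows(lapply(1:15, function(i) {
    tibble::tibble(child_id = paste0("c", i), age_years = ages,
                   height_cm = tpl$height(ages))
  }))
  fit <- suppressWarnings(suppressMessages(fit_sitar(dat)))
  grid <- seq(7, 19, 0.05)
  expect_lt(max(abs(predict_height(fit, grid) - tpl$height(grid))), 0.1)
})

test_that("height and age translations move only size and timing", {
  f1 <- fx_fit_F
  shifted <- dplyr::mutate(fx_growth_F, height_cm = height_cm + 10)
  f2 <- suppressWarnings(suppressMessages(fit_sitar(shifted, df = 8)))
  expect_equal(f2$a0 - f1$a0, 10, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-8)

  aged <- dplyr::mutate(fx_growth_F, age_years = age_years + 2)
  f3 <- suppressWarnings(suppressMessages(fit_sitar(aged, df = 8)))
  pk1 <- peak_markers(f1)
  pk3 <- peak_markers(f3)
  # refits on shifted data follow their own floating-point path, so the
  # peak location is equivariant only up to optimizer-level noise
  expect_equal(pk3$aphv - pk1$aphv, 2, tolerance = 0.02)
  expect_equal(pk3$phv, pk1$phv, tolerance = 1e-3)
})

test_that("per-child timing effects track the generating truth", {
  tr <- fx_truth_F[match(fx_fit_F$ranef$child_id, fx_truth_F$child_id), ]
  many <- fx_fit_F$ranef$n_obs >= 10
  expect_gt(sum(many), 10)
  expect_gt(cor(fx_fit_F$ranef$b[many], tr$b[many]), 0.9)
  expect_gt(cor(fx_fit_F$ranef$a[many], tr$a[many]), 0.9)
})

test_that("the marginal log-likelihood reduces to the Gaussian sum without random effects", {
  tpl <- growth_template("F")
  kn <- seq(7, 19, length.out = 9)
  g <- seq(7, 19, 0.02)
  X <- cbind(1, ns_basis(g, kn))
  beta <- qr.solve(X, tpl$height(g))
  ages <- seq(7.5, 18.5, 1)
  set.seed(8)
  dat <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(child_id = paste0("c", i), age_years = ages,
                   height_cm = tpl$height(ages) + rnorm(length(ages), 0, 0.6))
  }))
  fit <- new_sitar_fit(knots = kn, beta = beta[-1], a0 = beta[1],
                       Omega = diag(3) * 0, sigma = 0.6)
  ll <- sitar_loglik(fit, dat)
  mu <- beta[1] + drop(ns_basis(dat$age_years, kn) %*% beta[-1])
  closed <- sum(dnorm(dat$height_cm, mu, 0.6, log = TRUE))
  expect_equal(ll, closed, tolerance = 1e-8)

  # duplicating every observation doubles the fixed-effects log-likelihood
  ll_dup <- sitar_loglik(fit, dplyr::bind_rows(dat, dat))
  expect_equal(ll_dup, 2 * ll, tolerance = 1e-8)

  # the fitted residual SD is a local optimum of the marginal likelihood
  f <- fx_fit_F
  for (fac in c(0.8, 1.25)) {
    pert <- f
    pert$sigma <- f$sigma * fac
    expect_lt(sitar_loglik(pert, fx_growth_F), sitar_loglik(f, fx_growth_F))
  }
})

test_that("input validation catches bad tables", {
  expect_error(fit_sitar(tibble::tibble(child_id = "a", age_years = 1)),
               "missing columns")
  two_sex <- dplyr::bind_rows(
    tibble::tibble(child_id = "a", sex = "F", age_years = c(8, 9), height_cm = c(130, 135)),
    tibble::tibble(child_id = "b", sex = "M", age_years = c(8, 9), height_cm = c(130, 135))
  )
  expect_error(fit_sitar(two_sex), "one sex")
  one_child <- tibble::tibble(child_id = "a", age_years = c(8, 9, 10),
                              height_cm = c(130, 135, 140))
  expect_error(suppressMessages(fit_sitar(one_child)), "at least 2")

  dup <- dplyr::bind_rows(fx_growth_F,
                          fx_growth_F[fx_growth_F$child_id == fx_growth_F$child_id[1], ][1, ])
  expect_warning(
    expect_warning(fit_sitar(dup, df = 5,
                             control = sitar_control(max_iter = 2)),
                   "averaged"),
    "converge"
  )
})

test_that("prediction targets must exist in the fit", {
  expect_error(predict_height(fx_fit_F, 10, cohort = "nope"), "Unknown cohort")
  expect_error(predict_height(fx_fit_F, 10, child_id = "nope"), "Unknown child")
})
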