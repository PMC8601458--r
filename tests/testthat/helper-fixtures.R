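# Shared fixtures, built once per test run.  Sizes are kept small: these
# power the unit tests; the acceptance tests build their own study-sized
# simulations.

fx_sim <- simulate_cohort(sim_config(n_children = 40, seed = 101))

fx_growth_F <- dplyr::filter(fx_sim$growth, sex == "F",
                             age_years >= 7, age_years <= 19)
fx_truth_F <- dplyr::filter(fx_sim$truth, child_id %in% fx_growth_F$child_id)

fx_fit_F <- suppressWarnings(suppressMessages(
  fit_sitar(fx_growth_F, df = 8)
))
fx_markers_F <- suppressMessages(growth_markers(fx_fit_F))

# a synthetic mean curve with a well-resolved velocity peak, as a directly
# constructed fit object (no estimation): spline approximation of a smooth
# template, so its true peak is known to high accuracy by dense grid search
make_template_fit <- function(sex = "M", df = 12, ranef = NULL,
                              cohorts = NULL) {
  tpl <- growth_template(sex)
  g <- seq(7, 19, 0.02)
  kn <- seq(7, 19, length.out = df + 1)
  X <- cbind(1, ns_basis(g, kn))
  beta <- qr.solve(X, tpl$height(g))
  new_sitar_fit(knots = kn, beta = beta[-1], a0 = beta[1],
                cohorts = cohorts, ranef = ranef, sigma = 0.5,
                age_range = c(7, 19))
}

# interval data generated directly from the linear-Gaussian onset link with
# annual staging visits from age 8 (no growth modelling involved)
make_onset_data <- function(n, seed, b_aphv = 0.9, b_phv = -0.3, b_ow = -1,
                            sigma = 0.9, intercept = 2.5, visit_gap = 1,
                            right_cens_age = 19) {
  withr::with_seed(seed, {
    aphv <- rnorm(n, 11.7, 0.85)
    phv <- rnorm(n, 7.8, 0.9)
    size <- rnorm(n, 0, 5.4)
    overweight <- as.numeric(runif(n) < 0.2)
    onset <- intercept + b_aphv * aphv + b_phv * phv + b_ow * overweight +
      rnorm(n, 0, sigma)
    lo <- 8 + visit_gap * floor((onset - 8) / visit_gap)
    hi <- lo + visit_gap
    d <- tibble::tibble(
      child_id = sprintf("c%04d", seq_len(n)),
      left = lo, right = hi, censor_type = "interval",
      aphv = aphv, phv = phv, size = size, overweight = overweight,
      onset = onset
    )
    left_cens <- d$left < 8
    d$censor_type[left_cens] <- "left"
    d$right[left_cens] <- 8
    d$left[left_cens] <- 0
    right_cens <- d$right > right_cens_age
    d$censor_type[right_cens] <- "right"
    d$left[right_cens] <- right_cens_age
    d$right[right_cens] <- Inf
    d
  })
}
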