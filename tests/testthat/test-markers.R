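test_that("analytic velocity matches numeric differentiation of the height curve", {
  fit <- make_template_fit("M")
  ages <- seq(8, 18, 0.1)
  h <- 1e-5
  num <- (predict_height(fit, ages + h) - predict_height(fit, ages - h)) / (2 * h)
  expect_lt(max(abs(velocity_curve(fit, ages) - num)), 1e-4)
})

test_that("velocity is constant beyond the boundary knots", {
  fit <- make_template_fit("F")
  v_out <- velocity_curve(fit, c(19.2, 19.5, 19.9))
  expect_lt(max(abs(v_out - v_out[1])), 1e-10)
  expect_error(velocity_curve(fit, 25), "outside")
})

test_that("intensity rescales the velocity curve by exp(c)", {
  ranef <- tibble::tibble(child_id = c("z", "s"), cohort = "all",
                          a = 0, b = 0, c = c(0, log(1.1)))
  fit <- make_template_fit("M", ranef = ranef)
  ages <- seq(9, 17, 0.5)
  v_cohort <- velocity_curve(fit, ages, cohort = "all")
  # child with c = log(1.1): velocity = 1.1 x cohort velocity at rescaled ages
  v_child <- velocity_curve(fit, ages, child_id = "s")
  v_expect <- 1.1 * velocity_curve(fit, 1.1 * ages, cohort = "all")
  expect_equal(v_child, v_expect, tolerance = 1e-9)
  # zero random effects: identical to the cohort curve
  expect_equal(velocity_curve(fit, ages, child_id = "z"), v_cohort)
  expect_equal(predict_height(fit, ages, child_id = "z"),
               predict_height(fit, ages, cohort = "all"))
})

test_that("peak markers recover the template peak and match a grid oracle", {
  fit <- make_template_fit("M") # template peak 13.7 y / 9.9 cm per y
  pm <- peak_markers(fit)
  expect_equal(pm$aphv, 13.7, tolerance = 0.02)
  expect_equal(pm$phv, 9.9, tolerance = 0.02)
  expect_false(pm$boundary)

  # exhaustive 1e-4-spaced grid oracle
  g <- seq(8, 18, 1e-4)
  v <- velocity_curve(fit, g)
  expect_equal(pm$aphv, g[which.max(v)], tolerance = 1e-3)
  expect_equal(pm$phv, max(v), tolerance = 1e-6)
})

test_that("individual closed-form markers equal a per-child grid search", {
  set.seed(21)
  n <- 100
  ranef <- tibble::tibble(
    child_id = sprintf("c%03d", 1:n), cohort = "all",
    a = rnorm(n, 0, 5), b = rnorm(n, 0, 0.8), c = rnorm(n, 0, 0.1)
  )
  fit <- make_template_fit("F", ranef = ranef)
  mk <- suppressMessages(growth_markers(fit))
  for (i in sample(n, 20)) {
    g <- seq(7, 19, 5e-4)
    v <- velocity_curve(fit, g, child_id = ranef$child_id[i])
    expect_equal(mk$aphv[i], g[which.max(v)], tolerance = 1e-3)
    expect_equal(mk$phv[i], max(v), tolerance = 1e-3)
  }
  # monotonicity in c: higher intensity, earlier and taller peak
  ord <- order(ranef$c)
  same_b <- ranef$b[ord]
  # construct controlled comparison: two children differing only in c
  ranef2 <- tibble::tibble(child_id = c("lo", "hi"), cohort = "all",
                           a = 0, b = 0.3, c = c(0.0, 0.1))
  fit2 <- make_template_fit("F", ranef = ranef2)
  mk2 <- suppressMessages(growth_markers(fit2))
  expect_lt(mk2$aphv[mk2$child_id == "hi"], mk2$aphv[mk2$child_id == "lo"])
  expect_gt(mk2$phv[mk2$child_id == "hi"], mk2$phv[mk2$child_id == "lo"])
})

test_that("takeoff is the pre-peak velocity minimum and precedes aPHV", {
  tpl <- growth_template("F")
  ranef <- tibble::tibble(child_id = "k", cohort = "all", a = 0, b = 0, c = 0,
                          first_age = 7, last_age = 19, n_obs = 12L)
  fit <- make_template_fit("F", ranef = ranef)
  tk <- takeoff_age(fit, "k")
  expect_false(tk$takeoff_boundary)
  expect_equal(tk$takeoff_age, tpl$theta_takeoff, tolerance = 0.02)

  mk <- suppressMessages(growth_markers(fx_fit_F))
  ok <- !mk$takeoff_boundary & !is.na(mk$takeoff_age)
  expect_true(all(mk$takeoff_age[ok] < mk$aphv[ok]))

  # a child first seen after their velocity nadir gets flagged
  late <- tibble::tibble(child_id = "late", cohort = "all", a = 0, b = 0, c = 0,
                         first_age = 11.5, last_age = 19, n_obs = 8L)
  fit_late <- make_template_fit("F", ranef = late)
  expect_true(takeoff_age(fit_late, "late")$takeoff_boundary)
})

test_that("cohort contrasts report sane estimates, CIs and an overall test", {
  cc <- cohort_contrasts(fx_fit_F)
  expect_s3_class(cc, "cohort_contrasts")
  expect_true(all(c("aphv_mean", "phv_mean", "height_at_8", "height_at_18")
                  %in% names(cc$by_cohort)))
  if (nrow(cc$pairs)) {
    expect_true(all(cc$pairs$conf.low <= cc$pairs$estimate))
    expect_true(all(cc$pairs$estimate <= cc$pairs$conf.high))
    expect_true(all(cc$pairs$std.error > 0))
    expect_true(all(cc$overall$df == nrow(fx_fit_F$cohorts) - 1))
  }
})

test_that("a pure size offset shifts the cohort curve by a constant at every age", {
  cohorts <- tibble::tibble(cohort = c("ref", "tall"),
                            a = c(0, 2.25), b = 0, c = 0)
  fit <- make_template_fit("M", cohorts = cohorts)
  ages <- c(8, 10.5, 14, 18)
  d <- predict_height(fit, ages, cohort = "tall") -
    predict_height(fit, ages, cohort = "ref")
  expect_equal(d, rep(2.25, length(ages)), tolerance = 1e-10)
})

test_that("a single-cohort fit yields a means-only contrast table", {
  ranef <- tibble::tibble(child_id = c("a", "b"), cohort = "all",
                          a = c(1, -1), b = 0, c = 0)
  fit <- make_template_fit("F", ranef = ranef)
  cc <- cohort_contrasts(fit)
  expect_equal(nrow(cc$pairs), 0)
  expect_equal(nrow(cc$by_cohort), 1)
})
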