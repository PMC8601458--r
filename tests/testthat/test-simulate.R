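test_that("growth templates hit their calibration targets", {
  for (sx in c("F", "M")) {
    tpl <- growth_template(sx)
    tg <- tpl$targets
    expect_equal(tpl$theta_peak, tg$aphv, tolerance = 1e-6)
    expect_equal(tpl$phv, tg$phv, tolerance = 1e-6)
    expect_equal(tpl$height(8), tg$h8, tolerance = 1e-6)
    expect_equal(tpl$height(18), tg$h18, tolerance = 1e-4)
    expect_lt(tpl$theta_takeoff, tpl$theta_peak)
    expect_gt(tpl$v_takeoff, 0)
  }
})

test_that("near-zero random effects collapse every child onto the template", {
  cfg <- sim_config(n_children = 15, Omega = diag(3) * 1e-12,
                    cohorts = list(sim_cohort_spec("A", pubertal_spacing = 12,
                                                   dropout_hazard = 0)),
                    seed = 3)
  sim <- simulate_cohort(cfg)
  tplF <- growth_template("F")$theta_peak
  tplM <- growth_template("M")$theta_peak
  expected <- ifelse(sim$truth$sex == "F", tplF, tplM)
  expect_equal(sim$truth$aphv, expected, tolerance = 1e-4)
})

test_that("the onset link is exactly linear in its inputs", {
  # no marker effects, no noise: overweight shifts onset by exactly -1 year
  link <- list(
    F = list(intercept = 11, b_aphv = 0, b_phv = 0, b_ow = -1,
             b_aphv_ow = 0, sigma = 1e-9),
    M = list(intercept = 12, b_aphv = 0, b_phv = 0, b_ow = -1,
             b_aphv_ow = 0, sigma = 1e-9)
  )
  sim <- simulate_cohort(sim_config(n_children = 120, onset_link = link,
                                    seed = 5))
  tr <- sim$truth
  for (sx in c("F", "M")) {
    t_s <- dplyr::filter(tr, sex == sx)
    d <- mean(t_s$onset_age[t_s$overweight]) - mean(t_s$onset_age[!t_s$overweight])
    expect_equal(d, -1, tolerance = 1e-6)
  }
})

test_that("simulated truth reproduces the template-scale marker means", {
  sim <- simulate_cohort(sim_config(n_children = 250, seed = 42))
  girls <- dplyr::filter(sim$truth, sex == "F", cohort == "DIPP")
  # Monte-Carlo error of the mean ~ 0.85/sqrt(n)
  expect_equal(mean(girls$aphv), 11.7, tolerance = 3 * 0.85 / sqrt(nrow(girls)))
  expect_equal(mean(girls$phv), 7.8, tolerance = 3 * 1 / sqrt(nrow(girls)))
  expect_true(all(sim$truth$phv > 0))
  expect_true(all(sim$truth$takeoff_age < sim$truth$aphv))
})

test_that("visit schedules respect spacing, start age and dropout", {
  sp12 <- sim_cohort_spec("A", growth_spacing = c(12, 12),
                          pubertal_spacing = 12, dropout_hazard = 0)
  sch <- visit_schedule(sp12, seed = 1)
  expect_equal(sch$growth, 7:19)
  expect_length(sch$growth, 13)
  expect_true(min(sch$pubertal) >= 8)

  sp6 <- sim_cohort_spec("B", growth_spacing = c(6, 6), pubertal_spacing = 6,
                         dropout_hazard = 0)
  expect_true(min(visit_schedule(sp6, seed = 2)$pubertal) >= 8)

  drop_all <- sim_cohort_spec("C", dropout_hazard = 1)
  expect_length(visit_schedule(drop_all, seed = 3)$growth, 1)

  expect_error(sim_cohort_spec("D", growth_spacing = c(3, 6)), "6 to 12")
})

test_that("zero measurement noise puts observations exactly on the curves", {
  cfg <- sim_config(n_children = 10, sigma_height = 0, sigma_bmi = 0, seed = 7)
  sim <- simulate_cohort(cfg)
  tpl <- list(F = growth_template("F"), M = growth_template("M"))
  g <- dplyr::inner_join(sim$growth, sim$truth[, c("child_id", "a", "b", "c")],
                         by = "child_id")
  expected <- g$a + vapply(seq_len(nrow(g)), function(i) {
    tpl[[g$sex[i]]]$height((g$age_years[i] - g$b[i]) * exp(g$c[i]))
  }, numeric(1))
  expect_equal(g$height_cm, expected, tolerance = 1e-10)
})

test_that("emitted staging brackets the true onset (noise-free recovery)", {
  sim <- simulate_cohort(sim_config(n_children = 150, seed = 13))
  iv <- onset_intervals(sim$pubertal)
  d <- dplyr::inner_join(iv, sim$truth[, c("child_id", "onset_age")],
                         by = "child_id")
  ic <- dplyr::filter(d, censor_type == "interval")
  expect_gt(nrow(ic), 50)
  expect_true(all(ic$left < ic$onset_age))
  expect_true(all(ic$onset_age <= ic$right + 1e-9))
  # girls: recorded stage is B1 strictly before onset, >= B2 at/after
  pb <- dplyr::inner_join(
    dplyr::filter(sim$pubertal, sex == "F"),
    sim$truth[, c("child_id", "onset_age")], by = "child_id"
  )
  expect_true(all(pb$tanner_breast[pb$age_years < pb$onset_age] == 1))
  expect_true(all(pb$tanner_breast[pb$age_years >= pb$onset_age] >= 2))
  # boys: first >= 25 mm measurement is the first visit at/after onset
  tb <- dplyr::inner_join(
    dplyr::filter(sim$pubertal, sex == "M"),
    sim$truth[, c("child_id", "onset_age")], by = "child_id"
  )
  expect_true(all(tb$testis_len_mm[tb$age_years < tb$onset_age] < 25))
  expect_true(all(tb$testis_len_mm[tb$age_years >= tb$onset_age] >= 25))
})

test_that("simulation is deterministic given the seed and round-trips to CSV", {
  cfg <- sim_config(n_children = 20, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$growth, s2$growth)
  expect_identical(s1$truth, s2$truth)

  dir <- withr::local_tempdir()
  write_sim(s1, dir)
  back <- read_truth(file.path(dir, "truth.csv"))
  expect_equal(nrow(back), nrow(s1$truth))
  expect_equal(back$onset_age, s1$truth$onset_age, tolerance = 1e-12)
  expect_identical(back$overweight, s1$truth$overweight)

  # header-only file for an empty truth table
  empty <- s1
  empty$truth <- s1$truth[0, ]
  write_sim(empty, dir)
  expect_equal(nrow(read_truth(file.path(dir, "truth.csv"))), 0)
})

test_that("invalid configurations are rejected", {
  O_bad <- diag(c(1, -1, 1))
  expect_error(sim_config(Omega = O_bad), "positive definite")
  O_asym <- diag(3); O_asym[1, 2] <- 0.5
  expect_error(sim_config(Omega = O_asym), "symmetric")
  expect_error(sim_config(overweight_prevalence = c(F = 0, M = 0.2)), "prevalence")
})
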