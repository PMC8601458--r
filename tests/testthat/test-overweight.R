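test_that("noise-free polynomial BMI data is reproduced exactly", {
  set.seed(31)
  ages <- seq(8, 14, 1)
  dat <- dplyr::bind_rows(lapply(1:12, function(i) {
    co <- c(17 + rnorm(1, 0, 1), 0.3 + rnorm(1, 0, 0.1), rnorm(1, 0, 0.02))
    z <- ages - 11
    tibble::tibble(child_id = paste0("c", i), age_years = ages,
                   bmi = co[1] + co[2] * z + co[3] * z^2)
  }))
  fit <- suppressWarnings(fit_bmi_trajectory(dat, degree = 2))
  pred <- suppressWarnings(bmi_at_age(fit, dat$child_id, dat$age_years))
  expect_equal(pred, dat$bmi, tolerance = 1e-6)
})

test_that("bmi_at_age equals direct polynomial arithmetic with the stored coefficients", {
  dat <- dplyr::filter(fx_sim$growth, sex == "M", !is.na(bmi))
  fit <- suppressWarnings(fit_bmi_trajectory(dat, degree = 3))
  id <- fit$coefficients$child_id[1]
  age <- 12.3
  cf <- as.numeric(fit$coefficients[1, -1])
  z <- (age - fit$m_age) / fit$s_age
  manual <- sum(cf * z^(0:3))
  expect_equal(bmi_at_age(fit, id, age), manual, tolerance = 1e-10)

  # constant-BMI child evaluates to the same value at any age
  flat <- dplyr::bind_rows(
    tibble::tibble(child_id = "flat", age_years = seq(8, 16, 1), bmi = 18),
    tibble::tibble(child_id = "flat2", age_years = seq(8, 16, 1), bmi = 22)
  )
  ffit <- suppressWarnings(fit_bmi_trajectory(flat, degree = 2))
  vals <- suppressWarnings(bmi_at_age(ffit, "flat", c(8, 11, 15.5)))
  expect_lt(diff(range(vals)), 1e-6)

  expect_error(bmi_at_age(fit, "not-a-child", 10), "Unknown child_id")
  expect_warning(bmi_at_age(fit, id, 25), "outside")
})

test_that("zero between-child variance drives the random effects to the boundary", {
  ages <- seq(8, 14, 1)
  set.seed(5)
  dat <- dplyr::bind_rows(lapply(1:30, function(i) {
    tibble::tibble(child_id = paste0("c", i), age_years = ages,
                   bmi = 16 + 0.3 * (ages - 8) + rnorm(length(ages), 0, 0.2))
  }))
  fit <- suppressWarnings(fit_bmi_trajectory(dat, degree = 1))
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  re_sd <- vc$sdcor[is.na(vc$var2) & vc$grp != "Residual"]
  expect_lt(max(re_sd), 0.05)
})

test_that("ISO-BMI classification is strict at 25 and monotone in BMI", {
  ref <- synthetic_iso_bmi_reference()
  # find the child BMI whose adult equivalent is exactly 25 at age 10 (girls)
  target <- 25 / 21.7 * pubgrowth:::bmi_median_curve(10, "F")
  expect_equal(iso_bmi(target, 10, "F", ref), 25, tolerance = 1e-9)
  expect_false(classify_overweight(target, 10, "F", ref))       # exactly 25
  expect_true(classify_overweight(target + 1e-6, 10, "F", ref)) # just above

  bmis <- seq(14, 30, 0.5)
  iso <- iso_bmi(bmis, 11, "M", ref)
  expect_true(all(diff(iso) > 0))
  flags <- classify_overweight(bmis, 11, "M", ref)
  expect_true(all(diff(as.numeric(flags)) >= 0)) # never flips back
})

test_that("the reference reader validates schema and monotonicity", {
  ref <- synthetic_iso_bmi_reference()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ref, path)
  back <- read_iso_bmi_reference(path)
  expect_s3_class(back, "iso_bmi_reference")
  expect_equal(nrow(back), nrow(ref))

  bad <- ref
  bad$bmi_adult_equiv[2] <- 100 # breaks monotonicity at one age
  readr::write_csv(bad, path)
  expect_error(read_iso_bmi_reference(path), "increasing")

  readr::write_csv(ref[, -4], path)
  expect_error(read_iso_bmi_reference(path), "missing columns")
})

test_that("generator truth and reference-based classification agree exactly", {
  sim <- simulate_cohort(sim_config(n_children = 100, seed = 37))
  tr <- sim$truth
  p <- c(F = 0.15, M = 0.18)[tr$sex]
  scale <- (25 / 21.7 - 1) / qnorm(1 - p)
  bmi_true <- pubgrowth:::bmi_median_curve(tr$takeoff_age, tr$sex) *
    (1 + scale * tr$bmi_z)
  flags <- classify_overweight(bmi_true, tr$takeoff_age, tr$sex)
  expect_identical(unname(flags), tr$overweight)
})

test_that("overweight at takeoff agrees with classification at aPHV minus 2 years", {
  dat <- dplyr::filter(fx_sim$growth, sex == "F", !is.na(bmi))
  bfit <- suppressWarnings(fit_bmi_trajectory(dat, degree = 3))
  mk <- overweight_at_takeoff(fx_markers_F, bfit, "F")
  ok <- !is.na(mk$overweight) & !is.na(mk$aphv)
  alt_age <- pmin(pmax(mk$aphv[ok] - 2, 6), 20)
  alt_bmi <- suppressWarnings(bmi_at_age(bfit, mk$child_id[ok], alt_age))
  alt <- classify_overweight(alt_bmi, alt_age, "F")
  expect_gte(mean(mk$overweight[ok] == alt), 0.95)
})
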