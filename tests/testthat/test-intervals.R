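girl <- function(id, ages, stages) {
  tibble::tibble(child_id = id, age_years = ages, tanner_breast = stages)
}
boy <- function(id, ages, lens) {
  tibble::tibble(child_id = id, age_years = ages, testis_len_mm = lens)
}

test_that("the breast-stage rule covers all censoring patterns", {
  iv <- intervals_from_tanner_breast(girl("a", c(9, 10, 11), c(1, 1, 2)))
  expect_equal(iv$left, 10); expect_equal(iv$right, 11)
  expect_equal(iv$censor_type, "interval")
  expect_equal(iv$interval_length, 1)

  # missing B2, next available stage used
  iv <- intervals_from_tanner_breast(girl("a", c(9, 10, 11), c(1, NA, 3)))
  expect_equal(iv$left, 9); expect_equal(iv$right, 11)

  # all prepubertal: right-censored at the last staged visit
  iv <- intervals_from_tanner_breast(girl("a", c(9, 10, 11), c(1, 1, 1)))
  expect_equal(iv$censor_type, "right")
  expect_equal(iv$left, 11); expect_equal(iv$right, Inf)

  # pubertal at first visit: left-censored with left bound 0
  iv <- intervals_from_tanner_breast(girl("a", 8.2, 2))
  expect_equal(iv$censor_type, "left")
  expect_equal(iv$left, 0); expect_equal(iv$right, 8.2)

  # decreasing sequence warns but still applies the rule
  expect_warning(
    iv <- intervals_from_tanner_breast(girl("a", c(9, 10, 11), c(1, 2, 1))),
    "decreasing"
  )
  expect_equal(iv$left, 9); expect_equal(iv$right, 10)

  # no usable stages: dropped with a log entry
  expect_message(
    iv <- intervals_from_tanner_breast(girl("a", c(9, 10), c(NA, NA))),
    "dropped"
  )
  expect_equal(nrow(iv), 0)
})

test_that("the testis-length rule requires two successive visits at threshold", {
  iv <- intervals_from_testis_length(boy("a", c(10, 10.5, 11, 11.5),
                                         c(20, 24, 26, 27)))
  expect_equal(iv$left, 10.5); expect_equal(iv$right, 11)
  expect_equal(iv$censor_type, "interval")

  # qualifies from the first visit: left-censored
  iv <- intervals_from_testis_length(boy("a", c(10, 10.5), c(26, 27)))
  expect_equal(iv$censor_type, "left")
  expect_equal(iv$left, 0); expect_equal(iv$right, 10)

  # transient crossing ignored; onset at the first qualifying pair
  iv <- intervals_from_testis_length(boy("a", c(10, 11, 12, 13, 14),
                                         c(20, 26, 23, 26, 27)))
  expect_equal(iv$left, 12); expect_equal(iv$right, 13)

  # never qualifying: right-censored at the last visit
  iv <- intervals_from_testis_length(boy("a", c(10, 11, 12), c(18, 20, 23)))
  expect_equal(iv$censor_type, "right"); expect_equal(iv$left, 12)

  # unconfirmed single crossing at the final visit: right-censored, logged
  iv <- intervals_from_testis_length(boy("a", c(10, 11, 12), c(20, 23, 26)))
  expect_equal(iv$censor_type, "right"); expect_equal(iv$left, 12)
  expect_equal(attr(iv, "unconfirmed"), "a")

  # legacy 20 mm threshold available as an override
  iv <- intervals_from_testis_length(boy("a", c(10, 11, 12), c(18, 21, 22)),
                                     threshold_mm = 20)
  expect_equal(iv$censor_type, "interval")
  expect_equal(iv$left, 10); expect_equal(iv$right, 11)
})

test_that("the larger testis is used when both sides are recorded", {
  d <- tibble::tibble(child_id = "a", age_years = c(10, 11, 12),
                      testis_left_mm = c(20, 26, 24),
                      testis_right_mm = c(21, 24, 26))
  iv <- intervals_from_testis_length(d)
  expect_equal(iv$left, 10); expect_equal(iv$right, 11)
})

test_that("every child maps to exactly one censor type and reruns are idempotent", {
  sim <- simulate_cohort(sim_config(n_children = 80, seed = 19))
  iv <- onset_intervals(sim$pubertal)
  ids <- unique(sim$pubertal$child_id)
  expect_equal(sort(iv$child_id), sort(ids))
  expect_true(all(iv$censor_type %in% c("interval", "right", "left")))
  expect_true(all(iv$left < iv$right))
  expect_true(all(iv$left[iv$censor_type == "left"] == 0))
  expect_true(all(is.infinite(iv$right[iv$censor_type == "right"])))

  # idempotence: re-apply the rules to the staging implied by the intervals
  girls <- dplyr::filter(iv, sex == "F", censor_type == "interval")
  implied <- dplyr::bind_rows(lapply(seq_len(nrow(girls)), function(i) {
    girl(girls$child_id[i], c(girls$left[i], girls$right[i]), c(1, 2))
  }))
  iv2 <- intervals_from_tanner_breast(implied)
  expect_equal(iv2$left[match(girls$child_id, iv2$child_id)], girls$left)
  expect_equal(iv2$right[match(girls$child_id, iv2$child_id)], girls$right)
})

test_that("inclusion criteria filter the window, count heights and tally reasons", {
  growth <- dplyr::bind_rows(
    tibble::tibble(child_id = "few", age_years = c(8, 9, 10), height_cm = 130),
    tibble::tibble(child_id = "edge", age_years = c(6.5, 8, 9, 10, 11), height_cm = 130),
    tibble::tibble(child_id = "ok", age_years = c(8, 9, 10, 11, 12), height_cm = 140)
  )
  intervals <- tibble::tibble(
    child_id = c("few", "edge", "ok"),
    left = 10, right = 11, censor_type = "interval", interval_length = 1
  )
  res <- apply_inclusion_criteria(growth, intervals)
  expect_false("few" %in% res$eligible$child_id)
  # the age-6.5 row is dropped by the window but the child keeps 4 rows
  expect_true("edge" %in% res$eligible$child_id)
  expect_true(all(res$growth$age_years >= 7))
  expect_equal(res$report$n_excluded_few_heights, 1)
  expect_equal(res$report$n_eligible, 2)
  expect_equal(res$report$by_censor_type$interval, 2)

  # counting oracle on simulated data
  sim <- simulate_cohort(sim_config(n_children = 60, seed = 23))
  iv <- onset_intervals(sim$pubertal)
  res2 <- apply_inclusion_criteria(sim$growth, iv, min_heights = 4)
  direct <- sim$growth |>
    dplyr::filter(age_years >= 7, age_years <= 19) |>
    dplyr::count(child_id)
  eligible_direct <- intersect(direct$child_id[direct$n >= 4], iv$child_id)
  expect_setequal(res2$eligible$child_id, eligible_direct)
})
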