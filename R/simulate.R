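#' Cohort specification for the synthetic-data generator
#'
#' Describes one cohort's recruitment size, SITAR-scale shifts relative to
#' the overall mean curve, visit schedules and dropout.  The defaults in
#' [sim_config()] set up three cohorts shaped like typical Finnish follow-up
#' studies: a large cohort with growth data only, a medium cohort with annual
#' pubertal staging, and a small all-boys cohort with 6-monthly visits.
#'
#' @param name cohort label.
#' @param n number of children (overrides `n_children` in [sim_config()]).
#' @param size_offset,timing_offset,intensity_offset cohort fixed effects:
#'   cm, years, and log-scale intensity (0.01 is roughly a 1 percent change in peak velocity).
#' @param growth_spacing length-2 numeric, months between growth visits
#'   (uniform jitter between the two values); both within 6 to 12 months.
#' @param pubertal_spacing months between pubertal staging visits, or `NA`
#'   for a cohort without pubertal follow-up.
#' @param pubertal_start age (years) of the first pubertal staging visit.
#' @param sex "both", "F" or "M".
#' @param dropout_hazard per-visit probability of dropping out after a growth
#'   visit (geometric stopping; 0 = complete follow-up).
#' @return a list of class `sim_cohort_spec`.
#' @export
sim_cohort_spec <- function(name, n = NULL, size_offset = 0, timing_offset = 0,
                            intensity_offset = 0, growth_spacing = c(6, 12),
                            pubertal_spacing = NA_real_, pubertal_start = 8,
                            sex = "both", dropout_hazard = 0.02) {
  stopifnot(length(growth_spacing) == 2L, sex %in% c("both", "F", "M"))
  if (any(growth_spacing < 6 | growth_spacing > 12)) {
    stop("`growth_spacing` must lie within 6 to 12 months.")
  }
  if (diff(growth_spacing) < 0) stop("`growth_spacing` must be non-decreasing.")
  if (!is.na(pubertal_spacing) && pubertal_spacing <= 0) {
    stop("`pubertal_spacing` must be positive (months) or NA.")
  }
  if (dropout_hazard < 0 || dropout_hazard > 1) stop("`dropout_hazard` in [0, 1].")
  structure(as.list(environment()), class = "sim_cohort_spec")
}

#' Configuration of the synthetic multi-cohort generator
#'
#' Bundles everything [simulate_cohort()] needs: cohort specs, the
#' random-effect covariance of the SITAR size/timing/intensity effects, the
#' residual SDs, the linear-Gaussian link from growth markers to the age at
#' pubertal onset, and the overweight prevalence that calibrates the BMI
#' spread.
#'
#' The default onset links are calibrated to the default growth templates so
#' the mean onset is about 10.5 years (SD about 1.25) in girls and about
#' 11.6 years (SD about 0.95) in boys, with overweight girls starting
#' puberty 1.0 year earlier on average and no overweight effect in boys.
#'
#' @param n_children default children per cohort (cohort specs may override).
#' @param cohorts list of [sim_cohort_spec()]s.
#' @param Omega 3x3 symmetric positive-definite covariance of the per-child
#'   (size cm, timing years, intensity log-scale) random effects.  The
#'   default is calibrated through the closed-form marker identities so the
#'   implied between-child SDs are about 0.8-0.87 years for aPHV, 11.7
#'   percent for PHV and 5.4 cm for size, with aPHV and PHV negatively
#'   correlated.
#' @param sigma_height,sigma_bmi residual SDs for height (cm) and BMI.
#' @param onset_link named list with elements `F` and `M`, each a list with
#'   `intercept`, `b_aphv` (years per year), `b_phv` (years per cm/year),
#'   `b_ow` (years), `b_aphv_ow` (interaction, years per year) and `sigma`
#'   (residual SD, years).
#' @param overweight_prevalence named numeric, proportion of overweight
#'   children per sex.
#' @param tanner_stage_duration years spent in each breast stage after onset.
#' @param testis_noise_sd measurement noise SD (mm) for testis length.
#' @param seed integer seed making the whole simulation reproducible.
#' @return a list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_children = 50, seed = 7)
#' sim <- simulate_cohort(cfg)
#' dplyr::count(sim$truth, cohort, sex)
#' @export
sim_config <- function(n_children = 120,
                       cohorts = NULL,
                       Omega = NULL,
                       sigma_height = 0.7,
                       sigma_bmi = 0.25,
                       onset_link = NULL,
                       overweight_prevalence = c(F = 0.15, M = 0.18),
                       tanner_stage_duration = 1,
                       testis_noise_sd = 0.8,
                       seed = 1L) {
  cohorts <- cohorts %||% list(
    sim_cohort_spec("DIPP", growth_spacing = c(6, 12)),
    sim_cohort_spec("STRIP", size_offset = 1.7, timing_offset = -0.07,
                    intensity_offset = 0.0165, growth_spacing = c(6, 12),
                    pubertal_spacing = 12),
    sim_cohort_spec("BOY", n = 66, size_offset = 2.25, timing_offset = 0.13,
                    intensity_offset = 0.013, growth_spacing = c(6, 6),
                    pubertal_spacing = 6, sex = "M")
  )
  if (is.null(Omega)) {
    # calibrated so the *implied marker* spreads are realistic: since
    # aPHV_i = b_i + theta* exp(-c_i), intensity variation feeds into aPHV
    # with factor ~theta*; these values give SD(aPHV) ~ 0.8-0.87 y,
    # SD(PHV)/PHV ~ 11.7%, SD(size) 5.4 cm and cor(aPHV, PHV) ~ -0.3
    Omega <- diag(c(5.4^2, 2.16, 0.117^2))
    Omega[2, 3] <- Omega[3, 2] <- 0.145
  }
  onset_link <- onset_link %||% list(
    F = list(intercept = 2.46, b_aphv = 0.9, b_phv = -0.3, b_ow = -1.0,
             b_aphv_ow = 0, sigma = 0.9),
    M = list(intercept = 5.17, b_aphv = 0.65, b_phv = -0.25, b_ow = 0,
             b_aphv_ow = 0, sigma = 0.72)
  )
  cfg <- structure(list(
    n_children = n_children, cohorts = cohorts, Omega = Omega,
    sigma_height = sigma_height, sigma_bmi = sigma_bmi,
    onset_link = onset_link,
    overweight_prevalence = overweight_prevalence,
    tanner_stage_duration = tanner_stage_duration,
    testis_noise_sd = testis_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  O <- cfg$Omega
  if (!isTRUE(all.equal(O, t(O)))) stop("Omega must be symmetric.")
  ev <- eigen(O, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Omega must be positive definite.")
  if (cfg$sigma_height < 0 || cfg$sigma_bmi < 0) stop("Residual SDs must be >= 0.")
  for (s in c("F", "M")) {
    if (cfg$onset_link[[s]]$sigma <= 0) stop("onset sigma must be > 0.")
    p <- cfg$overweight_prevalence[[s]]
    if (is.na(p) || p <= 0 || p >= 1) stop("overweight prevalence in (0, 1).")
  }
  for (sp in cfg$cohorts) stopifnot(inherits(sp, "sim_cohort_spec"))
  invisible(cfg)
}

# one child's visit schedule drawn from the current RNG stream
schedule_one <- function(spec, start = 7, end = 19) {
  ages <- start
  repeat {
    gap <- runif(1, spec$growth_spacing[1L], spec$growth_spacing[2L]) / 12
    nxt <- ages[length(ages)] + gap
    if (nxt > end) break
    ages <- c(ages, nxt)
  }
  if (spec$dropout_hazard > 0) {
    keep <- min(rgeom(1, spec$dropout_hazard) + 1L, length(ages))
  } else {
    keep <- length(ages)
  }
  growth <- ages[seq_len(keep)]
  dropout_age <- growth[length(growth)]
  pubertal <- numeric(0)
  if (!is.na(spec$pubertal_spacing)) {
    pubertal <- seq(spec$pubertal_start, end, by = spec$pubertal_spacing / 12)
    pubertal <- pubertal[pubertal <= dropout_age + 1e-9]
  }
  list(growth = growth, pubertal = pubertal, dropout_age = dropout_age)
}

#' Draw one child's visit schedule
#'
#' Growth visits start at age 7 and recur with gaps drawn uniformly between
#' the cohort's spacing bounds until age 19; pubertal staging visits run at
#' fixed spacing from the cohort's start age.  A geometric per-visit dropout
#' hazard truncates both series at the dropout age.
#'
#' @param spec a [sim_cohort_spec()].
#' @param seed integer seed.
#' @return list with `growth`, `pubertal` (ages in years) and `dropout_age`.
#' @export
visit_schedule <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sim_cohort_spec"))
  withr::with_seed(as.integer(seed), schedule_one(spec))
}

#' Simulate a multi-cohort longitudinal growth and puberty study
#'
#' Generates, per child: SITAR random effects plus cohort offsets; the
#' implied true aPHV, PHV and takeoff age (closed-form shift identities on
#' the sex-specific template curve); a latent BMI level whose spread is
#' calibrated so that the configured proportion of children exceeds the
#' adult-equivalent BMI 25 cutoff; a true pubertal onset age from the
#' linear-Gaussian onset link; and then emits noisy growth visits, BMI
#' values, Tanner breast stages (girls) and testis lengths (boys) on the
#' cohort's visit schedules with dropout.
#'
#' Everything is reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `pubgrowth_sim`: list with tibbles `growth`
#'   (child_id, sex, cohort, age_years, height_cm, bmi), `pubertal`
#'   (child_id, sex, cohort, age_years, tanner_breast, testis_len_mm) and
#'   `truth` (one row per child).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  tpl <- list(F = growth_template("F"), M = growth_template("M"))
  Lchol <- chol(config$Omega)
  ref <- synthetic_iso_bmi_reference()

  truth <- list(); growth <- list(); pubertal <- list()
  row <- 0L
  for (spec in config$cohorts) {
    n <- spec$n %||% config$n_children
    for (i in seq_len(n)) {
      row <- row + 1L
      id <- sprintf("%s_%04d", spec$name, i)
      sex <- if (spec$sex == "both") sample(c("F", "M"), 1L) else spec$sex
      u <- c(rnorm(3) %*% Lchol)
      a_tot <- spec$size_offset + u[1L]
      b_tot <- spec$timing_offset + u[2L]
      c_tot <- spec$intensity_offset + u[3L]
      tp <- tpl[[sex]]
      aphv <- b_tot + tp$theta_peak * exp(-c_tot)
      phv <- exp(c_tot) * tp$phv
      takeoff <- b_tot + tp$theta_takeoff * exp(-c_tot)

      p_ow <- config$overweight_prevalence[[sex]]
      z_bmi <- rnorm(1)
      bmi_scale <- (25 / 21.7 - 1) / qnorm(1 - p_ow)
      # classify through the same reference map used downstream, so truth
      # and reference-based classification agree exactly
      ow <- classify_overweight(
        bmi_median_curve(takeoff, sex) * (1 + bmi_scale * z_bmi),
        takeoff, sex, ref
      )

      lk <- config$onset_link[[sex]]
      onset <- lk$intercept + lk$b_aphv * aphv + lk$b_phv * phv +
        lk$b_ow * ow + lk$b_aphv_ow * aphv * ow + rnorm(1, 0, lk$sigma)

      sch <- schedule_one(spec)
      h <- a_tot + tp$height((sch$growth - b_tot) * exp(c_tot)) +
        rnorm(length(sch$growth), 0, config$sigma_height)
      bmi <- bmi_median_curve(sch$growth, sex) * (1 + bmi_scale * z_bmi) +
        rnorm(length(sch$growth), 0, config$sigma_bmi)
      growth[[row]] <- tibble::tibble(
        child_id = id, sex = sex, cohort = spec$name,
        age_years = sch$growth, height_cm = h, bmi = bmi
      )

      if (length(sch$pubertal)) {
        if (sex == "F") {
          stage <- ifelse(sch$pubertal < onset, 1L,
                          pmin(5L, 2L + floor((sch$pubertal - onset) /
                                                config$tanner_stage_duration)))
          pubertal[[row]] <- tibble::tibble(
            child_id = id, sex = sex, cohort = spec$name,
            age_years = sch$pubertal,
            tanner_breast = as.integer(stage),
            testis_len_mm = NA_real_
          )
        } else {
          s <- 0.35
          t50 <- onset + s * log((45 - 25) / (25 - 18))
          len <- 18 + 27 / (1 + exp(-(sch$pubertal - t50) / s)) +
            rnorm(length(sch$pubertal), 0, config$testis_noise_sd)
          pre <- sch$pubertal < onset
          len[pre] <- pmin(len[pre], 24.5)
          len[!pre] <- pmax(len[!pre], 25)
          pubertal[[row]] <- tibble::tibble(
            child_id = id, sex = sex, cohort = spec$name,
            age_years = sch$pubertal,
            tanner_breast = NA_integer_,
            testis_len_mm = round(len, 1)
          )
        }
      }

      truth[[row]] <- tibble::tibble(
        child_id = id, sex = sex, cohort = spec$name,
        a = a_tot, b = b_tot, c = c_tot,
        aphv = aphv, phv = phv, takeoff_age = takeoff,
        overweight = ow, onset_age = onset,
        bmi_z = z_bmi, dropout_age = sch$dropout_age
      )
    }
  }
  structure(list(
    growth = dplyr::bind_rows(growth),
    pubertal = dplyr::bind_rows(pubertal),
    truth = dplyr::bind_rows(truth),
    config = config
  ), class = "pubgrowth_sim")
}

#' @export
print.pubgrowth_sim <- function(x, ...) {
  cat(sprintf("<pubgrowth_sim>  %d children (%d with pubertal data), %d growth rows; seed %d\n",
              nrow(x$truth), dplyr::n_distinct(x$pubertal$child_id),
              nrow(x$growth), x$config$seed))
  invisible(x)
}

#' Write or read a simulated study as plain CSV
#'
#' `write_sim()` writes `growth.csv`, `pubertal.csv` and `truth.csv` in the
#' package's CSV dialect; `read_truth()` reads a truth table back with the
#' correct column types, so that a write-read cycle is lossless.
#'
#' @param sim a `pubgrowth_sim`.
#' @param dir output directory (created if needed).
#' @return `write_sim()` the directory, invisibly; `read_truth()` a tibble.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "pubgrowth_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$growth, file.path(dir, "growth.csv"))
  readr::write_csv(sim$pubertal, file.path(dir, "pubertal.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_sim
#' @param path path to a `truth.csv`.
#' @export
read_truth <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    child_id = readr::col_character(), sex = readr::col_character(),
    cohort = readr::col_character(), overweight = readr::col_logical(),
    .default = readr::col_double()
  ))
}
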