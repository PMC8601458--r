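# median child BMI by age used by the synthetic ISO-BMI reference and the
# simulator; linear in age, anchored at typical school-age values
bmi_median_curve <- function(age, sex) {
  f <- as.numeric(sex == "F")
  (15.3 * f + 15.5 * (1 - f)) + (0.457 * f + 0.443 * (1 - f)) * (age - 6)
}

#' Synthetic ISO-BMI reference table
#'
#' A self-contained, clearly synthetic adult-equivalent BMI reference with
#' the schema expected by [read_iso_bmi_reference()]: for each sex and age,
#' several child-BMI grid points map to adult-equivalent values.  The mapping
#' is \eqn{\mathrm{ISO}(a, b) = 21.7 \cdot b / m(a)} with \eqn{m(a)} a
#' sex-specific median curve, which is strictly increasing in BMI at every
#' age.  It stands in for national reference tables (which are not shipped);
#' real analyses should supply their own reference CSV.
#'
#' @param ages age grid (years).
#' @param ratios child BMI grid expressed as multiples of the age median.
#' @return a tibble with columns `sex`, `age_years`, `bmi_child`,
#'   `bmi_adult_equiv`.
#' @export
synthetic_iso_bmi_reference <- function(ages = 6:20,
                                        ratios = c(0.6, 0.8, 1, 1.2, 1.5, 2)) {
  tidyr::expand_grid(sex = c("F", "M"), age_years = ages, ratio = ratios) |>
    dplyr::mutate(
      bmi_child = bmi_median_curve(.data$age_years, .data$sex) * .data$ratio,
      bmi_adult_equiv = 21.7 * .data$ratio
    ) |>
    dplyr::select(-"ratio")
}

#' Read and validate an ISO-BMI reference table
#'
#' The CSV must have columns `sex`, `age_years`, `bmi_child`,
#' `bmi_adult_equiv`, with the adult-equivalent value strictly increasing in
#' `bmi_child` at every (sex, age).
#'
#' @param path CSV path.
#' @return a validated reference tibble of class `iso_bmi_reference`.
#' @export
read_iso_bmi_reference <- function(path) {
  ref <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(), .default = readr::col_double()
  ))
  need <- c("sex", "age_years", "bmi_child", "bmi_adult_equiv")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("Reference is missing columns: ", paste(miss, collapse = ", "))
  bad <- ref |>
    dplyr::arrange(.data$sex, .data$age_years, .data$bmi_child) |>
    dplyr::group_by(.data$sex, .data$age_years) |>
    dplyr::summarise(mono = all(diff(.data$bmi_adult_equiv) > 0), .groups = "drop") |>
    dplyr::filter(!.data$mono)
  if (nrow(bad)) {
    stop("Reference not strictly increasing in BMI at: ",
         paste(bad$sex, round(bad$age_years, 1), collapse = "; "))
  }
  class(ref) <- c("iso_bmi_reference", class(ref))
  ref
}

#' Adult-equivalent (ISO) BMI
#'
#' Converts a child's BMI at a given age to the adult-equivalent scale by
#' monotone linear interpolation in BMI within the two bracketing reference
#' ages, then linear interpolation in age (ages outside the grid are clamped
#' to the nearest tabulated age).
#'
#' @param bmi,age numeric vectors (recycled).
#' @param sex "F" or "M" (vector allowed).
#' @param ref a reference tibble from [read_iso_bmi_reference()] or
#'   [synthetic_iso_bmi_reference()].
#' @return numeric vector of adult-equivalent BMI values.
#' @export
iso_bmi <- function(bmi, age, sex, ref = synthetic_iso_bmi_reference()) {
  n <- max(length(bmi), length(age), length(sex))
  bmi <- rep_len(bmi, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  vapply(seq_len(n), function(i) {
    if (is.na(bmi[i]) || is.na(age[i]) || is.na(sex[i])) return(NA_real_)
    rs <- ref[ref$sex == sex[i], ]
    if (!nrow(rs)) stop("Reference has no rows for sex ", sex[i])
    ags <- sort(unique(rs$age_years))
    a <- min(max(age[i], min(ags)), max(ags))
    lo <- max(ags[ags <= a]); hi <- min(ags[ags >= a])
    interp_at <- function(a0) {
      rr <- rs[rs$age_years == a0, ]
      if (nrow(rr) < 2L) stop("Reference needs >= 2 BMI rows at age ", a0,
                              " for sex ", sex[i])
      stats::approx(rr$bmi_child, rr$bmi_adult_equiv, xout = bmi[i],
                    rule = 2)$y +
        # linear extrapolation beyond the tabulated BMI range using end slopes
        extrap_excess(rr$bmi_child, rr$bmi_adult_equiv, bmi[i])
    }
    v_lo <- interp_at(lo)
    if (hi == lo) return(v_lo)
    v_hi <- interp_at(hi)
    v_lo + (v_hi - v_lo) * (a - lo) / (hi - lo)
  }, numeric(1))
}

extrap_excess <- function(x, y, x0) {
  k <- length(x)
  if (x0 < x[1L]) return((x0 - x[1L]) * (y[2L] - y[1L]) / (x[2L] - x[1L]))
  if (x0 > x[k]) return((x0 - x[k]) * (y[k] - y[k - 1L]) / (x[k] - x[k - 1L]))
  0
}

#' Classify overweight at a given age
#'
#' A child is classified overweight when the adult-equivalent BMI strictly
#' exceeds 25 (overweight and obese combined); a value of exactly 25 is
#' "other".  Typically evaluated at the growth-spurt takeoff age with the
#' BMI taken from the fitted individual BMI trajectory.
#'
#' @inheritParams iso_bmi
#' @return logical vector.
#' @export
classify_overweight <- function(bmi, age, sex, ref = synthetic_iso_bmi_reference()) {
  iso_bmi(bmi, age, sex, ref) > 25
}

#' Fit per-child BMI-age trajectories
#'
#' A polynomial linear mixed-effects model for BMI against age, with a
#' random intercept and random effects for every polynomial coefficient,
#' fitted by maximum likelihood.  Ages are centred and scaled internally for
#' conditioning.  Individual curves are the fixed part plus the child's
#' predicted random coefficients.
#'
#' @param data data frame with columns `child_id`, `age_years` and either
#'   `bmi` or both `height_cm` and `weight_kg` (BMI is then computed).
#' @param degree polynomial degree (default 3).
#' @return an object of class `bmi_trajectory_fit`.
#' @export
fit_bmi_trajectory <- function(data, degree = 3L) {
  stopifnot(is.data.frame(data), degree >= 1L)
  if (!"bmi" %in% names(data)) {
    if (!all(c("height_cm", "weight_kg") %in% names(data))) {
      stop("`data` needs a `bmi` column or both `height_cm` and `weight_kg`.")
    }
    data$bmi <- data$weight_kg / (data$height_cm / 100)^2
  }
  dat <- dplyr::as_tibble(data) |>
    dplyr::filter(!is.na(.data$bmi), !is.na(.data$age_years))
  if (dplyr::n_distinct(dat$age_years) <= degree) {
    stop("Polynomial degree must be smaller than the number of distinct ages.")
  }
  if (nrow(dat) < degree + 2L) stop("Too few observations for degree ", degree)
  m_age <- mean(dat$age_years); s_age <- sd(dat$age_years)
  if (s_age == 0) stop("All ages identical; cannot fit a trajectory.")
  dat$z <- (dat$age_years - m_age) / s_age
  for (d in seq_len(degree)) dat[[paste0("z", d)]] <- dat$z^d
  zt <- paste0("z", seq_len(degree))
  form <- stats::as.formula(paste(
    "bmi ~", paste(zt, collapse = " + "),
    "+ (", paste(c("1", zt), collapse = " + "), "| child_id)"
  ))
  fit <- lme4::lmer(form, data = dat, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("BMI trajectory fit is singular: at least one random-effect ",
            "variance is estimated at the boundary (near zero).")
  }
  coefs <- stats::coef(fit)$child_id
  structure(list(
    model = fit, degree = degree, m_age = m_age, s_age = s_age,
    coefficients = tibble::as_tibble(coefs, rownames = "child_id"),
    sigma = stats::sigma(fit),
    age_range = range(dat$age_years)
  ), class = "bmi_trajectory_fit")
}

#' @export
print.bmi_trajectory_fit <- function(x, ...) {
  cat(sprintf("<bmi_trajectory_fit>  degree %d, %d children, residual SD %.3f\n",
              x$degree, nrow(x$coefficients), x$sigma))
  invisible(x)
}

#' Evaluate a child's fitted BMI trajectory at an age
#'
#' Direct polynomial evaluation of the child's fixed-plus-random
#' coefficients.  Evaluation more than 1 year outside the observed age range
#' is allowed but flagged with a warning.
#'
#' @param fit a [fit_bmi_trajectory()] object.
#' @param child_id child identifier (scalar or vector).
#' @param age age in years (recycled against `child_id`).
#' @return numeric vector of BMI values.
#' @export
bmi_at_age <- function(fit, child_id, age) {
  stopifnot(inherits(fit, "bmi_trajectory_fit"))
  n <- max(length(child_id), length(age))
  child_id <- rep_len(as.character(child_id), n); age <- rep_len(age, n)
  if (any(age < fit$age_range[1L] - 1 | age > fit$age_range[2L] + 1)) {
    warning("BMI evaluated more than 1 year outside the observed age range.")
  }
  rows <- match(child_id, fit$coefficients$child_id)
  if (anyNA(rows)) {
    stop("Unknown child_id: ", paste(unique(child_id[is.na(rows)]), collapse = ", "))
  }
  cf <- as.matrix(fit$coefficients[rows, -1L, drop = FALSE])
  z <- (age - fit$m_age) / fit$s_age
  Z <- outer(z, 0:fit$degree, `^`)
  rowSums(cf * Z)
}

#' Overweight status at growth-spurt takeoff
#'
#' Convenience wrapper joining growth markers to fitted BMI trajectories:
#' evaluates each child's BMI at their takeoff age and classifies overweight
#' through the ISO-BMI reference.  Children without a valid takeoff age get
#' `NA`.
#'
#' @param markers a [growth_markers()] tibble (needs `child_id`,
#'   `takeoff_age`).
#' @param bmi_fit a [fit_bmi_trajectory()] object.
#' @param sex "F" or "M" for all children in `markers`.
#' @param ref ISO-BMI reference tibble.
#' @return `markers` with added columns `bmi_at_takeoff` and `overweight`.
#' @export
overweight_at_takeoff <- function(markers, bmi_fit, sex,
                                  ref = synthetic_iso_bmi_reference()) {
  stopifnot(is.data.frame(markers), inherits(bmi_fit, "bmi_trajectory_fit"))
  ok <- !is.na(markers$takeoff_age) &
    markers$child_id %in% bmi_fit$coefficients$child_id
  bmi <- rep(NA_real_, nrow(markers))
  if (any(ok)) {
    bmi[ok] <- suppressWarnings(
      bmi_at_age(bmi_fit, markers$child_id[ok], markers$takeoff_age[ok])
    )
  }
  markers$bmi_at_takeoff <- bmi
  markers$overweight <- ifelse(
    is.na(bmi), NA,
    classify_overweight(bmi, pmin(pmax(markers$takeoff_age, 6), 20), sex, ref)
  )
  markers
}
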