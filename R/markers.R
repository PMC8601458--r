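#' Height velocity from a SITAR fit
#'
#' Analytic derivative of the fitted height curve for a cohort mean curve or
#' an individual child: \eqn{v(t) = e^{c} h'\{(t - b) e^{c}\}} with the
#' target's total timing/intensity effects.  Never a finite difference of
#' data.
#'
#' @param fit a `sitar_fit`.
#' @param ages numeric vector of ages (years), inside the fitted range.
#' @param cohort,child_id target curve (see [predict_height()]).
#' @return numeric vector of velocities (cm/year).
#' @export
velocity_curve <- function(fit, ages, cohort = NULL, child_id = NULL) {
  stopifnot(inherits(fit, "sitar_fit"))
  if (any(ages < fit$age_range[1L] - 1 | ages > fit$age_range[2L] + 1)) {
    stop("Ages outside the fitted range (plus a 1-year margin).")
  }
  eff <- sitar_effects(fit, cohort, child_id)
  theta <- (ages - eff$b) * exp(eff$c)
  as.numeric(exp(eff$c) * (ns_basis(theta, fit$knots, 1L) %*% fit$beta))
}

# argmax of the mean-curve derivative h'(u) on the transformed-age scale:
# coarse grid then golden-section refinement
mean_curve_peak <- function(fit, grid_step = 0.01) {
  lo <- min(fit$knots); hi <- max(fit$knots)
  g <- seq(lo, hi, by = grid_step)
  v <- as.numeric(ns_basis(g, fit$knots, 1L) %*% fit$beta)
  k <- which.max(v)
  interior <- k > 1L && k < length(g)
  bracket <- c(g[max(1L, k - 1L)], g[min(length(g), k + 1L)])
  opt <- stats::optimize(function(u) -as.numeric(ns_basis(u, fit$knots, 1L) %*% fit$beta),
                         interval = bracket, tol = 1e-5)
  list(u_star = opt$minimum, h1_star = -opt$objective, interior = interior)
}

#' Age at peak height velocity and peak height velocity
#'
#' aPHV is the age at which the velocity curve attains its maximum; PHV is
#' the velocity there.  For the mean/cohort curve the maximum is located by a
#' 0.01-year grid search refined by golden-section search; individual values
#' follow from the closed-form SITAR shift identities
#' \deqn{aPHV_i = b_{tot} + u^* e^{-c_{tot}}, \quad PHV_i = e^{c_{tot}} h'(u^*),}
#' where \eqn{u^*} is the mean-curve peak location on the transformed age
#' scale.  A maximum on the boundary of the fitted range is flagged as
#' unreliable.
#'
#' @param fit a `sitar_fit`.
#' @param cohort,child_id target curve.
#' @return a one-row tibble with `aphv`, `phv` and `boundary` flag.
#' @export
peak_markers <- function(fit, cohort = NULL, child_id = NULL) {
  stopifnot(inherits(fit, "sitar_fit"))
  pk <- mean_curve_peak(fit)
  eff <- sitar_effects(fit, cohort, child_id)
  tibble::tibble(
    aphv = eff$b + pk$u_star * exp(-eff$c),
    phv = exp(eff$c) * pk$h1_star,
    boundary = !pk$interior
  )
}

#' Age at growth-spurt takeoff for one child
#'
#' The takeoff is the minimum of the individual velocity curve on the window
#' from the child's first observed age up to (but not including) the child's
#' aPHV; located by a 0.01-year grid search with golden-section refinement.
#' A minimum at the left end of the window is flagged: the pre-spurt nadir
#' was not observed.
#'
#' @param fit a `sitar_fit`.
#' @param child_id child identifier present in the fit.
#' @return one-row tibble with `takeoff_age` and `takeoff_boundary`.
#' @export
takeoff_age <- function(fit, child_id) {
  stopifnot(inherits(fit, "sitar_fit"))
  row <- fit$ranef[fit$ranef$child_id == child_id, ]
  if (nrow(row) != 1L) stop("Unknown child_id: ", child_id)
  pm <- peak_markers(fit, child_id = child_id)
  lo <- row$first_age
  hi <- pm$aphv - 1e-3
  if (!is.finite(lo)) lo <- fit$age_range[1L]
  if (hi <= lo + 0.02) {
    return(tibble::tibble(takeoff_age = NA_real_, takeoff_boundary = TRUE))
  }
  g <- seq(lo, hi, by = 0.01)
  v <- velocity_curve(fit, g, child_id = child_id)
  k <- which.min(v)
  bracket <- c(g[max(1L, k - 1L)], g[min(length(g), k + 1L)])
  opt <- stats::optimize(function(t) velocity_curve(fit, t, child_id = child_id),
                         interval = bracket, tol = 1e-5)
  tibble::tibble(takeoff_age = opt$minimum,
                 takeoff_boundary = k == 1L)
}

#' Per-child growth markers from a SITAR fit
#'
#' Derives, for every child in the fit, the age at peak height velocity
#' (aPHV, years), the peak height velocity (PHV, cm/year), the size parameter
#' (cm; the child's vertical shift from the reference mean curve, cohort
#' offset plus random effect),
#' the growth-spurt takeoff age, and reliability flags.  Children whose
#' velocity peak lies on the boundary of the fitted range are flagged and are
#' excluded from downstream onset modelling by [apply_inclusion_criteria()].
#'
#' @param fit a `sitar_fit`.
#' @param takeoff if `FALSE`, skip the per-child takeoff search (cheaper;
#'   used where only peak markers are needed).
#' @return a tibble with one row per child: `child_id`, `cohort`, `aphv`,
#'   `phv`, `size`, `takeoff_age`, `n_measurements`, `aphv_boundary`,
#'   `takeoff_boundary`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_children = 30, seed = 1))
#' fit <- fit_sitar(dplyr::filter(sim$growth, sex == "F"), df = 6)
#' growth_markers(fit)
#' @export
growth_markers <- function(fit, takeoff = TRUE) {
  stopifnot(inherits(fit, "sitar_fit"))
  pk <- mean_curve_peak(fit)
  co <- fit$cohorts[match(fit$ranef$cohort, fit$cohorts$cohort), ]
  b_tot <- fit$b0 + co$b + fit$ranef$b
  c_tot <- fit$c0 + co$c + fit$ranef$c
  aphv <- b_tot + pk$u_star * exp(-c_tot)
  out <- tibble::tibble(
    child_id = fit$ranef$child_id,
    cohort = fit$ranef$cohort,
    aphv = aphv,
    phv = exp(c_tot) * pk$h1_star,
    size = co$a + fit$ranef$a,
    n_measurements = fit$ranef$n_obs,
    aphv_boundary = !pk$interior |
      aphv <= fit$age_range[1L] | aphv >= fit$age_range[2L]
  )
  if (takeoff) {
    tk <- purrr::map_dfr(out$child_id, function(id) takeoff_age(fit, id))
    out$takeoff_age <- tk$takeoff_age
    out$takeoff_boundary <- tk$takeoff_boundary
  } else {
    out$takeoff_age <- NA_real_
    out$takeoff_boundary <- NA
  }
  n_flag <- sum(out$aphv_boundary | (out$takeoff_boundary %in% TRUE))
  if (n_flag) {
    message(n_flag, " children carry a boundary flag (peak or takeoff at the ",
            "edge of the observed range).")
  }
  dplyr::relocate(out, "child_id", "cohort", "aphv", "phv", "size",
                  "takeoff_age", "n_measurements")
}

#' Cohort contrasts of the growth markers
#'
#' Summarises the growth markers by cohort and contrasts cohorts pairwise,
#' mirroring the usual multi-cohort reporting layout: per-cohort means (SD)
#' of aPHV and PHV, model-based mean heights at 8 and 18 years, pairwise
#' differences with delta-method 95\% CIs and Wald tests, and an overall
#' joint Wald test per marker.
#'
#' Timing differences propagate the covariance of the cohort fixed effects
#' through \eqn{aPHV_C = b_C + u^* e^{-c_C}}; intensity differences through
#' \eqn{PHV_C = e^{c_C} h'(u^*)}; size differences use \eqn{a_C} directly.
#' The mean-curve quantities \eqn{u^*} and \eqn{h'(u^*)} are treated as
#' fixed.
#'
#' @param fit a `sitar_fit` with at least 2 cohorts and `vcov_fixed`
#'   available (see `compute_vcov` in [fit_sitar()]); with a single cohort a
#'   means-only table is returned.
#' @param level confidence level for the difference CIs.
#' @return an object of class `cohort_contrasts`: a list of tibbles
#'   `by_cohort`, `pairs`, `overall`.
#' @export
cohort_contrasts <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sitar_fit"))
  mk <- growth_markers(fit, takeoff = FALSE)
  pk <- mean_curve_peak(fit)
  z <- z_level(level)

  by_cohort <- mk |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      n = dplyr::n(),
      aphv_mean = mean(.data$aphv), aphv_sd = sd(.data$aphv),
      phv_mean = mean(.data$phv), phv_sd = sd(.data$phv),
      size_sd = sd(.data$size), .groups = "drop"
    )
  h8 <- vapply(by_cohort$cohort, function(ch) predict_height(fit, 8, cohort = ch), numeric(1))
  h18 <- vapply(by_cohort$cohort, function(ch) predict_height(fit, 18, cohort = ch), numeric(1))
  by_cohort$height_at_8 <- h8
  by_cohort$height_at_18 <- h18

  C <- nrow(fit$cohorts)
  if (C < 2L || is.null(fit$vcov_fixed)) {
    return(structure(list(by_cohort = by_cohort,
                          pairs = tibble::tibble(),
                          overall = tibble::tibble()),
                     class = "cohort_contrasts"))
  }

  V <- fit$vcov_fixed
  cohs <- fit$cohorts$cohort
  # parameter vector: (a, b, c) per non-reference cohort, in cohort order
  par_index <- function(coh, what) {
    nm <- paste(coh, what, sep = ".")
    match(nm, rownames(V))
  }
  eff <- fit$cohorts
  # per-cohort marker values implied by the fixed effects (reference included)
  aphv_C <- fit$b0 + eff$b + pk$u_star * exp(-(fit$c0 + eff$c))
  phv_C <- exp(fit$c0 + eff$c) * pk$h1_star
  size_C <- eff$a

  # gradient of each cohort's marker wrt the full offset parameter vector
  grad_of <- function(k, what) {
    g <- numeric(nrow(V))
    if (k == 1L) return(g) # reference: offsets fixed at zero
    coh <- cohs[k]
    if (what == "aphv") {
      g[par_index(coh, "b")] <- 1
      g[par_index(coh, "c")] <- -pk$u_star * exp(-(fit$c0 + eff$c[k]))
    } else if (what == "phv") {
      g[par_index(coh, "c")] <- phv_C[k]
    } else {
      g[par_index(coh, "a")] <- 1
    }
    g
  }

  marker_vals <- list(aphv = aphv_C, phv = phv_C, size = size_C)
  pairs <- tidyr::expand_grid(i = seq_len(C), j = seq_len(C)) |>
    dplyr::filter(.data$i > .data$j)
  pair_rows <- purrr::pmap_dfr(pairs, function(i, j) {
    purrr::map_dfr(names(marker_vals), function(w) {
      est <- marker_vals[[w]][i] - marker_vals[[w]][j]
      g <- grad_of(i, w) - grad_of(j, w)
      se <- sqrt(drop(t(g) %*% V %*% g))
      tibble::tibble(
        marker = w, cohort = cohs[i], reference = cohs[j],
        estimate = est, std.error = se,
        conf.low = est - z * se, conf.high = est + z * se,
        statistic = est / se,
        p.value = 2 * stats::pnorm(-abs(est / se))
      )
    })
  })

  overall <- purrr::map_dfr(names(marker_vals), function(w) {
    ests <- vapply(2:C, function(k) marker_vals[[w]][k] - marker_vals[[w]][1L], numeric(1))
    G <- t(vapply(2:C, function(k) grad_of(k, w), numeric(nrow(V))))
    Vg <- G %*% V %*% t(G)
    stat <- tryCatch(drop(t(ests) %*% solve(Vg, ests)), error = function(e) NA_real_)
    tibble::tibble(marker = w, chisq = stat, df = C - 1L,
                   p.value = stats::pchisq(stat, C - 1L, lower.tail = FALSE))
  })

  structure(list(by_cohort = by_cohort, pairs = pair_rows, overall = overall),
            class = "cohort_contrasts")
}

#' @export
print.cohort_contrasts <- function(x, ...) {
  cat("Growth markers by cohort:\n")
  print(as.data.frame(x$by_cohort), row.names = FALSE, digits = 4)
  if (nrow(x$pairs)) {
    cat("\nPairwise differences (delta method):\n")
    print(as.data.frame(x$pairs), row.names = FALSE, digits = 3)
    cat("\nOverall Wald tests:\n")
    print(as.data.frame(x$overall), row.names = FALSE, digits = 3)
  }
  invisible(x)
}
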