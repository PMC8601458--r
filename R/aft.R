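# stabilized log{Phi(zR) - Phi(zL)}; mirrors into the lower tail and falls
# back to a midpoint-density approximation for extremely narrow intervals
log_pnorm_diff <- function(zL, zR) {
  lo <- zL; hi <- zR
  flip <- zL + zR > 0
  if (any(flip)) {
    lo[flip] <- -zR[flip]
    hi[flip] <- -zL[flip]
  }
  a <- stats::pnorm(hi, log.p = TRUE)
  d <- stats::pnorm(lo, log.p = TRUE) - a
  out <- a + log1p(-exp(d))
  narrow <- !is.finite(out) | d > -1e-12
  if (any(narrow)) {
    mid <- (lo[narrow] + hi[narrow]) / 2
    out[narrow] <- stats::dnorm(mid, log = TRUE) + log(hi[narrow] - lo[narrow])
  }
  out
}

#' Interval-censored Gaussian log-likelihood
#'
#' The onset age of child \eqn{i} is modelled as \eqn{N(x_i^\top\beta,
#' \sigma^2)}.  Interval-censored children contribute
#' \eqn{\log\{\Phi((R_i-\mu_i)/\sigma) - \Phi((L_i-\mu_i)/\sigma)\}},
#' right-censored \eqn{\log\{1 - \Phi((L_i-\mu_i)/\sigma)\}}, left-censored
#' \eqn{\log\Phi((R_i-\mu_i)/\sigma)}, and degenerate intervals
#' (\eqn{L_i = R_i}, exact observations) the Gaussian log-density.  The
#' interval terms are evaluated with complementary-form stabilization so
#' very narrow intervals do not underflow.
#'
#' @param beta coefficient vector aligned with the columns of `X`.
#' @param sigma residual SD (> 0).
#' @param intervals tibble with `left`, `right`, `censor_type`.
#' @param X design matrix, one row per interval row.
#' @return scalar log-likelihood.
#' @export
interval_gaussian_loglik <- function(beta, sigma, intervals, X) {
  stopifnot(sigma > 0, nrow(X) == nrow(intervals), ncol(X) == length(beta))
  L <- intervals$left; R <- intervals$right
  if (any(L > R, na.rm = TRUE)) stop("Found an interval with left > right.")
  mu <- drop(X %*% beta)
  type <- intervals$censor_type
  ll <- numeric(nrow(X))
  ex <- type == "interval" & L == R
  iv <- type == "interval" & L < R
  ri <- type == "right"
  le <- type == "left"
  if (any(ex)) ll[ex] <- stats::dnorm(L[ex], mu[ex], sigma, log = TRUE)
  if (any(iv)) ll[iv] <- log_pnorm_diff((L[iv] - mu[iv]) / sigma,
                                        (R[iv] - mu[iv]) / sigma)
  if (any(ri)) ll[ri] <- stats::pnorm((L[ri] - mu[ri]) / sigma,
                                      lower.tail = FALSE, log.p = TRUE)
  if (any(le)) ll[le] <- stats::pnorm((R[le] - mu[le]) / sigma, log.p = TRUE)
  sum(ll)
}

# gradient of the log-likelihood in (beta, log sigma)
interval_gaussian_grad <- function(beta, log_sigma, intervals, X) {
  sigma <- exp(log_sigma)
  L <- intervals$left; R <- intervals$right
  mu <- drop(X %*% beta)
  type <- intervals$censor_type
  dmu <- numeric(nrow(X)); dls <- numeric(nrow(X))
  ex <- type == "interval" & L == R
  iv <- type == "interval" & L < R
  ri <- type == "right"
  le <- type == "left"
  if (any(ex)) {
    z <- (L[ex] - mu[ex]) / sigma
    dmu[ex] <- z / sigma
    dls[ex] <- z^2 - 1
  }
  if (any(iv)) {
    zL <- (L[iv] - mu[iv]) / sigma; zR <- (R[iv] - mu[iv]) / sigma
    lden <- log_pnorm_diff(zL, zR)
    phiL <- exp(stats::dnorm(zL, log = TRUE) - lden)
    phiR <- exp(stats::dnorm(zR, log = TRUE) - lden)
    dmu[iv] <- (phiL - phiR) / sigma
    dls[iv] <- phiL * zL - phiR * zR
  }
  if (any(ri)) {
    zL <- (L[ri] - mu[ri]) / sigma
    lam <- exp(stats::dnorm(zL, log = TRUE) -
                 stats::pnorm(zL, lower.tail = FALSE, log.p = TRUE))
    dmu[ri] <- lam / sigma
    dls[ri] <- lam * zL
  }
  if (any(le)) {
    zR <- (R[le] - mu[le]) / sigma
    lam <- exp(stats::dnorm(zR, log = TRUE) - stats::pnorm(zR, log.p = TRUE))
    dmu[le] <- -lam / sigma
    dls[le] <- -lam * zR
  }
  c(drop(crossprod(X, dmu)), sum(dls))
}

#' Model term presets for the onset regression
#'
#' `"simple"` uses only aPHV and PHV; `"extended_girls"` adds overweight and
#' its interaction with aPHV; `"extended_boys"` adds overweight only.
#' Custom term vectors may use `aphv`, `phv`, `size`, `overweight` and `:`
#' interactions between them; interactions require their main effects
#' (hierarchy).
#'
#' @param spec preset name or character vector of terms.
#' @return character vector of terms, validated for hierarchy.
#' @export
onset_model_spec <- function(spec = c("simple", "extended_girls", "extended_boys")) {
  if (length(spec) == 1L && spec %in% c("simple", "extended_girls", "extended_boys")) {
    spec <- switch(spec,
      simple = c("aphv", "phv"),
      extended_girls = c("aphv", "phv", "overweight", "aphv:overweight"),
      extended_boys = c("aphv", "phv", "overweight")
    )
  }
  mains <- spec[!grepl(":", spec)]
  for (tm in spec[grepl(":", spec)]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    if (!all(parts %in% mains)) {
      stop("Interaction ", tm, " requires its main effects in the model.")
    }
  }
  spec
}

aft_design <- function(data, terms) {
  cols <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("Missing covariate column(s): ", paste(miss, collapse = ", "))
  }
  X <- matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)"))
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    v <- Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- tm
  }
  if (anyNA(X)) stop("Covariates contain missing values.")
  X
}

#' Fit the interval-censored Gaussian time-to-pubertal-onset model
#'
#' Maximizes [interval_gaussian_loglik()] over \eqn{(\beta, \log\sigma)} by
#' BFGS with analytic gradients, started from least squares on interval
#' midpoints.  Standard errors come from the observed information (numeric
#' Hessian at the optimum).
#'
#' @param data tibble containing `left`, `right`, `censor_type` and the
#'   covariate columns named in `spec`.
#' @param spec an [onset_model_spec()] (preset name, term vector, or
#'   `character(0)` for an intercept-only model).
#' @return object of class `aft_fit` with `coefficients`, `sigma`,
#'   `logLik`, `vcov` (of \eqn{(\beta, \log\sigma)}), term names and
#'   censoring counts.  Methods: `tidy()`, `glance()`, [predict_onset()].
#' @examples
#' toy <- tibble::tibble(left = c(9, 10, 11), right = c(10, 11, 12),
#'                       censor_type = "interval", aphv = c(11, 12, 13))
#' fit <- fit_aft(toy, "aphv")
#' tidy(fit)
#' @export
fit_aft <- function(data, spec = "simple") {
  stopifnot(is.data.frame(data))
  terms <- if (length(spec)) onset_model_spec(spec) else character(0)
  need <- c("left", "right", "censor_type")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("`data` is missing columns: ", paste(miss, collapse = ", "))
  data <- dplyr::as_tibble(data)
  if (!all(data$censor_type %in% c("interval", "right", "left"))) {
    stop("censor_type must be interval, right or left.")
  }
  X <- aft_design(data, terms)
  if (nrow(X) <= ncol(X)) stop("More parameters than children.")

  # start: least squares on pseudo-midpoints
  mid <- dplyr::case_when(
    data$censor_type == "interval" ~ (data$left + data$right) / 2,
    data$censor_type == "right" ~ data$left + 1,
    TRUE ~ pmax(data$right - 1, 0)
  )
  b0 <- qr.solve(X, mid)
  s0 <- max(sd(mid - drop(X %*% b0)), 0.25)
  par0 <- c(b0, log(s0))

  negll <- function(par) {
    s <- exp(par[length(par)])
    if (!is.finite(s) || s < 1e-10) return(1e10)
    v <- -interval_gaussian_loglik(par[-length(par)], s, data, X)
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(par) {
    ls <- min(max(par[length(par)], -20), 20)
    g <- -interval_gaussian_grad(par[-length(par)], ls, data, X)
    g[!is.finite(g)] <- 0
    g
  }
  opt <- stats::optim(par0, negll, neggr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("Onset model did not converge (optim code ", opt$convergence, ").")
  }
  p <- length(opt$par) - 1L
  H <- stats::optimHess(opt$par, negll, neggr)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 1L, p + 1L))
  nm <- c(colnames(X), "log(sigma)")
  dimnames(V) <- list(nm, nm)
  structure(list(
    coefficients = setNames(opt$par[seq_len(p)], colnames(X)),
    sigma = unname(exp(opt$par[p + 1L])),
    logLik = -opt$value,
    vcov = V,
    terms = terms,
    n = nrow(X),
    n_by_type = as.list(table(data$censor_type)),
    data = data
  ), class = "aft_fit")
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("<aft_fit>  n = %d (%s); sigma = %.3f y; logLik = %.2f\n",
              x$n,
              paste(names(x$n_by_type), unlist(x$n_by_type),
                    sep = ": ", collapse = ", "),
              x$sigma, x$logLik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.aft_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  p <- length(x$coefficients)
  se <- sqrt(diag(x$vcov))[seq_len(p)]
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * stats::pnorm(-abs(unname(x$coefficients / se)))
  )
  if (conf.int) {
    z <- z_level(conf.level)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' @export
glance.aft_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_interval = x$n_by_type$interval %||% 0L,
    n_right = x$n_by_type$right %||% 0L,
    n_left = x$n_by_type$left %||% 0L,
    sigma = x$sigma, logLik = x$logLik,
    AIC = -2 * x$logLik + 2 * (length(x$coefficients) + 1)
  )
}

#' Predict pubertal onset with normal-quantile prediction intervals
#'
#' The point prediction is the fitted mean \eqn{x^\top\hat\beta}; each
#' requested prediction interval is \eqn{x^\top\hat\beta \pm z_{(1+l)/2}
#' \hat\sigma} (residual spread only, no parameter-uncertainty inflation).
#'
#' @param fit an `aft_fit`.
#' @param newdata tibble with the fitted covariate columns.
#' @param levels prediction-interval levels.
#' @return tibble with `.pred` and `lo`/`hi` columns per level (percent
#'   suffix, e.g. `lo95`).
#' @export
predict_onset <- function(fit, newdata, levels = c(0.5, 0.75, 0.95)) {
  stopifnot(inherits(fit, "aft_fit"))
  X <- aft_design(dplyr::as_tibble(newdata), fit$terms)
  out <- tibble::tibble(.pred = drop(X %*% fit$coefficients))
  for (l in levels) {
    z <- z_level(l)
    tag <- sprintf("%.0f", 100 * l)
    out[[paste0("lo", tag)]] <- out$.pred - z * fit$sigma
    out[[paste0("hi", tag)]] <- out$.pred + z * fit$sigma
  }
  out
}

#' Intercept-only onset summaries by group
#'
#' Fits a separate intercept-only interval-censored Gaussian model per
#' group; the intercept is the group's mean onset age and \eqn{\hat\sigma}
#' its SD (maximum likelihood, so in the censoring-free limit the
#' denominator is n).
#'
#' @param intervals onset interval tibble.
#' @param group name of the grouping column in `intervals`.
#' @param min_n minimum group size.
#' @return tibble with `group`, `n`, `mean_onset`, `sd_onset`.
#' @export
summarize_onset <- function(intervals, group = "cohort", min_n = 10L) {
  stopifnot(group %in% names(intervals))
  intervals |>
    dplyr::group_by(grp = .data[[group]]) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < min_n) {
        stop("Group ", key$grp, " has fewer than ", min_n, " children.")
      }
      if (all(g$censor_type == "right")) {
        stop("Group ", key$grp, " is entirely right-censored; ",
             "the mean onset is not estimable.")
      }
      f <- fit_aft(g, character(0))
      tibble::tibble(group = key$grp, n = nrow(g),
                     mean_onset = unname(f$coefficients[1L]),
                     sd_onset = f$sigma)
    }) |>
    dplyr::bind_rows() |>
    stats::setNames(c(group, "n", "mean_onset", "sd_onset"))
}
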