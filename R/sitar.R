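#' Control parameters for the SITAR fitter
#'
#' @param max_iter maximum outer iterations.
#' @param tol relative change in the Laplace marginal log-likelihood at which
#'   the alternating scheme is declared converged.
#' @param re_iter Gauss-Newton sweeps for the random-effect modes per outer
#'   iteration.
#' @param basis_df number of spline basis columns used when the mean curve is
#'   penalized (the default `df = NULL` in [fit_sitar()]).
#' @param lambda fixed curvature penalty; `NULL` selects it by GCV during the
#'   first `gcv_freeze` outer iterations and then freezes it.
#' @param gcv_freeze outer iteration after which the GCV penalty is frozen.
#' @param sigma_floor,omega_floor lower bounds keeping the residual SD and the
#'   random-effect covariance away from singularity.
#' @return a named list of class `sitar_control`.
#' @export
sitar_control <- function(max_iter = 600L, tol = 1e-6, re_iter = 2L,
                          basis_df = 16L, lambda = NULL, gcv_freeze = 5L,
                          sigma_floor = 1e-3, omega_floor = 1e-8) {
  structure(as.list(environment()), class = "sitar_control")
}

# ---- internal helpers --------------------------------------------------------

# curvature penalty matrix int h''(u)^2 du for the basis on its knot span
curvature_penalty <- function(knots) {
  g <- seq(min(knots), max(knots), length.out = 2001L)
  B2 <- ns_basis(g, knots, deriv = 2L)
  crossprod(B2) * (g[2L] - g[1L])
}

chol_logdet <- function(M) 2 * sum(log(diag(chol(M))))

# vectorised per-child accumulation of J'J (6 entries) and J'r (3 entries)
# returns list of 3x3 solves done in a light loop over children
re_normal_eqs <- function(r, j2, j3, child_index, n_children) {
  prods <- cbind(j2, j3, j2 * j2, j2 * j3, j3 * j3, r, j2 * r, j3 * r,
                 rep(1, length(r)))
  agg <- rowsum(prods, child_index, reorder = FALSE)
  # column order: S2 S3 S22 S23 S33 Sr S2r S3r n
  agg
}

# ---- fitter ------------------------------------------------------------------

#' Fit the SITAR growth-curve model
#'
#' Super-Imposition by Translation And Rotation: every child's height curve is
#' a shifted, time-scaled copy of a shared mean curve,
#' \deqn{y_{ij} = (a_0 + a_{C(i)} + a_i) + h\{(t_{ij} - b_{C(i)} - b_i)
#'   e^{c_{C(i)} + c_i}\} + \varepsilon_{ij},}
#' with \eqn{\varepsilon \sim N(0, \sigma_e^2)} and per-child random effects
#' \eqn{(a_i, b_i, c_i) \sim N(0, \Omega)}.  `a` is size (cm, vertical shift),
#' `b` is timing (years, horizontal shift of the growth spurt), and `c` is
#' intensity: velocity is multiplied by \eqn{e^c}, so small `c` reads as a
#' percentage difference in peak velocity.  Cohort-specific fixed effects
#' (`a_C`, `b_C`, `c_C`) are offsets relative to a reference cohort.
#'
#' Estimation alternates (i) a penalized update of the mean curve and size
#' fixed effects, (ii) Gauss-Newton updates of the per-child random-effect
#' modes of the Laplace-approximate posterior, with cohort means of the modes
#' transferred into the cohort fixed effects, and (iii) closed-form
#' Laplace/EM updates of \eqn{\Omega} and \eqn{\sigma_e^2}; convergence is
#' monitored on the Laplace marginal log-likelihood.
#'
#' The mean curve \eqn{h} is a natural cubic spline.  By default it uses
#' `control$basis_df` basis columns with a curvature penalty chosen by GCV,
#' which keeps the velocity curve (the analytic derivative of \eqn{h}) stable
#' enough for peak-location work; passing an integer `df` instead gives an
#' unpenalized spline with `df` columns.
#'
#' @param data a data frame with columns `child_id`, `age_years`, `height_cm`
#'   and (if more than one cohort) `cohort`.  One sex at a time: if a `sex`
#'   column is present it must be constant.
#' @param df `NULL` (default, penalized curve) or an integer number of
#'   unpenalized spline basis columns.
#' @param reference reference cohort; default is the first alphabetically.
#' @param compute_vcov if `TRUE` (default) and there are 2 or more cohorts,
#'   the covariance of the cohort fixed effects is computed from the numeric
#'   Hessian of the Laplace marginal log-likelihood.
#' @param control a [sitar_control()] list.
#' @return an object of class `sitar_fit`; see [predict_height()],
#'   [growth_markers()], [cohort_contrasts()], `tidy()`, `glance()`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_children = 30, seed = 1))
#' girls <- dplyr::filter(sim$growth, sex == "F")
#' fit <- fit_sitar(girls, df = 6)
#' glance(fit)
#' @export
fit_sitar <- function(data, df = NULL, reference = NULL, compute_vcov = TRUE,
                      control = sitar_control()) {
  stopifnot(is.data.frame(data))
  need <- c("child_id", "age_years", "height_cm")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("`data` is missing columns: ", paste(miss, collapse = ", "))
  if ("sex" %in% names(data) && dplyr::n_distinct(data$sex) > 1L) {
    stop("`data` contains more than one sex; fit sexes separately.")
  }
  if (!"cohort" %in% names(data)) data$cohort <- "all"

  dat <- dplyr::as_tibble(data) |>
    dplyr::filter(!is.na(.data$age_years), !is.na(.data$height_cm)) |>
    dplyr::arrange(.data$child_id, .data$age_years)
  if (any(dat$age_years <= 0 | dat$age_years >= 25)) {
    stop("Ages must lie in (0, 25) years.")
  }

  dup <- dat |>
    dplyr::count(.data$child_id, .data$age_years) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    warning(sprintf("%d duplicated (child_id, age) rows averaged.", sum(dup$n) - nrow(dup)))
    dat <- dat |>
      dplyr::group_by(.data$child_id, .data$cohort, .data$age_years) |>
      dplyr::summarise(height_cm = mean(.data$height_cm), .groups = "drop") |>
      dplyr::arrange(.data$child_id, .data$age_years)
  }

  nv <- dat |> dplyr::count(.data$child_id)
  few <- nv$child_id[nv$n < 2L]
  if (length(few)) {
    message(length(few), " children with fewer than 2 height measurements dropped.")
    dat <- dplyr::filter(dat, !.data$child_id %in% few)
  }
  if (dplyr::n_distinct(dat$child_id) < 2L) stop("Need at least 2 usable children.")

  ctrl <- control
  penalized <- is.null(df)
  p_df <- if (penalized) ctrl$basis_df else as.integer(df)

  t <- dat$age_years
  y <- dat$height_cm
  child <- factor(dat$child_id, levels = unique(dat$child_id))
  idx <- as.integer(child)
  N <- nlevels(child)
  cohorts <- sort(unique(as.character(dat$cohort)))
  reference <- reference %||% cohorts[1L]
  if (!reference %in% cohorts) stop("Unknown reference cohort: ", reference)
  cohorts <- c(reference, setdiff(cohorts, reference))
  coh_of_child <- dat$cohort[!duplicated(idx)][order(unique(idx))]
  coh_child <- match(as.character(coh_of_child), cohorts) # per child, 1 = ref
  coh_obs <- coh_child[idx]
  C <- length(cohorts)

  knots <- sitar_knots(t, p_df)
  Pmat <- if (penalized) curvature_penalty(knots) else NULL

  # --- starting values --------------------------------------------------------
  tmax_inc <- vapply(split(seq_along(t), idx), function(ii) {
    ti <- t[ii]; yi <- y[ii]
    if (length(ii) < 2L) return(mean(ti))
    vel <- diff(yi) / diff(ti)
    k <- which.max(vel)
    (ti[k] + ti[k + 1L]) / 2
  }, numeric(1))
  coh_mean_t <- as.numeric(tapply(tmax_inc, coh_child, mean))
  # global timing/intensity (b0, c0) are explicit parameters; cohort offsets
  # b_C/c_C are relative to the reference cohort (first entry pinned at 0)
  b0 <- 0; c0 <- 0
  b_C <- coh_mean_t - coh_mean_t[1L]
  u <- cbind(a = rep(0, N),
             b = tmax_inc - coh_mean_t[coh_child],
             c = rep(0, N))
  a_C <- rep(0, C); c_C <- rep(0, C)
  Omega <- diag(c(25, 0.4, 0.01))
  sig2 <- 1
  a0 <- 0; beta <- rep(0, p_df)
  lambda <- if (penalized) ctrl$lambda else 0

  n_obs <- length(y)
  coh_dum <- if (C > 1L) {
    D <- matrix(0, n_obs, C - 1L)
    for (k in 2:C) D[coh_obs == k, k - 1L] <- 1
    D
  } else NULL

  theta_of <- function(b0, c0, b_C, c_C, u) {
    bt <- b0 + b_C[coh_obs] + u[idx, 2L]
    ct <- c0 + c_C[coh_obs] + u[idx, 3L]
    list(theta = (t - bt) * exp(ct), ect = exp(ct))
  }

  # mean-curve update: shape coefficients, size effects, and a linearized
  # global time-shift/scale correction (db0, dc0) via two extra columns
  curve_step <- function(b0, c0, b_C, c_C, u, beta_prev, lambda, select_gcv) {
    tf <- theta_of(b0, c0, b_C, c_C, u)
    B <- ns_basis(tf$theta, knots)
    m1 <- c(ns_basis(tf$theta, knots, 1L) %*% beta_prev)
    warp <- max(abs(m1)) > 1e-8
    W <- if (warp) cbind(-tf$ect * m1, tf$theta * m1) else NULL
    X <- cbind(1, coh_dum, W, B)
    n_fix <- ncol(X) - p_df
    resp <- y - u[idx, 1L]
    XtX <- crossprod(X); Xty <- crossprod(X, resp)
    if (penalized) {
      Pfull <- matrix(0, ncol(X), ncol(X))
      Pfull[(n_fix + 1):ncol(X), (n_fix + 1):ncol(X)] <- Pmat
      if (select_gcv) {
        gcv <- function(ll) {
          A <- XtX + exp(ll) * Pfull
          bh <- solve(A, Xty)
          edf <- sum(diag(solve(A, XtX)))
          n_obs * sum((resp - X %*% bh)^2) / (n_obs - edf)^2
        }
        lambda <- exp(stats::optimize(gcv, c(-6, 16))$minimum)
      }
      bh <- solve(XtX + lambda * Pfull, Xty)
    } else {
      bh <- solve(XtX, Xty)
    }
    k <- 1L
    a0 <- bh[k]; k <- k + 1L
    a_C_new <- if (C > 1L) { v <- c(0, bh[k:(k + C - 2L)]); k <- k + C - 1L; v } else 0
    if (warp) { db0 <- bh[k]; dc0 <- bh[k + 1L]; k <- k + 2L } else db0 <- dc0 <- 0
    list(a0 = a0, a_C_new = a_C_new, db0 = db0, dc0 = dc0,
         beta = bh[k:(k + p_df - 1L)], lambda = lambda)
  }

  # evaluate residuals and RE design for current state
  model_parts <- function(a0, a_C, b0, c0, b_C, c_C, beta, u) {
    tf <- theta_of(b0, c0, b_C, c_C, u)
    B <- ns_basis(tf$theta, knots)
    m1 <- c(ns_basis(tf$theta, knots, 1L) %*% beta)
    mu <- a0 + a_C[coh_obs] + u[idx, 1L] + c(B %*% beta)
    r <- y - mu
    j2 <- -tf$ect * m1          # d mu / d b_i
    j3 <- tf$theta * m1         # d mu / d c_i
    list(r = r, j2 = j2, j3 = j3)
  }

  child_obj <- function(a0, a_C, b0, c0, b_C, c_C, beta, u, Oinv, sig2) {
    tf <- theta_of(b0, c0, b_C, c_C, u)
    mu <- a0 + a_C[coh_obs] + u[idx, 1L] + c(ns_basis(tf$theta, knots) %*% beta)
    sse <- rowsum((y - mu)^2, idx, reorder = FALSE)[, 1L]
    pen <- rowSums((u %*% Oinv) * u)
    sse / (2 * sig2) + pen / 2
  }

  # joint Gauss-Newton step for the random-effect modes and the non-reference
  # cohort (b_C, c_C) offsets, coupled through a Schur complement so the
  # near-flat "offset vs mean of modes" direction converges in a few steps
  fused_update <- function(a0, a_C, b0, c0, b_C, c_C, beta, u, Oinv, sig2, sweeps) {
    for (s in seq_len(sweeps)) {
      mp <- model_parts(a0, a_C, b0, c0, b_C, c_C, beta, u)
      agg <- re_normal_eqs(mp$r, mp$j2, mp$j3, idx, N)
      Hinv_g <- matrix(0, N, 3L)        # H^-1 g_u per child
      Hinv_Ct <- array(0, c(N, 3L, 2L)) # H^-1 C' per child
      Mk <- replicate(C, matrix(0, 2L, 2L), simplify = FALSE)
      gk <- replicate(C, numeric(2L), simplify = FALSE)
      for (i in seq_len(N)) {
        JtJ <- matrix(c(agg[i, 9L], agg[i, 1L], agg[i, 2L],
                        agg[i, 1L], agg[i, 3L], agg[i, 4L],
                        agg[i, 2L], agg[i, 4L], agg[i, 5L]), 3L, 3L)
        Jtr <- c(agg[i, 6L], agg[i, 7L], agg[i, 8L])
        H <- JtJ / sig2 + Oinv
        gu <- Jtr / sig2 - c(Oinv %*% u[i, ])
        Hi_g <- solve(H, gu)
        Hinv_g[i, ] <- Hi_g
        k <- coh_child[i]
        if (k > 1L) {
          Ci <- JtJ[2:3, , drop = FALSE] / sig2  # Joff' Ju
          HiCt <- solve(H, t(Ci))
          Hinv_Ct[i, , ] <- HiCt
          Mk[[k]] <- Mk[[k]] + JtJ[2:3, 2:3] / sig2 - Ci %*% HiCt
          gk[[k]] <- gk[[k]] + Jtr[2:3] / sig2 - c(Ci %*% Hi_g)
        }
      }
      d_off <- matrix(0, C, 2L)
      for (k in seq_len(C)[-1L]) {
        d_off[k, ] <- tryCatch(solve(Mk[[k]], gk[[k]]), error = function(e) c(0, 0))
      }
      delta_u <- Hinv_g
      for (i in seq_len(N)) {
        k <- coh_child[i]
        if (k > 1L) delta_u[i, ] <- delta_u[i, ] - c(Hinv_Ct[i, , ] %*% d_off[k, ])
      }
      # joint line search on the penalized objective (offsets carry no prior)
      obj_tot <- function(b_C, c_C, u) {
        sum(child_obj(a0, a_C, b0, c0, b_C, c_C, beta, u, Oinv, sig2))
      }
      o0 <- obj_tot(b_C, c_C, u)
      step <- 1
      repeat {
        b_new <- b_C + d_off[, 1L] * step
        c_new <- c_C + d_off[, 2L] * step
        u_new <- u + delta_u * step
        if (obj_tot(b_new, c_new, u_new) <= o0 + 1e-10 || step < 1 / 64) break
        step <- step / 2
      }
      if (step >= 1 / 64) {
        b_C <- b_C + d_off[, 1L] * step
        c_C <- c_C + d_off[, 2L] * step
        u <- u + delta_u * step
      }
    }
    list(u = u, b_C = b_C, c_C = c_C)
  }

  # Laplace marginal log-likelihood plus per-child curvature pieces
  laplace_pieces <- function(a0, a_C, b0, c0, b_C, c_C, beta, u, Omega, sig2) {
    Oinv <- solve(Omega)
    mp <- model_parts(a0, a_C, b0, c0, b_C, c_C, beta, u)
    agg <- re_normal_eqs(mp$r, mp$j2, mp$j3, idx, N)
    ld_O <- chol_logdet(Omega)
    ll <- 0
    Hinv <- vector("list", N)
    tr_corr <- numeric(N)
    sse <- rowsum(mp$r^2, idx, reorder = FALSE)[, 1L]
    n_i <- agg[, 9L]
    for (i in seq_len(N)) {
      JtJ <- matrix(c(agg[i, 9L], agg[i, 1L], agg[i, 2L],
                      agg[i, 1L], agg[i, 3L], agg[i, 4L],
                      agg[i, 2L], agg[i, 4L], agg[i, 5L]), 3L, 3L)
      H <- JtJ / sig2 + Oinv
      Hi <- solve(H)
      Hinv[[i]] <- Hi
      tr_corr[i] <- sum(JtJ * Hi) # tr(J'J H^-1)
      ll <- ll - 0.5 * chol_logdet(H)
    }
    ll <- ll - 0.5 * sum(n_i) * log(2 * pi * sig2) - sum(sse) / (2 * sig2) -
      0.5 * sum(rowSums((u %*% Oinv) * u)) - 0.5 * N * ld_O
    list(ll = ll, Hinv = Hinv, tr_corr = tr_corr, sse = sse, n_i = n_i)
  }

  floor_spd <- function(M, floor) {
    M <- (M + t(M)) / 2
    e <- eigen(M, symmetric = TRUE)
    e$values <- pmax(e$values, floor)
    e$vectors %*% (e$values * t(e$vectors))
  }

  # --- main loop --------------------------------------------------------------
  ll_old <- -Inf; converged <- FALSE; iter <- 0L
  for (iter in seq_len(ctrl$max_iter)) {
    cs <- curve_step(b0, c0, b_C, c_C, u, beta, lambda,
                     select_gcv = penalized && is.null(ctrl$lambda) &&
                       iter <= ctrl$gcv_freeze)
    a0 <- cs$a0; beta <- cs$beta; a_C <- cs$a_C_new; lambda <- cs$lambda
    b0 <- b0 + cs$db0; c0 <- c0 + cs$dc0

    Oinv <- solve(Omega)
    fu <- fused_update(a0, a_C, b0, c0, b_C, c_C, beta, u, Oinv, sig2, ctrl$re_iter)
    u <- fu$u; b_C <- fu$b_C; c_C <- fu$c_C

    # move cohort means of the modes into the fixed effects (exact centering)
    for (k in seq_len(C)) {
      ii <- coh_child == k
      m <- colMeans(u[ii, , drop = FALSE])
      if (k == 1L) {
        a0 <- a0 + m[1L]; b0 <- b0 + m[2L]; c0 <- c0 + m[3L]
      } else {
        a_C[k] <- a_C[k] + m[1L]
        b_C[k] <- b_C[k] + m[2L]
        c_C[k] <- c_C[k] + m[3L]
      }
      u[ii, ] <- sweep(u[ii, , drop = FALSE], 2L, m)
    }
    # keep cohort offsets relative (reference pinned at zero)
    b0 <- b0 + b_C[1L]; c0 <- c0 + c_C[1L]
    b_C <- b_C - b_C[1L]; c_C <- c_C - c_C[1L]

    lp <- laplace_pieces(a0, a_C, b0, c0, b_C, c_C, beta, u, Omega, sig2)

    # Laplace/EM variance updates
    S <- crossprod(u) / N + Reduce(`+`, lp$Hinv) / N
    Omega <- floor_spd(S, ctrl$omega_floor)
    sig2 <- max((sum(lp$sse) + sum(lp$tr_corr)) / sum(lp$n_i), ctrl$sigma_floor^2)

    if (is.finite(ll_old) &&
        abs(lp$ll - ll_old) / (abs(ll_old) + 1) < ctrl$tol) {
      converged <- TRUE
      ll_old <- lp$ll
      break
    }
    ll_old <- lp$ll
  }
  if (!converged) {
    warning("SITAR fit did not converge in ", ctrl$max_iter,
            " outer iterations (last rel. change above tolerance).")
  }
  lp <- laplace_pieces(a0, a_C, b0, c0, b_C, c_C, beta, u, Omega, sig2)

  child_tbl <- dat |>
    dplyr::group_by(.data$child_id) |>
    dplyr::summarise(cohort = dplyr::first(.data$cohort),
                     first_age = min(.data$age_years),
                     last_age = max(.data$age_years),
                     n_obs = dplyr::n(), .groups = "drop")
  ord <- match(levels(child), child_tbl$child_id)
  child_tbl <- child_tbl[ord, ]

  fit <- structure(list(
    knots = knots, beta = as.numeric(beta), a0 = as.numeric(a0),
    b0 = as.numeric(b0), c0 = as.numeric(c0),
    cohorts = tibble::tibble(cohort = cohorts, a = a_C, b = b_C, c = c_C),
    reference = reference,
    ranef = tibble::tibble(child_id = as.character(child_tbl$child_id),
                           cohort = as.character(child_tbl$cohort),
                           a = u[, 1L], b = u[, 2L], c = u[, 3L],
                           first_age = child_tbl$first_age,
                           last_age = child_tbl$last_age,
                           n_obs = child_tbl$n_obs),
    Omega = Omega, sigma = sqrt(sig2), logLik = lp$ll,
    lambda = if (penalized) lambda else NULL, df = p_df, penalized = penalized,
    age_range = range(t), n_obs = n_obs, n_children = N,
    sex = if ("sex" %in% names(dat)) as.character(dat$sex[1L]) else NA_character_,
    convergence = list(converged = converged, iterations = iter),
    vcov_fixed = NULL
  ), class = "sitar_fit")

  if (compute_vcov && C > 1L) {
    fit$vcov_fixed <- sitar_fixed_vcov(fit, dat)
  }
  fit$data <- dat
  fit
}

# covariance of the cohort fixed effects from the Gauss-Newton/GLS
# information of the linearized mixed model at convergence: fixed effects
# (a0, b0, c0) and per-non-reference-cohort offsets (a_C, b_C, c_C), with
# per-child marginal covariance Z_i Omega Z_i' + sigma^2 I inverted by
# Woodbury.  The global parameters are included so offset SEs marginalize
# over reference-cohort uncertainty; the spline shape is held fixed.
sitar_fixed_vcov <- function(fit, dat) {
  C <- nrow(fit$cohorts)
  dat <- dplyr::arrange(dplyr::as_tibble(dat), .data$child_id, .data$age_years)
  t <- dat$age_years; y <- dat$height_cm
  child <- factor(dat$child_id, levels = unique(dat$child_id))
  idx <- as.integer(child); N <- nlevels(child)
  coh <- match(as.character(dat$cohort), fit$cohorts$cohort)
  mi <- match(levels(child), fit$ranef$child_id)
  u <- as.matrix(fit$ranef[mi, c("a", "b", "c")])
  co <- fit$cohorts
  b_tot <- fit$b0 + co$b[coh] + u[idx, 2L]
  c_tot <- fit$c0 + co$c[coh] + u[idx, 3L]
  theta <- (t - b_tot) * exp(c_tot)
  m1 <- c(ns_basis(theta, fit$knots, 1L) %*% fit$beta)
  j2 <- -exp(c_tot) * m1
  j3 <- theta * m1
  sig2 <- fit$sigma^2
  Oinv <- solve(fit$Omega)

  q <- 3L * C
  nm <- c("(a0)", "(b0)", "(c0)",
          if (C > 1L) as.vector(t(outer(co$cohort[-1L], c("a", "b", "c"),
                                        paste, sep = "."))))
  info <- matrix(0, q, q)
  for (i in seq_len(N)) {
    ii <- which(idx == i)
    Z <- cbind(1, j2[ii], j3[ii])
    k <- coh[ii[1L]]
    Xf <- matrix(0, length(ii), q)
    Xf[, 1:3] <- Z
    if (k > 1L) Xf[, (3 * k - 2):(3 * k)] <- Z
    # V^-1 = (1/sig2) (I - Z (sig2 Oinv + Z'Z)^-1 Z')
    A <- sig2 * Oinv + crossprod(Z)
    ZtX <- crossprod(Z, Xf)
    info <- info + (crossprod(Xf) - crossprod(ZtX, solve(A, ZtX))) / sig2
  }
  V_all <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(V_all) || any(diag(V_all) <= 0)) {
    warning("Fixed-effect information matrix not positive definite; ",
            "cohort contrast SEs unavailable.")
    return(NULL)
  }
  dimnames(V_all) <- list(nm, nm)
  V_all[-(1:3), -(1:3), drop = FALSE]
}

# Laplace marginal log-likelihood of `fit` on a visit table, optionally with
# overridden cohort offsets; random-effect modes are re-optimized.
sitar_marginal_ll <- function(fit, visits, a_C = NULL, b_C = NULL, c_C = NULL) {
  dat <- dplyr::as_tibble(visits) |>
    dplyr::arrange(.data$child_id, .data$age_years)
  if (!"cohort" %in% names(dat)) dat$cohort <- fit$cohorts$cohort[1L]
  t <- dat$age_years; y <- dat$height_cm
  child <- factor(dat$child_id, levels = unique(dat$child_id))
  idx <- as.integer(child); N <- nlevels(child)
  coh <- match(as.character(dat$cohort), fit$cohorts$cohort)
  if (anyNA(coh)) stop("Visits contain cohorts unknown to the fit.")
  coh_obs <- coh
  a_C <- a_C %||% fit$cohorts$a
  b_C <- b_C %||% fit$cohorts$b
  c_C <- c_C %||% fit$cohorts$c
  knots <- fit$knots; beta <- fit$beta; a0 <- fit$a0
  b_C <- b_C + (fit$b0 %||% 0); c_C <- c_C + (fit$c0 %||% 0)
  sig2 <- fit$sigma^2; Omega <- fit$Omega

  zero_omega <- max(abs(Omega)) < 1e-12
  if (zero_omega) {
    theta <- t * exp(c_C[coh_obs]) - b_C[coh_obs] * exp(c_C[coh_obs])
    mu <- a0 + a_C[coh_obs] + c(ns_basis(theta, knots) %*% beta)
    return(sum(stats::dnorm(y, mu, sqrt(sig2), log = TRUE)))
  }

  Oinv <- solve(Omega)
  # warm start from stored modes where children match
  u <- matrix(0, N, 3L)
  mi <- match(levels(child), fit$ranef$child_id)
  ok <- !is.na(mi)
  u[ok, ] <- as.matrix(fit$ranef[mi[ok], c("a", "b", "c")])

  obj_all <- function(u) {
    bt <- b_C[coh_obs] + u[idx, 2L]; ct <- c_C[coh_obs] + u[idx, 3L]
    theta <- (t - bt) * exp(ct)
    mu <- a0 + a_C[coh_obs] + u[idx, 1L] + c(ns_basis(theta, knots) %*% beta)
    sse <- rowsum((y - mu)^2, idx, reorder = FALSE)[, 1L]
    sse / (2 * sig2) + rowSums((u %*% Oinv) * u) / 2
  }
  for (s in 1:25) {
    bt <- b_C[coh_obs] + u[idx, 2L]; ct <- c_C[coh_obs] + u[idx, 3L]
    theta <- (t - bt) * exp(ct); ect <- exp(ct)
    m1 <- c(ns_basis(theta, knots, 1L) %*% beta)
    mu <- a0 + a_C[coh_obs] + u[idx, 1L] + c(ns_basis(theta, knots) %*% beta)
    r <- y - mu; j2 <- -ect * m1; j3 <- theta * m1
    agg <- re_normal_eqs(r, j2, j3, idx, N)
    delta <- matrix(0, N, 3L)
    for (i in seq_len(N)) {
      JtJ <- matrix(c(agg[i, 9L], agg[i, 1L], agg[i, 2L],
                      agg[i, 1L], agg[i, 3L], agg[i, 4L],
                      agg[i, 2L], agg[i, 4L], agg[i, 5L]), 3L, 3L)
      delta[i, ] <- solve(JtJ / sig2 + Oinv,
                          c(agg[i, 6L], agg[i, 7L], agg[i, 8L]) / sig2 - Oinv %*% u[i, ])
    }
    obj0 <- obj_all(u); step <- rep(1, N)
    for (h in 1:4) {
      u_new <- u + delta * step
      bad <- obj_all(u_new) > obj0 + 1e-12
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
    }
    u_new <- u + delta * step
    worse <- obj_all(u_new) > obj0 + 1e-12
    u_new[worse, ] <- u[worse, ]
    moved <- max(abs(u_new - u))
    u <- u_new
    if (moved < 1e-7) break
  }

  bt <- b_C[coh_obs] + u[idx, 2L]; ct <- c_C[coh_obs] + u[idx, 3L]
  theta <- (t - bt) * exp(ct); ect <- exp(ct)
  m1 <- c(ns_basis(theta, knots, 1L) %*% beta)
  mu <- a0 + a_C[coh_obs] + u[idx, 1L] + c(ns_basis(theta, knots) %*% beta)
  r <- y - mu; j2 <- -ect * m1; j3 <- theta * m1
  agg <- re_normal_eqs(r, j2, j3, idx, N)
  ll <- -0.5 * length(y) * log(2 * pi * sig2) - sum(r^2) / (2 * sig2) -
    0.5 * sum(rowSums((u %*% Oinv) * u)) - 0.5 * N * chol_logdet(Omega)
  for (i in seq_len(N)) {
    JtJ <- matrix(c(agg[i, 9L], agg[i, 1L], agg[i, 2L],
                    agg[i, 1L], agg[i, 3L], agg[i, 4L],
                    agg[i, 2L], agg[i, 4L], agg[i, 5L]), 3L, 3L)
    ll <- ll - 0.5 * chol_logdet(JtJ / sig2 + Oinv)
  }
  ll
}

#' Laplace marginal log-likelihood of a SITAR fit on a visit table
#'
#' Re-optimizes the random-effect modes for the supplied visits at the fit's
#' parameter values and returns the Laplace-approximate marginal
#' log-likelihood (the criterion maximized by [fit_sitar()]).  With a zero
#' random-effect covariance this reduces exactly to the sum of independent
#' Gaussian log-densities.
#'
#' @param fit a `sitar_fit`.
#' @param visits a growth visit table (`child_id`, `age_years`, `height_cm`,
#'   optional `cohort`); defaults to the fitting data.
#' @return a scalar log-likelihood.
#' @export
sitar_loglik <- function(fit, visits = NULL) {
  stopifnot(inherits(fit, "sitar_fit"))
  sitar_marginal_ll(fit, visits %||% fit$data)
}

#' Construct a SITAR fit object from known components
#'
#' Mainly for simulation studies and tests: builds a `sitar_fit` directly from
#' a mean curve (knots and spline coefficients), cohort offsets and
#' random-effect values, without estimation.
#'
#' @param knots,beta natural-spline knots and coefficients of the mean curve
#'   (see [ns_basis()]); the curve is `a0 + ns_basis(x, knots) %*% beta`.
#' @param a0 intercept (cm).
#' @param cohorts tibble with columns cohort, a, b, c (first row = reference,
#'   offsets 0); default a single cohort "all".
#' @param ranef tibble with columns child_id, cohort, a, b, c (may be empty).
#' @param Omega,sigma random-effect covariance and residual SD.
#' @param age_range ages (years) over which the curve is considered supported.
#' @return a `sitar_fit` object.
#' @export
new_sitar_fit <- function(knots, beta, a0,
                          cohorts = NULL, ranef = NULL,
                          Omega = diag(3) * 0, sigma = 1,
                          age_range = range(knots)) {
  cohorts <- cohorts %||% tibble::tibble(cohort = "all", a = 0, b = 0, c = 0)
  ranef <- ranef %||% tibble::tibble(child_id = character(), cohort = character(),
                                     a = numeric(), b = numeric(), c = numeric())
  if (!"first_age" %in% names(ranef)) ranef$first_age <- age_range[1L]
  if (!"last_age" %in% names(ranef)) ranef$last_age <- age_range[2L]
  if (!"n_obs" %in% names(ranef)) ranef$n_obs <- NA_integer_
  structure(list(
    knots = knots, beta = beta, a0 = a0, b0 = 0, c0 = 0, cohorts = cohorts,
    reference = cohorts$cohort[1L], ranef = ranef, Omega = Omega,
    sigma = sigma, logLik = NA_real_, lambda = NULL, df = length(beta),
    penalized = FALSE, age_range = age_range, n_obs = NA_integer_,
    n_children = nrow(ranef), sex = NA_character_,
    convergence = list(converged = TRUE, iterations = 0L), vcov_fixed = NULL
  ), class = "sitar_fit")
}

#' Predict heights from a SITAR fit
#'
#' Evaluates the cohort mean curve (random effects zero) or an individual
#' child's curve at the requested ages.
#'
#' @param fit a `sitar_fit`.
#' @param ages numeric vector of ages (years).
#' @param cohort cohort name (default: the reference cohort).
#' @param child_id if given, the individual curve for that child (its cohort
#'   offsets plus its random effects).
#' @return numeric vector of heights (cm).
#' @export
predict_height <- function(fit, ages, cohort = NULL, child_id = NULL) {
  stopifnot(inherits(fit, "sitar_fit"))
  eff <- sitar_effects(fit, cohort, child_id)
  theta <- (ages - eff$b) * exp(eff$c)
  as.numeric(eff$a + fit$a0 + ns_basis(theta, fit$knots) %*% fit$beta)
}

# resolve total (a, b, c) for a cohort or child target
sitar_effects <- function(fit, cohort = NULL, child_id = NULL) {
  if (!is.null(child_id)) {
    row <- fit$ranef[fit$ranef$child_id == child_id, ]
    if (nrow(row) != 1L) stop("Unknown child_id: ", child_id)
    co <- fit$cohorts[fit$cohorts$cohort == row$cohort, ]
    list(a = co$a + row$a, b = (fit$b0 %||% 0) + co$b + row$b,
         c = (fit$c0 %||% 0) + co$c + row$c, cohort = row$cohort)
  } else {
    cohort <- cohort %||% fit$reference
    co <- fit$cohorts[fit$cohorts$cohort == cohort, ]
    if (nrow(co) != 1L) stop("Unknown cohort: ", cohort)
    list(a = co$a, b = (fit$b0 %||% 0) + co$b, c = (fit$c0 %||% 0) + co$c,
         cohort = cohort)
  }
}

#' @export
print.sitar_fit <- function(x, ...) {
  cat(sprintf("<sitar_fit>  %d children, %s obs, %s basis df%s\n",
              x$n_children, x$n_obs, x$df,
              if (x$penalized) sprintf(" (penalized, lambda = %.3g)", x$lambda) else ""))
  cat(sprintf("  residual SD %.3f cm; RE SDs a %.2f cm, b %.2f y, c %.3f\n",
              x$sigma, sqrt(x$Omega[1, 1]), sqrt(x$Omega[2, 2]), sqrt(x$Omega[3, 3])))
  if (nrow(x$cohorts) > 1L) {
    cat("  cohort offsets vs ", x$reference, ":\n", sep = "")
    print(as.data.frame(x$cohorts[-1L, ]), row.names = FALSE)
  }
  cat(sprintf("  Laplace logLik %.2f; converged: %s (%d iterations)\n",
              x$logLik, x$convergence$converged, x$convergence$iterations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sitar_fit <- function(x, ...) {
  out <- x$cohorts |>
    tidyr::pivot_longer(c("a", "b", "c"), names_to = "parameter",
                        values_to = "estimate") |>
    dplyr::mutate(term = paste(.data$cohort, .data$parameter, sep = "."))
  if (!is.null(x$vcov_fixed)) {
    se <- tibble::tibble(term = rownames(x$vcov_fixed),
                         std.error = sqrt(diag(x$vcov_fixed)))
    out <- dplyr::left_join(out, se, by = "term")
  } else {
    out$std.error <- NA_real_
  }
  dplyr::select(out, "term", "cohort", "parameter", "estimate", "std.error")
}

#' @export
glance.sitar_fit <- function(x, ...) {
  tibble::tibble(
    n_children = x$n_children, n_obs = x$n_obs, sigma = x$sigma,
    logLik = x$logLik, df = x$df, penalized = x$penalized,
    converged = x$convergence$converged,
    omega_a = sqrt(x$Omega[1, 1]), omega_b = sqrt(x$Omega[2, 2]),
    omega_c = sqrt(x$Omega[3, 3])
  )
}
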