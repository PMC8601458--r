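#' Out-of-fold onset predictions by k-fold cross-validation
#'
#' Children are partitioned into `k` seeded folds; each child's predicted
#' onset comes from the model fitted without their fold, so predictions are
#' always out of sample.  With `spec = "lasso"` the variable selection is
#' re-run inside every training fold (no selection leakage); the leaky
#' variant (select once on all data, then cross-validate the fixed model) is
#' available with `selection = "once"` for comparison.
#'
#' @param data tibble with `child_id`, `left`, `right`, `censor_type` and
#'   covariate columns.
#' @param spec an [onset_model_spec()] or `"lasso"`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold draw.
#' @param selection "per_fold" (default) or "once"; only relevant for
#'   `spec = "lasso"`.
#' @param lasso_args list of extra arguments for [lasso_select()].
#' @return tibble `child_id`, `fold`, `.pred`, plus attribute `sigma` (mean
#'   fitted residual SD across folds) and `folds`.
#' @export
kfold_predict <- function(data, spec = "simple", k = 10L, seed = 1L,
                          selection = c("per_fold", "once"),
                          lasso_args = list()) {
  selection <- match.arg(selection)
  data <- dplyr::as_tibble(data)
  stopifnot("child_id" %in% names(data), k >= 2L)
  if (anyDuplicated(data$child_id)) stop("One row per child expected.")
  n <- nrow(data)
  if (n < k) stop("Fewer children than folds.")
  folds <- withr::with_seed(as.integer(seed), sample(rep_len(seq_len(k), n)))

  is_lasso <- identical(spec, "lasso")
  if (is_lasso && selection == "once") {
    sel <- do.call(lasso_select, c(list(data = data, seed = seed), lasso_args))
    spec <- sel$selected
    is_lasso <- FALSE
  }

  out <- vector("list", k)
  sigmas <- numeric(k)
  for (fd in seq_len(k)) {
    tr <- data[folds != fd, ]
    te <- data[folds == fd, ]
    if (!any(tr$censor_type == "interval")) {
      stop("Fold ", fd, " leaves a training set without interval-censored ",
           "children; cannot refit.")
    }
    fit <- if (is_lasso) {
      do.call(lasso_select, c(list(data = tr, seed = seed), lasso_args))$fit
    } else {
      fit_aft(tr, spec)
    }
    pr <- predict_onset(fit, te, levels = numeric(0))
    out[[fd]] <- tibble::tibble(child_id = te$child_id, fold = fd,
                                .pred = pr$.pred)
    sigmas[fd] <- fit$sigma
  }
  res <- dplyr::bind_rows(out)
  attr(res, "sigma") <- mean(sigmas)
  attr(res, "folds") <- folds
  res
}

#' Interval-overlap agreement between observed and predicted onsets
#'
#' Each interval-censored child with an observed interval shorter than
#' `max_length` (1.5 years) is evaluated: the observed interval
#' \eqn{(L, R]} is compared with a one-year window centred on the predicted
#' onset, \eqn{[p - 0.5, p + 0.5]}, and counted as an agreement when the two
#' intervals overlap, i.e. \eqn{\max(L, p - 0.5) \le \min(R, p + 0.5)}
#' (touching endpoints count).  Right- and left-censored children are
#' excluded with counts.
#'
#' @param intervals onset interval tibble (`child_id`, `left`, `right`,
#'   `censor_type`).
#' @param predictions tibble with `child_id` and `.pred` (e.g. from
#'   [kfold_predict()]).
#' @param half_width half-width of the prediction window (years).
#' @param max_length exclusion threshold on the observed interval length.
#' @return object of class `pubgrowth_agreement`: counts, `agreement_pct`
#'   and a per-child `details` tibble.
#' @export
agreement <- function(intervals, predictions, half_width = 0.5,
                      max_length = 1.5) {
  d <- dplyr::inner_join(
    dplyr::as_tibble(intervals),
    dplyr::select(dplyr::as_tibble(predictions), "child_id", ".pred"),
    by = "child_id"
  )
  miss <- setdiff(intervals$child_id[intervals$censor_type == "interval"],
                  predictions$child_id)
  if (length(miss)) {
    stop("Missing predictions for interval-censored children: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  n_uncensorable <- sum(d$censor_type != "interval")
  iv <- d[d$censor_type == "interval", ]
  len <- iv$right - iv$left
  keep <- len < max_length
  ev <- iv[keep, ]
  overlap <- pmax(ev$left, ev$.pred - half_width) <=
    pmin(ev$right, ev$.pred + half_width)
  details <- tibble::tibble(
    child_id = ev$child_id, left = ev$left, right = ev$right,
    .pred = ev$.pred,
    pred_lo = ev$.pred - half_width, pred_hi = ev$.pred + half_width,
    agree = overlap
  )
  structure(list(
    n_evaluated = nrow(ev),
    n_excluded_by_length = sum(!keep),
    n_uncensorable = n_uncensorable,
    n_agreements = sum(overlap),
    agreement_pct = if (nrow(ev)) 100 * sum(overlap) / nrow(ev) else NA_real_,
    half_width = half_width, max_length = max_length,
    details = details
  ), class = "pubgrowth_agreement")
}

#' @export
print.pubgrowth_agreement <- function(x, ...) {
  cat(sprintf(
    "<pubgrowth_agreement>  %d evaluated (%d excluded: interval >= %.1f y; %d not interval-censored)\n",
    x$n_evaluated, x$n_excluded_by_length, x$max_length, x$n_uncensorable
  ))
  cat(sprintf("  agreements: %d (%.1f%%)\n", x$n_agreements, x$agreement_pct))
  invisible(x)
}

#' Compare onset-model specifications under identical folds
#'
#' Runs [kfold_predict()] for each specification with the same seed (hence
#' identical folds, a paired comparison) and tabulates the CV agreement next
#' to the full-data coefficient estimates.
#'
#' @param data as in [kfold_predict()].
#' @param specs named list of specifications (term vectors, preset names, or
#'   `"lasso"`).
#' @param k,seed folds and seed shared across specifications.
#' @param ... passed on to [kfold_predict()].
#' @return list with `summary` (one row per spec: agreement, counts, sigma)
#'   and `coefficients` (tidy table of full-data fits, S1-Table style).
#' @export
compare_models <- function(data, specs, k = 10L, seed = 1L, ...) {
  stopifnot(length(specs) >= 1L)
  if (is.null(names(specs))) names(specs) <- vapply(specs, function(s)
    paste(unlist(s), collapse = "+"), character(1))
  rows <- list(); coefs <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    pr <- kfold_predict(data, sp, k = k, seed = seed, ...)
    ag <- agreement(data, pr)
    rows[[nm]] <- tibble::tibble(
      model = nm, n_evaluated = ag$n_evaluated,
      agreement_pct = ag$agreement_pct,
      cv_sigma = attr(pr, "sigma")
    )
    full <- if (identical(sp, "lasso")) {
      lasso_select(data, seed = seed)$fit
    } else {
      fit_aft(data, sp)
    }
    coefs[[nm]] <- dplyr::mutate(tidy(full), model = nm, .before = 1L)
  }
  list(summary = dplyr::bind_rows(rows),
       coefficients = dplyr::bind_rows(coefs))
}

#' Plot observed onset intervals against predicted onsets
#'
#' The usual presentation of cross-validated onset predictions: one vertical
#' segment per child (the observed censoring interval) at its predicted
#' onset age, the identity line, and optional central normal prediction
#' bands at 50/75/95% computed from `sigma`.
#'
#' @param object a `pubgrowth_agreement`.
#' @param sigma residual SD used for the prediction bands (e.g.
#'   `attr(kfold_predict(...), "sigma")`); omit for no bands.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pubgrowth_agreement <- function(object, sigma = NULL, ...) {
  d <- object$details
  rng <- range(c(d$.pred, d$left, d$right), finite = TRUE)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$.pred))
  if (!is.null(sigma)) {
    grid <- tibble::tibble(x = seq(rng[1L] - 0.5, rng[2L] + 0.5, length.out = 50))
    for (lev in c(0.95, 0.75, 0.5)) {
      z <- z_level(lev)
      p <- p + ggplot2::geom_ribbon(
        data = grid,
        ggplot2::aes(x = .data$x, ymin = .data$x - z * sigma,
                     ymax = .data$x + z * sigma),
        inherit.aes = FALSE, fill = "grey70", alpha = 0.35
      )
    }
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$.pred, y = .data$left, yend = .data$right,
                   colour = .data$agree), linewidth = 0.4
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f02"),
                                 name = "overlap") +
    ggplot2::labs(x = "predicted onset age (years)",
                  y = "observed onset interval (years)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cohort growth and velocity curves from a SITAR fit
#'
#' Two panels: the fitted cohort mean height curves and the corresponding
#' analytic velocity curves over the fitted age range.
#'
#' @param object a `sitar_fit`.
#' @param ... unused.
#' @return a ggplot object (patchwork-free single plot, faceted).
#' @export
autoplot.sitar_fit <- function(object, ...) {
  ages <- seq(object$age_range[1L], object$age_range[2L], length.out = 200)
  d <- purrr::map_dfr(object$cohorts$cohort, function(ch) {
    tibble::tibble(
      cohort = ch, age = ages,
      height = predict_height(object, ages, cohort = ch),
      velocity = velocity_curve(object, ages, cohort = ch)
    )
  }) |>
    tidyr::pivot_longer(c("height", "velocity"), names_to = "panel")
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$value, colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = NULL) +
    ggplot2::theme_minimal()
}
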