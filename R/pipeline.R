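#' Read and validate a growth or pubertal visit CSV
#'
#' Growth files need `child_id`, `age_years`, `height_cm` (optional `sex`,
#' `cohort`, `bmi`, `weight_kg`); pubertal files need `child_id`,
#' `age_years` and at least one of `tanner_breast`, `testis_len_mm`.  Rows
#' with missing or non-positive ages are dropped and reported; duplicated
#' (child, age) height rows are averaged with a warning.
#'
#' @param path CSV file path.
#' @param kind "growth" or "pubertal".
#' @return a typed, sorted tibble; attribute `validation` lists dropped-row
#'   counts.
#' @export
read_visits <- function(path, kind = c("growth", "pubertal")) {
  kind <- match.arg(kind)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               col_types = readr::cols()))
  chr_cols <- intersect(c("child_id", "sex", "cohort"), hdr)
  types <- do.call(readr::cols, c(
    stats::setNames(rep(list(readr::col_character()), length(chr_cols)),
                    chr_cols),
    list(.default = readr::col_double())
  ))
  dat <- readr::read_csv(path, col_types = types, show_col_types = FALSE)
  need <- if (kind == "growth") c("child_id", "age_years", "height_cm")
  else c("child_id", "age_years")
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop("Missing required column(s): ", paste(miss, collapse = ", "))
  if (kind == "pubertal" &&
      !any(c("tanner_breast", "testis_len_mm") %in% names(dat))) {
    stop("Pubertal file needs `tanner_breast` and/or `testis_len_mm`.")
  }
  n0 <- nrow(dat)
  dat <- dplyr::filter(dat, !is.na(.data$age_years), .data$age_years > 0)
  n_bad_age <- n0 - nrow(dat)
  n_dup <- 0L
  if (kind == "growth") {
    dat <- dplyr::filter(dat, !is.na(.data$height_cm))
    dup <- dat |>
      dplyr::count(.data$child_id, .data$age_years) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(dup)) {
      n_dup <- sum(dup$n) - nrow(dup)
      warning(n_dup, " duplicated (child, age) height rows averaged.")
      keys <- intersect(c("child_id", "sex", "cohort", "age_years"), names(dat))
      dat <- dat |>
        dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
        dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                         .groups = "drop")
    }
  }
  dat <- dplyr::arrange(dat, .data$child_id, .data$age_years)
  attr(dat, "validation") <- list(rows_in = n0, rows_dropped_age = n_bad_age,
                                  rows_averaged = n_dup)
  dat
}

#' Configuration for a full pipeline run
#'
#' @param sex "F" or "M" — the pipeline mirrors fully sex-stratified
#'   analyses, one sex per run.
#' @param out_dir output directory for all artifacts.
#' @param growth,pubertal input CSV paths or tibbles; ignored when
#'   `simulate` is given.
#' @param simulate optional [sim_config()]; the run then starts by
#'   simulating its own data (written alongside the other artifacts).
#' @param iso_bmi_reference reference CSV path or tibble; default is the
#'   package's synthetic reference.
#' @param reference reference cohort for the SITAR fixed effects (default:
#'   first alphabetically; ignored if absent from the data).
#' @param df SITAR spline setting (see [fit_sitar()]).
#' @param bmi_degree polynomial degree of the BMI trajectory model.
#' @param model "simple", "extended" (preset by sex) or "lasso".
#' @param k,seed cross-validation folds and seed.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(sex, out_dir, growth = NULL, pubertal = NULL,
                       simulate = NULL, iso_bmi_reference = NULL,
                       reference = NULL, df = NULL, bmi_degree = 3L,
                       model = c("extended", "simple", "lasso"),
                       k = 10L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(sex %in% c("F", "M"))
  if (is.null(simulate)) {
    for (p in list(growth, pubertal)) {
      if (is.character(p) && !file.exists(p)) stop("Input file not found: ", p)
    }
    if (is.null(growth) || is.null(pubertal)) {
      stop("Provide `growth` and `pubertal` inputs, or a `simulate` config.")
    }
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  structure(list(
    sex = sex, out_dir = out_dir, growth = growth, pubertal = pubertal,
    simulate = simulate, iso_bmi_reference = iso_bmi_reference,
    reference = reference, df = df, bmi_degree = bmi_degree, model = model,
    k = as.integer(k), seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full two-stage pubertal-onset pipeline
#'
#' Mirrors the two-stage workflow: stage 1 fits the SITAR growth model to
#' all cohorts of one sex and derives per-child growth markers and cohort
#' contrasts; stage 2 builds censoring intervals from the pubertal
#' follow-up, classifies overweight at growth-spurt takeoff, applies the
#' inclusion criteria, fits the simple and configured onset models, and
#' evaluates them by seeded 10-fold cross-validated interval-overlap
#' agreement.  All artifacts (CSV/JSON tables, a manifest, and a markdown
#' report) are written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return an object of class `pubgrowth_run` (invisible list of all stage
#'   results plus the output directory).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- data -------------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_cohort(config$simulate))
    write_sim(sim, file.path(config$out_dir, "data"))
    growth <- sim$growth; pubertal <- sim$pubertal
  } else {
    sim <- NULL
    growth <- stage("read", if (is.character(config$growth))
      read_visits(config$growth, "growth") else dplyr::as_tibble(config$growth))
    pubertal <- stage("read", if (is.character(config$pubertal))
      read_visits(config$pubertal, "pubertal") else dplyr::as_tibble(config$pubertal))
  }
  ref <- stage("reference", {
    r <- config$iso_bmi_reference
    if (is.null(r)) synthetic_iso_bmi_reference()
    else if (is.character(r)) read_iso_bmi_reference(r)
    else dplyr::as_tibble(r)
  })
  sx <- config$sex
  growth_s <- dplyr::filter(growth, .data$sex == sx)
  pubertal_s <- dplyr::filter(pubertal, .data$sex == sx)
  if (!nrow(growth_s)) stop("No growth rows for sex ", sx)

  # --- stage 1: growth --------------------------------------------------------
  window <- c(7, 19)
  growth_w <- dplyr::filter(growth_s, .data$age_years >= window[1L],
                            .data$age_years <= window[2L])
  ref_coh <- config$reference
  if (!is.null(ref_coh) && !ref_coh %in% growth_w$cohort) ref_coh <- NULL
  fit <- stage("sitar",
               fit_sitar(growth_w, df = config$df, reference = ref_coh))
  markers <- stage("markers", growth_markers(fit))
  contrasts <- stage("contrasts", cohort_contrasts(fit))

  # --- stage 2: onset ---------------------------------------------------------
  intervals <- stage("intervals", onset_intervals(pubertal_s))
  bmi_fit <- stage("bmi", {
    bmi_dat <- dplyr::filter(growth_s, !is.na(.data$bmi))
    if (nrow(bmi_dat) > 50) fit_bmi_trajectory(bmi_dat, config$bmi_degree) else NULL
  })
  markers_ow <- if (!is.null(bmi_fit)) {
    stage("overweight", overweight_at_takeoff(markers, bmi_fit, sx, ref))
  } else {
    dplyr::mutate(markers, bmi_at_takeoff = NA_real_, overweight = NA)
  }
  incl <- stage("inclusion",
                apply_inclusion_criteria(growth_s, intervals, markers))
  d2 <- stage("join", {
    dplyr::inner_join(incl$eligible, markers_ow, by = "child_id") |>
      dplyr::filter(!is.na(.data$overweight) | config$model == "simple")
  })
  onset_summary <- stage("onset_summary", {
    ok <- d2 |> dplyr::count(.data$cohort) |> dplyr::filter(.data$n >= 10L)
    if (nrow(ok)) summarize_onset(dplyr::filter(d2, .data$cohort %in% ok$cohort),
                                  "cohort") else tibble::tibble()
  })

  specs <- list(simple = onset_model_spec("simple"))
  if (config$model == "extended") {
    specs$extended <- onset_model_spec(
      if (sx == "F") "extended_girls" else "extended_boys"
    )
  } else if (config$model == "lasso") {
    specs$lasso <- "lasso"
  }
  cmp <- stage("evaluate", compare_models(d2, specs, k = config$k,
                                          seed = config$seed))
  preds <- stage("predict", {
    pr <- kfold_predict(d2, specs[[length(specs)]], k = config$k,
                        seed = config$seed)
    dplyr::bind_cols(pr, predict_onset(
      fit_aft(d2, if (identical(specs[[length(specs)]], "lasso"))
        lasso_select(d2, seed = config$seed)$selected
        else specs[[length(specs)]]),
      d2[match(pr$child_id, d2$child_id), ]
    )[, -1L])
  })
  ag <- stage("agreement", agreement(d2, preds))

  # --- artifacts --------------------------------------------------------------
  out <- config$out_dir
  readr::write_csv(markers_ow, file.path(out, "markers.csv"))
  readr::write_csv(intervals, file.path(out, "intervals.csv"))
  readr::write_csv(preds, file.path(out, "predictions.csv"))
  readr::write_csv(ag$details, file.path(out, "agreement_children.csv"))
  if (nrow(onset_summary)) {
    readr::write_csv(onset_summary, file.path(out, "onset_summary.csv"))
  }
  readr::write_csv(contrasts$by_cohort, file.path(out, "contrasts_by_cohort.csv"))
  if (nrow(contrasts$pairs)) {
    readr::write_csv(contrasts$pairs, file.path(out, "contrasts_pairs.csv"))
    readr::write_csv(contrasts$overall, file.path(out, "contrasts_overall.csv"))
  }
  plot_ok <- tryCatch({
    p <- autoplot(ag, sigma = attr(preds, "sigma"))
    grDevices::svg(file.path(out, "agreement_plot.svg"), width = 7, height = 5)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) FALSE)
  jsonlite::write_json(list(
    exclusion = incl$report,
    agreement = list(
      n_evaluated = ag$n_evaluated, n_agreements = ag$n_agreements,
      n_excluded_by_length = ag$n_excluded_by_length,
      n_uncensorable = ag$n_uncensorable, agreement_pct = ag$agreement_pct
    ),
    models = cmp$summary
  ), file.path(out, "results.json"), auto_unbox = TRUE, digits = NA)
  write_sitar_json(fit, file.path(out, "sitar_fit.json"))
  readr::write_csv(cmp$coefficients, file.path(out, "model_coefficients.csv"))
  manifest <- list(
    package = "pubgrowth",
    version = as.character(utils::packageVersion("pubgrowth")),
    r_version = R.version.string,
    sex = sx, seed = config$seed, k = config$k, model = config$model,
    simulated = !is.null(config$simulate),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = list.files(out, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  write_report(out)

  res <- structure(list(
    dir = out, sitar = fit, markers = markers_ow, contrasts = contrasts,
    intervals = intervals, inclusion = incl$report,
    onset_summary = onset_summary, models = cmp, predictions = preds,
    agreement = ag, sim = sim, config = config
  ), class = "pubgrowth_run")
  invisible(res)
}

#' @export
print.pubgrowth_run <- function(x, ...) {
  cat(sprintf("<pubgrowth_run>  sex %s, %d eligible children, agreement %.1f%%\n",
              x$config$sex, x$agreement$n_evaluated + x$agreement$n_excluded_by_length +
                x$agreement$n_uncensorable, x$agreement$agreement_pct))
  cat("  artifacts in:", x$dir, "\n")
  invisible(x)
}

# serialize the mean curve and effects of a sitar_fit to JSON (reloadable)
write_sitar_json <- function(fit, path) {
  jsonlite::write_json(list(
    knots = fit$knots, beta = fit$beta, a0 = fit$a0, b0 = fit$b0, c0 = fit$c0,
    cohorts = fit$cohorts, reference = fit$reference,
    Omega = fit$Omega, sigma = fit$sigma, logLik = fit$logLik,
    df = fit$df, penalized = fit$penalized, age_range = fit$age_range,
    ranef = fit$ranef
  ), path, digits = NA, auto_unbox = TRUE)
}

#' Re-create a `sitar_fit` from its JSON serialization
#' @param path path written by [run_full_pipeline()] (`sitar_fit.json`).
#' @return a `sitar_fit` usable with [predict_height()], [growth_markers()].
#' @export
read_sitar_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- new_sitar_fit(
    knots = j$knots, beta = j$beta, a0 = j$a0,
    cohorts = tibble::as_tibble(j$cohorts),
    ranef = tibble::as_tibble(j$ranef),
    Omega = matrix(unlist(j$Omega), 3, 3), sigma = j$sigma,
    age_range = j$age_range
  )
  fit$b0 <- j$b0; fit$c0 <- j$c0
  fit$logLik <- j$logLik; fit$df <- j$df; fit$penalized <- j$penalized
  fit
}

#' Render a markdown report from stored pipeline artifacts
#'
#' Reads only the files written by [run_full_pipeline()] (no recomputation)
#' and renders `report.md`: cohort contrasts, onset-model coefficients,
#' onset summaries and the cross-validated agreement.
#'
#' @param run_dir a pipeline output directory containing `manifest.json`.
#' @return the report path, invisibly.
#' @export
write_report <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  res_path <- file.path(run_dir, "results.json")
  if (!file.exists(res_path)) stop("Missing artifact: results.json")
  res <- jsonlite::read_json(res_path, simplifyVector = TRUE)
  man <- if (file.exists(man_path)) jsonlite::read_json(man_path) else NULL

  md_table <- function(df, digits = 3) {
    if (!nrow(df)) return("(empty)")
    fmt <- function(v) if (is.numeric(v)) formatC(v, digits = digits, format = "g") else as.character(v)
    body <- apply(as.data.frame(lapply(df, fmt)), 1L, paste, collapse = " | ")
    paste(c(paste(names(df), collapse = " | "),
            paste(rep("---", ncol(df)), collapse = " | "),
            body), collapse = "\n")
  }
  read_if <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else tibble::tibble()
  }

  lines <- c(
    "# Pubertal onset pipeline report", "",
    if (!is.null(man)) sprintf("Sex %s; seed %s; %s-fold CV; model `%s`; generated %s.",
                               man$sex, man$seed, man$k, man$model, man$created), "",
    "## Growth-marker summaries by cohort", "",
    md_table(read_if("contrasts_by_cohort.csv")), "",
    "## Cohort contrasts (delta-method 95% CI, Wald tests)", "",
    md_table(read_if("contrasts_pairs.csv")), "",
    "## Onset summaries (interval-censored intercept-only models)", "",
    md_table(read_if("onset_summary.csv")), "",
    "## Onset model coefficients", "",
    md_table(read_if("model_coefficients.csv")), "",
    "## Cross-validated agreement", "",
    md_table(tibble::as_tibble(res$models)), "",
    sprintf("Final model agreement: %.1f%% (%d of %d evaluated; %d excluded by the < %s y interval-length filter).",
            res$agreement$agreement_pct, res$agreement$n_agreements,
            res$agreement$n_evaluated, res$agreement$n_excluded_by_length, "1.5"), ""
  )
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
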