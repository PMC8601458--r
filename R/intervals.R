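empty_intervals <- function() {
  tibble::tibble(child_id = character(), left = double(), right = double(),
                 censor_type = character(), interval_length = double())
}

#' Pubertal-onset censoring intervals from Tanner breast stages
#'
#' For each girl the onset of puberty is bracketed between the last visit at
#' breast stage B1 and the first visit at stage B2 or beyond; missing stages
#' are skipped, so a girl observed B1 then (after a gap) B3 gets the interval
#' from the last B1 to that first post-B1 stage.  Girls observed only at B1
#' are right-censored at their last staged visit; girls already at stage 2
#' or beyond at the first staged visit are left-censored there (left bound
#' 0, since onset age is positive).  Intervals are left-open/right-closed;
#' under the continuous-time onset model the open/closed convention does not
#' affect the likelihood.
#'
#' A decreasing stage sequence triggers a warning and the last-B1/first->=2
#' rule is applied verbatim; in the degenerate case where that yields an
#' empty interval, the last B1 *before* the first post-B1 stage is used.
#'
#' @param visits pubertal visit table with columns `child_id`, `age_years`,
#'   `tanner_breast` (1-5 or NA).
#' @return a tibble: `child_id`, `left`, `right`, `censor_type`
#'   ("interval", "right", "left"), `interval_length`.  Children with no
#'   usable stages are dropped; their ids are in attribute `dropped`.
#' @export
intervals_from_tanner_breast <- function(visits) {
  stopifnot(all(c("child_id", "age_years", "tanner_breast") %in% names(visits)))
  dat <- dplyr::as_tibble(visits) |>
    dplyr::filter(!is.na(.data$tanner_breast)) |>
    dplyr::arrange(.data$child_id, .data$age_years)
  if (nrow(dat) && any(dat$tanner_breast < 1 | dat$tanner_breast > 5)) {
    stop("Tanner breast stages must be in 1..5.")
  }
  all_ids <- unique(visits$child_id)
  dropped <- setdiff(all_ids, unique(dat$child_id))
  if (length(dropped)) {
    message(length(dropped), " girls without usable Tanner stages dropped.")
  }
  if (!nrow(dat)) {
    out <- empty_intervals()
    attr(out, "dropped") <- dropped
    return(out)
  }
  non_mono <- character(0)
  out <- dat |>
    dplyr::group_by(.data$child_id) |>
    dplyr::group_map(function(g, key) {
      st <- g$tanner_breast; ag <- g$age_years
      if (any(diff(st) < 0)) non_mono <<- c(non_mono, key$child_id)
      post <- which(st >= 2)
      pre <- which(st == 1)
      if (!length(post)) {
        return(tibble::tibble(child_id = key$child_id,
                              left = ag[max(pre)], right = Inf,
                              censor_type = "right"))
      }
      first_post <- min(post)
      if (!length(pre)) {
        return(tibble::tibble(child_id = key$child_id,
                              left = 0, right = ag[first_post],
                              censor_type = "left"))
      }
      last_b1 <- max(pre)
      if (ag[last_b1] >= ag[first_post]) {
        pre_before <- pre[pre < first_post]
        if (!length(pre_before)) {
          return(tibble::tibble(child_id = key$child_id,
                                left = 0, right = ag[first_post],
                                censor_type = "left"))
        }
        last_b1 <- max(pre_before)
      }
      tibble::tibble(child_id = key$child_id,
                     left = ag[last_b1], right = ag[first_post],
                     censor_type = "interval")
    }) |>
    dplyr::bind_rows()
  if (length(non_mono)) {
    warning(length(non_mono), " girls with decreasing Tanner stage sequences; ",
            "last-B1/first->=B2 rule applied as stated.")
  }
  out$interval_length <- out$right - out$left
  attr(out, "dropped") <- dropped
  out
}

#' Pubertal-onset censoring intervals from testis length
#'
#' A boy's pubertal onset is confirmed at the first visit `v` where the
#' (larger) testis length is at least 25 mm at `v` *and* at the following
#' visit; the onset is interval-censored between the last visit before `v`
#' with length below 25 mm and visit `v`.  Transient crossings that are not
#' confirmed at the next visit are ignored.  Boys who never meet the
#' two-successive-visit rule are right-censored at their last measured
#' visit — including the edge case of a single unconfirmed >= 25 mm
#' measurement at the final visit, which is counted in attribute
#' `unconfirmed`.  Boys who qualify from their first visit are
#' left-censored.
#'
#' @param visits pubertal visit table with columns `child_id`, `age_years`,
#'   `testis_len_mm` (if `testis_left_mm`/`testis_right_mm` are present the
#'   per-visit maximum is used).
#' @param threshold_mm onset threshold, 25 mm by default (20 mm reproduces
#'   the legacy definition for sensitivity analyses).
#' @return tibble as in [intervals_from_tanner_breast()].
#' @export
intervals_from_testis_length <- function(visits, threshold_mm = 25) {
  dat <- dplyr::as_tibble(visits)
  if (all(c("testis_left_mm", "testis_right_mm") %in% names(dat))) {
    dat$testis_len_mm <- pmax(dat$testis_left_mm, dat$testis_right_mm, na.rm = TRUE)
  }
  stopifnot(all(c("child_id", "age_years", "testis_len_mm") %in% names(dat)))
  dat <- dat |>
    dplyr::filter(!is.na(.data$testis_len_mm)) |>
    dplyr::arrange(.data$child_id, .data$age_years)
  all_ids <- unique(visits$child_id)
  dropped <- setdiff(all_ids, unique(dat$child_id))
  if (length(dropped)) {
    message(length(dropped), " boys without testis measurements dropped.")
  }
  if (!nrow(dat)) {
    out <- empty_intervals()
    attr(out, "dropped") <- dropped
    attr(out, "unconfirmed") <- character(0)
    return(out)
  }
  unconfirmed <- character(0)
  out <- dat |>
    dplyr::group_by(.data$child_id) |>
    dplyr::group_map(function(g, key) {
      len <- g$testis_len_mm; ag <- g$age_years
      n <- length(len)
      qual <- which(len >= threshold_mm &
                      c(len[-1L] >= threshold_mm, FALSE))
      if (!length(qual)) {
        if (len[n] >= threshold_mm) unconfirmed <<- c(unconfirmed, key$child_id)
        return(tibble::tibble(child_id = key$child_id,
                              left = ag[n], right = Inf,
                              censor_type = "right"))
      }
      v <- min(qual)
      below_before <- which(len < threshold_mm & seq_len(n) < v)
      if (v == 1L || !length(below_before)) {
        return(tibble::tibble(child_id = key$child_id,
                              left = 0, right = ag[v],
                              censor_type = "left"))
      }
      tibble::tibble(child_id = key$child_id,
                     left = ag[max(below_before)], right = ag[v],
                     censor_type = "interval")
    }) |>
    dplyr::bind_rows()
  out$interval_length <- out$right - out$left
  attr(out, "dropped") <- dropped
  attr(out, "unconfirmed") <- unconfirmed
  out
}

#' Censoring intervals for a mixed-sex pubertal visit table
#'
#' Dispatches each child to the Tanner-breast rule (girls) or the
#' testis-length rule (boys), using the `sex` column if present and
#' otherwise inferring the sex from which marker is recorded.
#'
#' @param visits pubertal visit table.
#' @param threshold_mm testis-length threshold passed to the boys' rule.
#' @return tibble of onset intervals with a `sex` column.
#' @export
onset_intervals <- function(visits, threshold_mm = 25) {
  dat <- dplyr::as_tibble(visits)
  if (!"sex" %in% names(dat)) {
    sex_tbl <- dat |>
      dplyr::group_by(.data$child_id) |>
      dplyr::summarise(sex = ifelse(any(!is.na(.data$tanner_breast)), "F", "M"),
                       .groups = "drop")
    dat <- dplyr::left_join(dat, sex_tbl, by = "child_id")
  }
  girls <- dplyr::filter(dat, .data$sex == "F")
  boys <- dplyr::filter(dat, .data$sex == "M")
  parts <- list()
  if (nrow(girls)) {
    gi <- intervals_from_tanner_breast(girls)
    if (nrow(gi)) gi$sex <- "F"
    parts <- c(parts, list(gi))
  }
  if (nrow(boys)) {
    bi <- intervals_from_testis_length(boys, threshold_mm)
    if (nrow(bi)) bi$sex <- "M"
    parts <- c(parts, list(bi))
  }
  dplyr::bind_rows(parts)
}

#' Apply the stage-2 inclusion criteria
#'
#' Growth rows are restricted to the 7-19-year window; eligibility for the
#' onset model requires at least `min_heights` height measurements inside
#' the window, a defined onset interval, and (if marker flags are supplied)
#' no boundary-flagged growth markers.  An exclusion report mirrors the
#' usual cohort-flow layout: counts by exclusion reason and by censor type.
#'
#' @param growth growth visit table (`child_id`, `age_years`, ...).
#' @param intervals onset interval table from [onset_intervals()].
#' @param markers optional [growth_markers()] tibble; children with
#'   `aphv_boundary` or `takeoff_boundary` flags are excluded.
#' @param age_window numeric length-2, years.
#' @param min_heights minimum height measurements within the window.
#' @return list with `growth` (window-filtered rows), `eligible` (interval
#'   rows of eligible children) and `report` (named list of counts).
#' @export
apply_inclusion_criteria <- function(growth, intervals, markers = NULL,
                                     age_window = c(7, 19), min_heights = 4L) {
  growth_w <- dplyr::filter(
    dplyr::as_tibble(growth),
    .data$age_years >= age_window[1L], .data$age_years <= age_window[2L]
  )
  counts <- growth_w |> dplyr::count(.data$child_id, name = "n_heights")
  ids <- unique(intervals$child_id)
  n_h <- counts$n_heights[match(ids, counts$child_id)]
  n_h[is.na(n_h)] <- 0L
  enough <- n_h >= min_heights
  flagged <- rep(FALSE, length(ids))
  if (!is.null(markers)) {
    mrow <- match(ids, markers$child_id)
    flagged <- !is.na(mrow) &
      (markers$aphv_boundary[mrow] %in% TRUE |
         markers$takeoff_boundary[mrow] %in% TRUE)
  }
  eligible_ids <- ids[enough & !flagged]
  eligible <- dplyr::filter(intervals, .data$child_id %in% eligible_ids)
  report <- list(
    n_with_interval = length(ids),
    n_excluded_few_heights = sum(!enough),
    n_excluded_marker_flags = sum(enough & flagged),
    n_eligible = nrow(eligible),
    by_censor_type = as.list(table(eligible$censor_type)),
    min_heights = min_heights, age_window = age_window
  )
  list(growth = growth_w, eligible = eligible, report = report)
}
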