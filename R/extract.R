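#' Detect sustained-inactivity periods in an arm-angle trace
#'
#' Implements the standard wrist-actigraphy heuristic for potential sleep:
#' maximal runs of consecutive 5 s epochs whose absolute epoch-to-epoch angle
#' change stays within `angle_threshold` degrees, kept only when the run
#' lasts at least `min_duration` minutes. Runs are broken exactly at
#' transitions exceeding the threshold, so the output intervals are disjoint
#' and sorted. The detector only looks at successive differences, so it is
#' invariant to adding a constant to all angles.
#'
#' @param series Data frame with columns `time` (minutes, strictly
#'   increasing, constant 5 s spacing) and `angle` (degrees).
#' @param angle_threshold Maximum allowed absolute change between successive
#'   epochs, degrees.
#' @param min_duration Minimum run length, minutes.
#' @return Tibble of intervals with columns `start`, `end`, `duration`
#'   (minutes); zero rows when nothing qualifies.
#' @examples
#' s <- tibble::tibble(time = seq(0, 10, by = 5 / 60),
#'                     angle = 0)
#' detect_inactivity_periods(s)
#' @export
detect_inactivity_periods <- function(series, angle_threshold = 5,
                                      min_duration = 5) {
  series <- as_tibble(series)
  if (!all(c("time", "angle") %in% names(series))) {
    abort("series needs columns 'time' and 'angle'")
  }
  n <- nrow(series)
  if (n < 60) abort("need at least 60 epochs (5 minutes) of data")
  dt <- diff(series$time)
  ep <- stats::median(dt)
  if (any(abs(dt - ep) > 1e-6) || ep <= 0) {
    abort("epoch spacing must be constant and positive",
          class = "twinsleep_epoch_error")
  }
  stable <- abs(diff(series$angle)) <= angle_threshold
  # segment epochs: epoch i+1 joins epoch i's run iff transition i is stable
  run_id <- cumsum(c(TRUE, !stable))
  runs <- tibble(id = run_id, time = series$time)
  out <- runs |>
    group_by(.data$id) |>
    summarise(start = min(.data$time), n_ep = dplyr::n(), .groups = "drop") |>
    mutate(duration = .data$n_ep * ep, end = .data$start + .data$duration) |>
    filter(.data$duration >= min_duration) |>
    arrange(.data$start) |>
    select("start", "end", "duration")
  out
}

#' Classify inactivity periods within the diary sleep window
#'
#' Sustained-inactivity periods are only treated as sleep when they fall in
#' the self-reported sleep window: each interval is intersected with
#' `[bed, rise]` and clipped at the window bounds. Intervals entirely outside
#' the window are dropped. Pieces shorter than the detection minimum after
#' clipping are retained — the sustained-inactivity rule applies at
#' detection, before windowing.
#'
#' @param intervals Tibble from [detect_inactivity_periods()].
#' @param diary_window Numeric length-2 `c(bed, rise)` on the noon-anchored
#'   minute axis, or a one-row data frame with columns `bed` and `rise`.
#' @return Tibble of clipped sleep periods (`start`, `end`, `duration`).
#' @export
classify_sleep_periods <- function(intervals, diary_window) {
  if (is.data.frame(diary_window)) {
    diary_window <- c(diary_window$bed[1], diary_window$rise[1])
  }
  if (length(diary_window) != 2 || diary_window[1] >= diary_window[2]) {
    abort("diary window must be c(bed, rise) with bed < rise")
  }
  intervals |>
    mutate(start = pmax(.data$start, diary_window[1]),
           end = pmin(.data$end, diary_window[2])) |>
    filter(.data$end > .data$start) |>
    mutate(duration = .data$end - .data$start)
}

#' Summarize one night's sleep periods into nightly phenotypes
#'
#' Applies the standard nightly definitions: sleep onset is the start of the
#' first sustained inactivity period inside the sleep window, wake time the
#' end of the last, sleep duration the sum of sleep-period lengths (so
#' nocturnal wake gaps do not count), and sleep midpoint the time halfway
#' between onset and wake (not weighted by where sleep fell). The diary
#' restorative item is coded Refreshed = 1, Tired = 0.
#'
#' @param sleep_periods Tibble from [classify_sleep_periods()].
#' @param restorative_response `"Refreshed"`, `"Tired"`, or `NA`.
#' @param night_type `"school"` or `"nonschool"` label to carry through.
#' @return One-row tibble: `onset`, `wake`, `duration`, `midpoint`
#'   (noon-anchored minutes), `restorative` (0/1/NA), `night_type`,
#'   `missing` (TRUE when no sleep period was found, in which case the
#'   timing fields are NA).
#' @export
summarize_night <- function(sleep_periods, restorative_response = NA,
                            night_type = NA_character_) {
  rest <- code_restorative(restorative_response)
  if (is.null(sleep_periods) || nrow(sleep_periods) == 0) {
    return(tibble(onset = NA_real_, wake = NA_real_, duration = NA_real_,
                  midpoint = NA_real_, restorative = rest,
                  night_type = night_type, missing = TRUE))
  }
  onset <- min(sleep_periods$start)
  wake <- max(sleep_periods$end)
  tibble(onset = onset, wake = wake,
         duration = sum(sleep_periods$duration),
         midpoint = onset + (wake - onset) / 2,
         restorative = rest, night_type = night_type, missing = FALSE)
}

code_restorative <- function(x) {
  if (length(x) != 1 || is.na(x)) return(NA_real_)
  if (is.numeric(x)) {
    if (!x %in% c(0, 1)) abort("numeric restorative response must be 0 or 1")
    return(as.numeric(x))
  }
  switch(tolower(as.character(x)),
         refreshed = 1, tired = 0,
         abort("restorative response must be 'Refreshed' or 'Tired'"))
}

#' Extract a night's phenotypes from raw angles plus a diary entry
#'
#' Convenience wrapper chaining [detect_inactivity_periods()],
#' [classify_sleep_periods()] and [summarize_night()].
#'
#' @inheritParams detect_inactivity_periods
#' @inheritParams classify_sleep_periods
#' @inheritParams summarize_night
#' @return One-row tibble as in [summarize_night()].
#' @export
extract_night <- function(series, diary_window, restorative_response = NA,
                          night_type = NA_character_, angle_threshold = 5,
                          min_duration = 5) {
  series |>
    detect_inactivity_periods(angle_threshold = angle_threshold,
                              min_duration = min_duration) |>
    classify_sleep_periods(diary_window) |>
    summarize_night(restorative_response = restorative_response,
                    night_type = night_type)
}
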