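#' Clock-time arithmetic on a noon-anchored continuous axis
#'
#' Adolescent sleep onsets span midnight (e.g. 19:35 one evening to 01:11 the
#' next morning), so naive clock arithmetic on hours-since-midnight breaks:
#' 01:11 would sort before 21:51. All internal sleep-timing arithmetic
#' therefore runs on a continuous axis of minutes since 12:00 noon of the
#' evening the night belongs to. On this axis 21:51 is 591 and 01:11 (next
#' day) is 791, so onset < wake always holds for a nocturnal sleep window.
#'
#' `hm_to_min()` parses `"hh:mm"` strings (24-h clock) to noon-anchored
#' minutes; times at or after 12:00 map to `[0, 720)` (same evening), times
#' before 12:00 map to `[720, 1440)` (next morning). `min_to_hm()` inverts the
#' mapping, reducing the axis value modulo 24 h back to a wall-clock string.
#'
#' @param x For `hm_to_min()`, a character vector of `"hh:mm"` times (hours
#'   may exceed 24, as in `"24:45"` for 00:45 past midnight). For
#'   `min_to_hm()`, a numeric vector of noon-anchored minutes.
#' @return `hm_to_min()`: numeric minutes since noon; `min_to_hm()`:
#'   character `"hh:mm"`.
#' @examples
#' hm_to_min(c("21:51", "01:11", "06:46"))
#' min_to_hm(c(591, 791, 1126))
#' @export
hm_to_min <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) abort("clock times must be 'hh:mm' strings")
  h <- as.numeric(vapply(parts, `[`, "", 1L))
  m <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(h) || anyNA(m)) abort("clock times must be 'hh:mm' strings")
  (h * 60 + m - 720) %% 1440
}

#' @rdname hm_to_min
#' @export
min_to_hm <- function(x) {
  tot <- (x + 720) %% 1440
  sprintf("%02d:%02d", floor(tot / 60), round(tot %% 60))
}
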