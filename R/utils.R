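#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero
#' (0.625 -> 0.63), the convention used for all reported per-megabase
#' attribution values and classification metrics. Base R's `round()`
#' rounds half to even and would print 0.62 instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# internal: log a message to stderr with a level prefix
sb_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

# internal: stop unless all values are non-negative whole numbers
assert_counts <- function(x, what = "counts") {
  if (any(is.na(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    stop(what, " must be non-negative integers", call. = FALSE)
  }
  invisible(TRUE)
}
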