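# Internal helpers: structured logging and argument checks.

fb_log <- function(..., level = "INFO") {
  message(sprintf("[fossilbracket %s] %s", level, paste0(...)))
}

fb_stop <- function(...) stop(paste0(...), call. = FALSE)

fb_warn <- function(...) warning(paste0(...), call. = FALSE)

#' @noRd
check_prob <- function(x, name = "C", allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    fb_stop(name, " must be a single numeric value")
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!lo_ok || x >= 1)
    fb_stop(name, " must lie in ", if (allow_zero) "[0, 1)" else "(0, 1)",
            "; got ", format(x))
  invisible(x)
}

check_count <- function(x, name = "n", min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    fb_stop(name, " must be an integer >= ", min, "; got ", format(x))
  as.integer(x)
}

check_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    fb_stop(name, " must be ", if (strict) "> 0" else ">= 0", "; got ", format(x))
  x
}

# round to 1 decimal Ma, the reporting convention used throughout
round_ma <- function(x) round(x, 1)
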