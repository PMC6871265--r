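#' Age interval in Ma before present
#'
#' An age with dating uncertainty, expressed as an interval
#' \code{[younger, older]} in millions of years before present (Ma). Ages
#' increase into the past and the present is 0. A precisely dated horizon has
#' \code{older == younger}.
#'
#' @param older Older bound in Ma.
#' @param younger Younger bound in Ma. Defaults to \code{older} (a point age).
#' @return An object of class \code{age_interval} with fields \code{older} and
#'   \code{younger}.
#' @examples
#' age_interval(7.5, 6.5)  # a poorly dated oldest hominin find
#' age_interval(4.4)       # a point age
#' @export
age_interval <- function(older, younger = older) {
  if (!is.numeric(older) || !is.numeric(younger) ||
      length(older) != 1L || length(younger) != 1L ||
      is.na(older) || is.na(younger))
    fb_stop("age_interval bounds must be single non-missing numerics")
  if (younger < 0)
    fb_stop("ages must be >= 0 Ma (present = 0); got younger = ", younger)
  if (older < younger)
    fb_stop("age_interval requires older >= younger; got [",
            younger, ", ", older, "]")
  structure(list(older = older, younger = younger), class = "age_interval")
}

#' @export
print.age_interval <- function(x, ...) {
  if (x$older == x$younger) cat(sprintf("<age %g Ma>\n", x$older))
  else cat(sprintf("<age %g-%g Ma>\n", x$younger, x$older))
  invisible(x)
}

#' @rdname age_interval
#' @param x An \code{age_interval}.
#' @export
age_midpoint <- function(x) {
  stopifnot(inherits(x, "age_interval"))
  (x$older + x$younger) / 2
}

is_point_age <- function(x) x$older == x$younger
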