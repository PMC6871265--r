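#' Piecewise-constant fossil recovery potential
#'
#' A relative fossil recovery-potential curve: nonnegative rates on
#' contiguous age intervals from the present (0 Ma) back to \code{t_max}.
#' Used by [ci_nonuniform()] to relax the assumption of stochastically
#' constant fossil recovery (recovery potential typically falls towards a
#' clade's time of origin).
#'
#' @param breakpoints Ascending ages in Ma starting at 0; length
#'   \code{length(rates) + 1}.
#' @param rates Nonnegative relative recovery rates, one per interval; at
#'   least one must be positive. Only relative magnitudes matter.
#' @return An object of class \code{recovery_curve}.
#' @examples
#' # Cenozoic rate 1, a 10-fold drop older than 66 Ma
#' recovery_curve(c(0, 66, 200), c(1, 0.1))
#' @export
recovery_curve <- function(breakpoints, rates) {
  if (!is.numeric(breakpoints) || !is.numeric(rates) ||
      length(breakpoints) != length(rates) + 1L)
    fb_stop("need length(breakpoints) == length(rates) + 1")
  if (breakpoints[1] != 0) fb_stop("breakpoints must start at 0 Ma")
  if (any(diff(breakpoints) <= 0)) fb_stop("breakpoints must be strictly ascending")
  if (any(rates < 0) || all(rates == 0))
    fb_stop("rates must be nonnegative with at least one positive")
  structure(list(breakpoints = as.numeric(breakpoints),
                 rates = as.numeric(rates),
                 t_max = breakpoints[length(breakpoints)]),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve: %d interval(s) on [0, %g] Ma>\n",
              length(x$rates), x$t_max))
  invisible(x)
}

#' Cumulative recovery potential G(t)
#'
#' Integrates the recovery curve from the present back to age \code{t}:
#' \eqn{G(t) = \int_0^t r(u)\,du}. Under the curve's model, fossil find ages
#' on \code{(0, T)} are distributed with density proportional to the rate, so
#' transforming ages by \code{G} makes finds uniform.
#'
#' @param curve A [recovery_curve()].
#' @param t Ages in Ma (vectorized); must not exceed \code{curve$t_max}.
#' @return Cumulative potential, same length as \code{t}.
#' @export
recovery_cumulative <- function(curve, t) {
  stopifnot(inherits(curve, "recovery_curve"))
  if (any(t < 0 | t > curve$t_max))
    fb_stop("t must lie in [0, ", curve$t_max, "]")
  bp <- curve$breakpoints
  widths <- diff(bp)
  cumG <- c(0, cumsum(widths * curve$rates))
  i <- findInterval(t, bp, rightmost.closed = TRUE)
  cumG[i] + (t - bp[i]) * curve$rates[pmin(i, length(curve$rates))]
}

# inverse of G on [0, G(t_max)]; piecewise linear, exact
recovery_cumulative_inverse <- function(curve, g) {
  bp <- curve$breakpoints
  widths <- diff(bp)
  cumG <- c(0, cumsum(widths * curve$rates))
  if (any(g < 0 | g > cumG[length(cumG)] + 1e-12))
    fb_stop("g outside the curve's cumulative span")
  out <- numeric(length(g))
  for (k in seq_along(g)) {
    i <- max(which(cumG <= g[k] + 1e-15))
    i <- min(i, length(curve$rates))
    r <- curve$rates[i]
    out[k] <- if (r > 0) bp[i] + (g[k] - cumG[i]) / r else bp[i + 1]
  }
  out
}

#' Read a recovery curve from CSV
#'
#' Expects columns \code{age_older_ma}, \code{age_younger_ma},
#' \code{relative_rate}; intervals must tile \code{[0, t_max]} contiguously
#' (any row order).
#'
#' @param path CSV file path.
#' @return A [recovery_curve()].
#' @export
read_recovery_curve <- function(path) {
  if (!file.exists(path)) fb_stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_older_ma", "age_younger_ma", "relative_rate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fb_stop(path, " is missing required column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$age_younger_ma), , drop = FALSE]
  if (df$age_younger_ma[1] != 0 ||
      any(abs(df$age_younger_ma[-1] - df$age_older_ma[-nrow(df)]) > 1e-9))
    fb_stop(path, ": intervals must tile [0, t_max] contiguously from 0")
  recovery_curve(c(df$age_younger_ma, df$age_older_ma[nrow(df)]),
                 df$relative_rate)
}
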