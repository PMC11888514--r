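#' Restricted cubic spline basis with 3 knots
#'
#' Truncated-power restricted cubic spline: cubic between the outer knots,
#' constrained to be linear beyond them. With 3 knots the basis has two
#' columns: the identity and one non-linear term
#' \deqn{[(x-t_1)_+^3 - (x-t_2)_+^3 (t_3-t_1)/(t_3-t_2) +
#'        (x-t_3)_+^3 (t_2-t_1)/(t_3-t_2)] / (t_3-t_1)^2.}
#' Knots default to the 0.1, 0.5 and 0.9 sample quantiles (the outer pair is
#' the customary choice for trial covariates; the middle knot at the median is
#' this package's documented convention and is configurable via `probs` or
#' explicit `knots`).
#'
#' @param x numeric vector.
#' @param knots optional length-3 increasing knot vector; overrides `probs`.
#' @param probs quantile probabilities used when `knots` is NULL.
#' @return numeric matrix with columns `lin` and `nl` and attribute `knots`.
#'   If fewer than 3 distinct knots can be placed, a one-column linear basis
#'   is returned with a warning.
#' @export
rcs3_basis <- function(x, knots = NULL, probs = c(0.1, 0.5, 0.9)) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (is.null(knots)) {
    if (length(unique(x[!is.na(x)])) < 3) {
      warning("fewer than 3 distinct values: falling back to a linear term")
      out <- cbind(lin = x)
      attr(out, "knots") <- NULL
      return(out)
    }
    knots <- unname(stats::quantile(x, probs = probs, na.rm = TRUE, type = 7))
  }
  if (length(knots) != 3 || any(diff(knots) <= 0)) {
    warning("knots are not 3 strictly increasing values: falling back to a linear term")
    out <- cbind(lin = x)
    attr(out, "knots") <- NULL
    return(out)
  }
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  p3 <- function(u) pmax(u, 0)^3
  nl <- (p3(x - t1) - p3(x - t2) * (t3 - t1) / (t3 - t2) +
           p3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  out <- cbind(lin = x, nl = nl)
  attr(out, "knots") <- knots
  out
}
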