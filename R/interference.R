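#' Interference distribution from a single strength parameter
#'
#' Builds the dummy-event count distribution \eqn{\gamma} of the gamma
#' (counting) model of chiasma interference from a single non-negative,
#' possibly non-integer strength parameter \eqn{q}.  Consecutive chiasmata
#' are separated by a random number of unobserved "dummy" events; under the
#' gamma model that number is \eqn{\lfloor q\rfloor} with probability
#' \eqn{1 - \{q\}} and \eqn{\lfloor q\rfloor + 1} with probability
#' \eqn{\{q\}}, where \eqn{\{q\}} is the fractional part.  \eqn{q = 0}
#' recovers the no-interference (Haldane) limit.
#'
#' @param q Non-negative interference strength.
#' @param m Maximum dummy count (vector is indexed 0..\code{m}).  Defaults to
#'   the smallest value that holds the support of \code{q}.
#' @return Numeric probability vector of length \code{m + 1}; element
#'   \code{i + 1} is the probability of \code{i} intervening dummy events.
#'   The strength is kept in attribute \code{"q"}.
#' @examples
#' gamma_from_strength(4)      # all mass on 4 dummy events
#' gamma_from_strength(3.72)   # mass 0.28 on 3, 0.72 on 4
#' @export
gamma_from_strength <- function(q, m = NULL) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("'q' must be a single non-negative number")
  fl <- floor(q)
  fr <- q - fl
  need <- if (fr > 0) fl + 1L else fl
  if (is.null(m)) m <- max(need, fl + 1L)
  m <- as.integer(m)
  if (m < need)
    stop("'m' too small to hold the support of q = ", q)
  gam <- numeric(m + 1L)
  gam[fl + 1L] <- 1 - fr
  if (fr > 0) gam[fl + 2L] <- fr
  attr(gam, "q") <- q
  gam
}

## internal: validate a probability vector over phases/dummy counts 0..m
check_pmf <- function(p, what = "distribution", tol = 1e-12) {
  if (!is.numeric(p) || length(p) < 1L)
    stop("'", what, "' must be a non-empty numeric vector")
  if (any(p < -tol)) stop("'", what, "' has negative entries")
  if (abs(sum(p) - 1) > 1e-8)
    stop("'", what, "' does not sum to 1 (sum = ", format(sum(p)), ")")
  invisible(p)
}

#' Stationary phase distribution of the renewal crossover process
#'
#' The phase at a point is the number of dummy events between that point and
#' the nearest chiasma in a given direction.  At an arbitrary point of the
#' equilibrium renewal process the phase follows
#' \deqn{\pi_i = \sum_{s=i}^{m} \gamma_s \Big/ \sum_{s=0}^{m} (s+1)\gamma_s .}
#'
#' @param gamma Interference distribution (see [gamma_from_strength()]).
#' @return Numeric probability vector of the same length as \code{gamma}.
#' @export
stationary_phase <- function(gamma) {
  check_pmf(gamma, "gamma")
  m <- length(gamma) - 1L
  tails <- rev(cumsum(rev(gamma)))          # tails[i+1] = sum_{s >= i} gamma_s
  pi <- tails / sum((seq_len(m + 1L)) * gamma)
  as.numeric(pi)
}

#' Renewal coefficients
#'
#' Probability \eqn{b_t} that an event of the stream is a chiasma given that a
#' chiasma occurred \eqn{t} events earlier:
#' \deqn{b_0 = 1,\qquad b_t = \sum_{a=0}^{t-1} b_a\,\gamma_{t-1-a}.}
#'
#' @param gamma Interference distribution.
#' @param tmax Truncation length (coefficients are returned for t = 0..tmax).
#' @return Numeric vector \code{b} of length \code{tmax + 1}, \code{b[1]} being
#'   \eqn{b_0}.
#' @export
renewal_coefficients <- function(gamma, tmax) {
  check_pmf(gamma, "gamma")
  tmax <- as.integer(tmax)
  if (tmax < 0) stop("'tmax' must be >= 0")
  m <- length(gamma) - 1L
  b <- numeric(tmax + 1L)
  b[1L] <- 1
  if (tmax >= 1L) {
    for (t in seq_len(tmax)) {
      a <- 0:(t - 1L)
      g_idx <- t - 1L - a            # gamma index needed for each a
      ok <- g_idx <= m
      b[t + 1L] <- sum(b[a[ok] + 1L] * gamma[g_idx[ok] + 1L])
    }
  }
  b
}

#' Expected events per chiasma
#'
#' Mean of (dummy events + 1) between chiasmata, \eqn{\sum_s (s+1)\gamma_s}.
#' Under the gamma model this equals \eqn{q + 1}.
#'
#' @param gamma Interference distribution.
#' @return Scalar multiplier.
#' @export
event_multiplier <- function(gamma) {
  check_pmf(gamma, "gamma")
  sum(seq_along(gamma) * gamma)
}

#' Expected event count of an interval
#'
#' Converts the heterokaryotype genetic length of an interval (in Morgans)
#' into the expected number of events (dummy + chiasma) of the counting
#' process: \eqn{\lambda = 2\,l'\sum_s (s+1)\gamma_s}.
#'
#' @param l_prime Genetic length in Morgans (non-negative).
#' @param gamma Interference distribution.
#' @return Scalar \eqn{\lambda \ge 0}.
#' @export
interval_rate <- function(l_prime, gamma) {
  if (any(l_prime < 0)) stop("negative genetic length")
  2 * l_prime * event_multiplier(gamma)
}
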