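#' Phase-transition matrix for an interval without chiasmata
#'
#' Element (i, j) is the probability that an interval with event rate
#' \eqn{\lambda} contains no chiasma and the phase drops from i (entering) to
#' j (leaving), i.e. exactly \eqn{i - j} dummy events fall in the interval:
#' \deqn{H[i,j] = \lambda^{i-j} e^{-\lambda} / (i-j)! \quad (i \ge j).}
#'
#' @param lambda Expected event count of the interval (see [interval_rate()]).
#' @param m Maximum phase; the matrix has order \code{m + 1}.
#' @return Lower-triangular (in phase ordering) matrix of order \code{m + 1};
#'   rows index the entering phase i = 0..m, columns the leaving phase j.
#' @export
h_matrix <- function(lambda, m) {
  if (lambda < 0) stop("'lambda' must be >= 0")
  m <- as.integer(m)
  H <- matrix(0, m + 1L, m + 1L)
  dp <- stats::dpois(0:m, lambda)
  for (j in 0:m) H[(j:m) + 1L, j + 1L] <- dp[seq_len(m - j + 1L)]
  H
}

## internal: number of t-terms after which the neglected mass of the Eq-4 sum
## is below tol: since b_t <= 1 the tail is bounded by the Poisson upper tail
## beyond the smallest count still to be added (1 + T).  Hard-capped.
renewal_truncation <- function(lambda, m, tol) {
  if (lambda == 0) return(0L)
  t_cap <- ceiling(10 * (m + 1L) + lambda + 10 * sqrt(lambda))
  T <- max(0L, stats::qpois(1 - tol, lambda) - 1L)
  while (stats::ppois(1L + T, lambda, lower.tail = FALSE) >= tol) {
    T <- T + 1L
    if (T > t_cap)
      stop("event-count sum did not converge to tolerance ", tol,
           " within the hard cap (lambda = ", lambda, ")")
  }
  T
}

## internal: f(c) = sum_{t = 0..T} b_t Pois(c + t; lambda), for c = 1..cmax.
## 'b' may be precomputed (length >= T + 1) and is shared across intervals.
renewal_poisson_sum <- function(lambda, gamma, cmax, tol = 1e-12, b = NULL) {
  if (lambda == 0) return(numeric(cmax))
  T <- renewal_truncation(lambda, length(gamma) - 1L, tol)
  if (is.null(b)) b <- renewal_coefficients(gamma, T)
  if (length(b) < T + 1L) stop("'b' too short for the truncation length")
  dp <- stats::dpois(seq_len(cmax + T), lambda)   # dp[x] = Pois(x; lambda)
  idx <- outer(seq_len(cmax), 0:T, `+`)
  drop(matrix(dp[idx], cmax) %*% b[seq_len(T + 1L)])
}

#' Phase-transition matrix for an interval with at least one chiasma
#'
#' Element (i, j) is the probability that an interval with event rate
#' \eqn{\lambda} contains one or more chiasmata and the leaving phase is j,
#' given entering phase i:
#' \deqn{G[i,j] = \sum_{t\ge 0} b_t \sum_{s=j}^{m} \gamma_s\,
#'   \frac{\lambda^{\,i+1+t+s-j} e^{-\lambda}}{(i+1+t+s-j)!}.}
#' The infinite t-sum is truncated once the Poisson upper-tail mass beyond the
#' smallest remaining count falls below \code{tol} (the coefficients
#' \eqn{b_t \le 1} make the tail a valid bound); non-convergence within the
#' hard cap is an error.
#'
#' @param lambda Expected event count of the interval.
#' @param gamma Interference distribution; its length fixes the matrix order.
#' @param tol Truncation tolerance for the t-sum.
#' @param b Optional precomputed [renewal_coefficients()] (long enough for
#'   the truncation; shared across intervals in repeated evaluations).
#' @return Matrix of order \code{length(gamma)}, all entries in [0, 1].
#' @export
g_matrix <- function(lambda, gamma, tol = 1e-12, b = NULL) {
  if (lambda < 0) stop("'lambda' must be >= 0")
  if (tol <= 0) stop("'tol' must be > 0")
  check_pmf(gamma, "gamma")
  m <- length(gamma) - 1L
  G <- matrix(0, m + 1L, m + 1L)
  if (lambda == 0) return(G)
  cmax <- 2L * m + 1L                      # largest i + 1 + s - j needed
  f <- renewal_poisson_sum(lambda, gamma, cmax, tol, b)
  D <- outer(0:m, 0:m, `-`) + 1L           # i - j + 1
  for (s in which(gamma > 0) - 1L) {       # few nonzero terms (gamma model: 2)
    idx <- D + s
    term <- gamma[s + 1L] * matrix(f[pmax(idx, 1L)], m + 1L) * (idx >= 1L)
    term[, seq_len(m + 1L) - 1L > s] <- 0  # s-sum requires s >= j
    G <- G + term
  }
  G
}

#' Interval transition matrices for recombinant and non-recombinant outcomes
#'
#' Each chiasma is transmitted to the sampled chromatid with probability 1/2
#' (no chromatid interference), so the matrix applied when interval k is
#' recombinant is \eqn{M(1) = G/2}, and when it is not,
#' \eqn{M(0) = G/2 + H}.
#'
#' @inheritParams g_matrix
#' @return List with elements \code{M0} and \code{M1}.
#' @export
transition_matrices <- function(lambda, gamma, tol = 1e-12, b = NULL) {
  m <- length(gamma) - 1L
  G <- g_matrix(lambda, gamma, tol, b)
  H <- h_matrix(lambda, m)
  list(M0 = 0.5 * G + H, M1 = 0.5 * G)
}

#' Probability of one recombination pattern along a chain of intervals
#'
#' Multilocus pattern probability by phase-matrix multiplication:
#' \deqn{\Pr(r) = \Omega \Big(\prod_k M_k(r_k)\Big) \mathbf{1}^T,}
#' where \eqn{\Omega} is the phase distribution at the chain's starting point.
#'
#' @param omega Starting phase distribution (same length as \code{gamma}).
#' @param lambdas Vector of interval event rates, ordered along the chain.
#' @param pattern Binary vector (0 = non-recombinant, 1 = recombinant), same
#'   length as \code{lambdas}.
#' @param gamma Interference distribution.
#' @param tol Truncation tolerance passed to [g_matrix()].
#' @return Probability in [0, 1].  An empty chain returns 1.
#' @export
pattern_probability <- function(omega, lambdas, pattern, gamma, tol = 1e-12) {
  check_pmf(omega, "omega")
  if (length(lambdas) != length(pattern))
    stop("'lambdas' and 'pattern' must have the same length")
  if (length(omega) != length(gamma))
    stop("'omega' and 'gamma' must have the same length")
  v <- matrix(omega, nrow = 1L)
  for (k in seq_along(lambdas)) {
    M <- transition_matrices(lambdas[k], gamma, tol)
    v <- v %*% (if (pattern[k] == 1) M$M1 else M$M0)
  }
  sum(v)
}

#' Full recombination-pattern distribution of a chain
#'
#' Computes the probabilities of all \eqn{2^n} recombination patterns of a
#' chain of n intervals in one pass (sharing the per-interval transition
#' matrices across patterns).
#'
#' @inheritParams pattern_probability
#' @return Numeric vector of length \eqn{2^n}; entry \code{idx + 1} is the
#'   probability of the pattern whose interval-k bit (k = 1..n, bit value
#'   \eqn{2^{k-1}}) is set iff interval k is recombinant.  For n = 0 the
#'   vector is \code{1}.
#' @export
chain_pattern_distribution <- function(omega, lambdas, gamma, tol = 1e-12,
                                       b = NULL) {
  check_pmf(omega, "omega")
  n <- length(lambdas)
  if (n == 0L) return(1)
  if (n > 24L) stop("chain too long to enumerate (n > 24)")
  Ms <- lapply(lambdas, transition_matrices, gamma = gamma, tol = tol, b = b)
  chain_dist_from_matrices(omega, Ms)
}

## internal: the doubling pass of chain_pattern_distribution, given the
## per-interval transition matrices.  States: rows are phase vectors for
## every pattern prefix; prefixes double at each interval with bit k placed
## at significance 2^(k-1); after interval k the bit-k = 1 block sits below
## the bit-k = 0 block, so row order is the binary pattern index.
chain_dist_from_matrices <- function(omega, Ms) {
  states <- matrix(omega, nrow = 1L)
  for (k in seq_along(Ms))
    states <- rbind(states %*% Ms[[k]]$M0, states %*% Ms[[k]]$M1)
  as.numeric(rowSums(states))
}
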