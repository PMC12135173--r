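## internal: draw n values from a discrete law over 0..m given by 'p'
rdiscrete0 <- function(n, p) {
  if (n == 0L) return(integer(0))
  sample.int(length(p), n, replace = TRUE, prob = p) - 1L
}

#' Simulate the counting process along one region chain
#'
#' Realises the renewal crossover process in event space: events form a
#' unit-rate Poisson stream on the cumulative \eqn{\lambda} axis of the
#' chain; the first chiasma occurs after an \eqn{\Omega}-drawn number of
#' dummy events and every later chiasma after a \eqn{\gamma}-drawn number.
#' Chiasmata are binned by subinterval, and each is independently transmitted
#' to the sampled chromatid (a crossover) with probability 1/2.
#'
#' @param lambdas Per-subinterval event rates along the chain.
#' @param gamma Interference distribution.
#' @param omega Starting phase distribution at the chain origin.
#' @param n Number of independent meioses to simulate.
#' @return List with integer matrices \code{chiasmata} and \code{crossovers}
#'   (n rows, one column per subinterval).
#' @export
simulate_region <- function(lambdas, gamma, omega, n) {
  check_pmf(gamma, "gamma"); check_pmf(omega, "omega")
  K <- length(lambdas)
  chi <- matrix(0L, n, K)
  xo <- matrix(0L, n, K)
  if (K == 0L || sum(lambdas) == 0 || n == 0L)
    return(list(chiasmata = chi, crossovers = xo))
  Lam <- sum(lambdas)
  k_i <- stats::rpois(n, Lam)              # events per meiosis
  M <- sum(k_i)
  if (M == 0L) return(list(chiasmata = chi, crossovers = xo))
  gid <- rep.int(seq_len(n), k_i)
  u <- stats::runif(M, 0, Lam)             # event positions
  u <- u[order(gid, u)]                    # sort by position within meiosis
  offset <- cumsum(c(0L, k_i))[seq_len(n)] # global index of event 0 per meiosis
  ## chiasma ranks: Omega-drawn wait, then gamma-drawn gaps
  is_chi <- logical(M)
  cur <- rdiscrete0(n, omega) + 1L
  active <- cur <= k_i
  while (any(active)) {
    is_chi[offset[active] + cur[active]] <- TRUE
    cur[active] <- cur[active] + 1L + rdiscrete0(sum(active), gamma)
    active <- cur <= k_i
  }
  bin <- findInterval(u, cumsum(lambdas), left.open = TRUE) + 1L
  g_of_event <- rep.int(seq_len(n), k_i)   # meiosis id in sorted order
  cells <- (g_of_event - 1L) * K + bin
  chi_cnt <- tabulate(cells[is_chi], nbins = n * K)
  chi <- matrix(chi_cnt, n, K, byrow = TRUE)
  kept <- is_chi & (stats::runif(M) < 0.5)
  xo_cnt <- tabulate(cells[kept], nbins = n * K)
  xo <- matrix(xo_cnt, n, K, byrow = TRUE)
  list(chiasmata = chi, crossovers = xo)
}

#' Simulate gametes of an inversion karyotype
#'
#' Simulates the four regions of a heterokaryotype independently (each chain
#' starting at its adjoining breakpoint with the hypothesis' phase law), or a
#' single stationary chain for a homokaryotype; computes per-marker-interval
#' recombination bits (XOR of subinterval crossover parities) and, for
#' heterokaryotypes, the balance of each gamete.
#'
#' @param layout A [chromosome_layout()].
#' @param spec A [hypothesis_spec()].
#' @param n Number of gametes.
#' @param lengths Per-interval lengths (Morgans); defaults to
#'   \code{layout$lengths}.
#' @param seed Optional seed.
#' @return List with \code{patterns} (n x n_intervals 0/1 matrix),
#'   \code{balanced} (logical, all TRUE for homokaryotypes) and
#'   \code{chiasmata} (total chiasma count per gamete's meiosis, for
#'   expectation checks).
#' @export
simulate_gametes <- function(layout, spec, n, lengths = NULL, seed = NULL) {
  stopifnot(inherits(layout, "xoinv_layout"),
            inherits(spec, "xoinv_hypothesis"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lengths)) lengths <- layout$lengths
  if (is.null(lengths)) stop("no interval lengths available")
  m <- required_m(spec)
  gam <- gamma_from_strength(spec$qc, m)
  decomp <- decompose_layout(layout)
  omega <- if (layout$karyotype == "homo") stationary_phase(gam)
           else start_phase(spec, m)
  nI <- layout$n_intervals
  pat <- matrix(0L, n, nI)
  chi_tot <- integer(n)
  balanced <- rep(TRUE, n)
  inner <- c("inner_left", "inner_right")
  for (r in names(decomp$chains)) {
    d <- decomp$chains[[r]]
    if (nrow(d) == 0L) next
    lam <- interval_rate(d$share * lengths[d$parent], gam)
    sim <- simulate_region(lam, gam, omega, n)
    bits <- sim$crossovers %% 2L
    for (j in seq_len(nrow(d)))
      pat[, d$parent[j]] <- bitwXor(pat[, d$parent[j]], bits[, j])
    chi_tot <- chi_tot + as.integer(rowSums(sim$chiasmata))
    if (layout$karyotype == "hetero" && r %in% inner)
      balanced <- xor(balanced, as.logical(rowSums(bits) %% 2L))
  }
  list(patterns = pat, balanced = balanced, chiasmata = chi_tot)
}

#' Synthesise a viable-offspring pattern dataset
#'
#' Draws gametes under the model and keeps balanced (viable) ones by
#' rejection until \code{N} are collected; tabulates their marker patterns.
#' The realised acceptance probability, an estimate of \eqn{1 - \zeta} of
#' the full inner regions, is attached as attribute
#' \code{"acceptance_rate"}.
#'
#' @inheritParams simulate_gametes
#' @param N Number of viable offspring to collect (> 0).
#' @return A [pattern_dataset()].
#' @export
synthesize_pattern_dataset <- function(layout, spec, N, lengths = NULL,
                                       seed = NULL) {
  if (N <= 0) stop("'N' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  nI <- layout$n_intervals
  got <- matrix(0L, 0L, nI)
  tried <- 0L
  while (nrow(got) < N) {
    batch <- max(1000L, ceiling(1.5 * (N - nrow(got))))
    sim <- simulate_gametes(layout, spec, batch, lengths)
    tried <- tried + batch
    got <- rbind(got, sim$patterns[sim$balanced, , drop = FALSE])
  }
  accepted <- nrow(got)
  got <- got[seq_len(N), , drop = FALSE]
  key <- as.vector(got %*% 2L^(seq_len(nI) - 1L))
  cnt <- tabulate(key + 1L, nbins = 2^nI)
  ds <- pattern_dataset(layout$markers,
                        stats::setNames(cnt, pattern_strings(nI)))
  attr(ds, "acceptance_rate") <- accepted / tried
  ds
}

#' Synthesise sterility records on the model surface
#'
#' Generates per-inversion observed sterilities from the closed-form model,
#' optionally perturbed by Gaussian noise truncated to [0, 1].
#'
#' @param spec A [hypothesis_spec()].
#' @param d_I Shared chiasma-suppression factor in (0, 1].
#' @param inversions Data frame with columns \code{inversion_id}, \code{I}
#'   (homokaryotype length, Morgans) and \code{rho}.
#' @param noise_sd Standard deviation of the additive noise (0 = exact).
#' @param seed Optional seed.
#' @return Data frame of sterility records (columns \code{inversion_id},
#'   \code{I}, \code{rho}, \code{observed}).
#' @export
synthesize_sterility_records <- function(spec, d_I, inversions, noise_sd = 0,
                                         seed = NULL) {
  stopifnot(inherits(spec, "xoinv_hypothesis"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  zeta <- vapply(seq_len(nrow(inversions)), function(i)
    expected_sterility(inversions$I[i], inversions$rho[i], spec, d_I),
    numeric(1))
  obs <- zeta
  if (noise_sd > 0)
    obs <- pmin(pmax(zeta + stats::rnorm(length(zeta), 0, noise_sd), 0), 1)
  data.frame(inversion_id = inversions$inversion_id, I = inversions$I,
             rho = inversions$rho, observed = obs)
}
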