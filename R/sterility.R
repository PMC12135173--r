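#' Recombination probability of an inner region
#'
#' Probability that a region adjoining a breakpoint, with event rate
#' \eqn{\lambda} and starting phase law \eqn{\Omega}, transmits a recombinant
#' chromatid:
#' \deqn{\Pr(r = 1) = \tfrac12\Big(1 - \sum_{s=0}^m \Omega_s
#'   \sum_{c=0}^s e^{-\lambda}\lambda^c/c!\Big).}
#' Recombination requires at least one chiasma (the inner Poisson sum is the
#' probability that fewer events than needed occur) and each chiasma reaches
#' the sampled chromatid with probability 1/2.
#'
#' @param omega Starting phase distribution.
#' @param lambda Expected event count of the region (>= 0).
#' @return Probability in [0, 1/2].
#' @export
inner_recombination_probability <- function(omega, lambda) {
  check_pmf(omega, "omega")
  if (lambda < 0) stop("'lambda' must be >= 0")
  s <- seq_along(omega) - 1L
  0.5 * (1 - sum(omega * stats::ppois(s, lambda)))
}

#' Sterility of a pericentric inversion heterokaryotype
#'
#' Proportion of unbalanced (inviable) gametes: the inversion of
#' heterokaryotype genetic length \code{I_prime} is split by the centromere
#' (relative position \code{rho}) into two inner regions of lengths
#' \eqn{I'\rho} and \eqn{I'(1-\rho)}; a gamete is unbalanced iff exactly one
#' of them is recombinant:
#' \deqn{\zeta = p_1(1-p_2) + p_2(1-p_1).}
#'
#' @param I_prime Heterokaryotype genetic length of the inversion (Morgans).
#' @param rho Relative centromere position in [0, 1].
#' @param gamma Interference distribution (sets the event rate scaling).
#' @param omega Starting phase distribution at the breakpoints.
#' @return Sterility in [0, 1/2].
#' @export
sterility <- function(I_prime, rho, gamma, omega) {
  if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1]")
  if (I_prime < 0) stop("'I_prime' must be >= 0")
  p1 <- inner_recombination_probability(omega,
                                        interval_rate(I_prime * rho, gamma))
  p2 <- inner_recombination_probability(omega,
                                        interval_rate(I_prime * (1 - rho),
                                                      gamma))
  p1 * (1 - p2) + p2 * (1 - p1)
}

#' Probability that both inner regions recombine
#'
#' The three-locus scenario with loci tied to the two breakpoints and the
#' centromere: the only recombination event observable in viable offspring is
#' a double crossover hitting both inner regions, with (unconditioned)
#' probability \eqn{p_1 p_2}.
#'
#' @inheritParams sterility
#' @return Probability in [0, 1/4].
#' @export
three_locus_recombination <- function(I_prime, rho, gamma, omega) {
  if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1]")
  if (I_prime < 0) stop("'I_prime' must be >= 0")
  p1 <- inner_recombination_probability(omega,
                                        interval_rate(I_prime * rho, gamma))
  p2 <- inner_recombination_probability(omega,
                                        interval_rate(I_prime * (1 - rho),
                                                      gamma))
  p1 * p2
}

## internal: expected sterility for one inversion under a hypothesis with
## shared suppression factor d_I (I' = d_I * I)
expected_sterility <- function(I, rho, spec, d_I) {
  m <- required_m(spec)
  gam <- gamma_from_strength(spec$qc, m)
  omega <- start_phase(spec, m)
  sterility(d_I * I, rho, gam, omega)
}

#' Least-squares sterility fit across inversions
#'
#' Fits the interference strength(s) and the shared chiasma-suppression
#' factor \eqn{d_I} by minimising the unweighted sum of squared deviations
#' between expected and observed sterilities over all inversions
#' (multi-start Nelder-Mead).  All inversions share the same parameters.
#'
#' @param records Data frame with columns \code{inversion_id}, \code{I}
#'   (homokaryotype length of the inversion, Morgans), \code{rho} and
#'   \code{observed} (sterility in [0, 1]).
#' @param hypothesis \code{"H0"}, \code{"H1"} or \code{"H2"}.
#' @param qmax Upper bound of the interference-strength box (default 30).
#' @param n_restarts Number of random Nelder-Mead starts.
#' @param seed Optional seed for the random starts.
#' @return List of class \code{"xoinv_sterility_fit"}: \code{hypothesis},
#'   \code{qc}, \code{qb}, \code{d_I}, \code{LS} (the achieved sum of
#'   squares), \code{expected} (fitted sterilities) and convergence
#'   metadata.  For H2 the optimum is known to be non-unique (the sterility
#'   depends on qb only through the starting phase law, and many (qc, qb)
#'   pairs realise the H1 optimum); a note is attached.
#' @export
fit_sterility <- function(records, hypothesis = c("H1", "H0", "H2"),
                          qmax = 30, n_restarts = 40, seed = NULL) {
  hypothesis <- match.arg(hypothesis)
  records <- validate_sterility_records(records)
  if (!is.null(seed)) set.seed(seed)
  two_q <- hypothesis == "H2"

  build <- function(th) {
    q1 <- qmax * stats::plogis(th[1L])
    d  <- stats::plogis(th[[length(th)]])
    qb <- if (two_q) qmax * stats::plogis(th[2L]) else NULL
    spec <- switch(hypothesis,
                   H0 = hypothesis_spec("H0", qc = q1),
                   H1 = hypothesis_spec("H1", qc = q1),
                   H2 = hypothesis_spec("H2", qc = q1, qb = qb))
    list(spec = spec, d_I = d)
  }
  obj <- function(th) {
    p <- build(th)
    exp_s <- vapply(seq_len(nrow(records)), function(i)
      expected_sterility(records$I[i], records$rho[i], p$spec, p$d_I),
      numeric(1))
    sum((exp_s - records$observed)^2)
  }
  npar <- 2L + as.integer(two_q)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    q0 <- stats::runif(if (two_q) 2L else 1L, 0, 10)
    d0 <- stats::runif(1, 0.1, 1)
    th0 <- c(stats::qlogis(pmin(pmax(q0 / qmax, 1e-4), 1 - 1e-4)),
             stats::qlogis(d0))
    opt <- tryCatch(
      stats::optim(th0, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- c(opt, list(restart = r))
  }
  if (is.null(best)) stop("all restarts failed to converge")
  p <- build(best$par)
  exp_s <- vapply(seq_len(nrow(records)), function(i)
    expected_sterility(records$I[i], records$rho[i], p$spec, p$d_I),
    numeric(1))
  out <- list(hypothesis = hypothesis, qc = p$spec$qc, qb = p$spec$qb,
              d_I = p$d_I, LS = best$value, expected = exp_s,
              records = records, n_restarts = n_restarts, npar = npar,
              restart = best$restart, counts = best$counts)
  if (two_q)
    out$note <- paste("the H2 sterility optimum is non-unique:",
                      "many (qc, qb) pairs attain the H1 least squares")
  class(out) <- "xoinv_sterility_fit"
  out
}

#' @export
print.xoinv_sterility_fit <- function(x, ...) {
  cat("Sterility fit,", x$hypothesis, "model (", nrow(x$records),
      "inversions )\n")
  cat(sprintf("  qc = %.3f", x$qc))
  if (!is.null(x$qb)) cat(sprintf("  qb = %.3f", x$qb))
  cat(sprintf("  d_I = %.3f  LS = %.4g\n", x$d_I, x$LS))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

## internal: coerce/validate a sterility record table
validate_sterility_records <- function(records) {
  records <- as.data.frame(records)
  need <- c("inversion_id", "I", "rho", "observed")
  if (!all(need %in% names(records)))
    stop("sterility records need columns: ", paste(need, collapse = ", "))
  if (any(records$I < 0)) stop("negative inversion length")
  if (any(records$rho < 0 | records$rho > 1)) stop("rho outside [0, 1]")
  if (any(records$observed < 0 | records$observed > 1))
    stop("observed sterility outside [0, 1]")
  records
}
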