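#' Recombination pattern-count dataset
#'
#' Observed counts of marker recombination patterns among surviving
#' offspring.  Patterns are binary strings of length n (one character per
#' marker interval, left to right; 1 = recombinant).
#'
#' @param markers Character vector of n + 1 marker names.
#' @param counts Named non-negative integer vector; names are pattern
#'   strings.  Missing patterns are imputed with count 0.
#' @return Object of class \code{"xoinv_dataset"} with the full
#'   \eqn{2^n}-vector of counts (canonical order, see
#'   [marker_pattern_distribution()]) and total \code{N}.
#' @export
pattern_dataset <- function(markers, counts) {
  markers <- as.character(markers)
  n <- length(markers) - 1L
  if (n < 1L) stop("need at least two markers")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be named by pattern strings")
  if (any(counts < 0)) stop("negative count")
  if (any(counts != round(counts))) stop("counts must be integers")
  bad <- names(counts)[!grepl(paste0("^[01]{", n, "}$"), names(counts))]
  if (length(bad))
    stop("malformed pattern string(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(counts))) stop("duplicated pattern strings")
  full <- stats::setNames(numeric(2^n), pattern_strings(n))
  full[names(counts)] <- counts
  structure(list(markers = markers, n_intervals = n, counts = full,
                 N = sum(full)),
            class = "xoinv_dataset")
}

#' @export
print.xoinv_dataset <- function(x, ...) {
  cat("Pattern dataset:", x$n_intervals, "intervals,", x$N,
      "offspring,", sum(x$counts > 0), "observed patterns\n")
  invisible(x)
}

#' Multinomial log-likelihood of a pattern dataset
#'
#' \eqn{\ln L = \sum_r c_r \log \Pr(r \mid \mathrm{viable})}, the multinomial
#' coefficient (constant in the parameters) omitted.  Model probabilities are
#' floored at \code{floor} before taking logs so that patterns observed with
#' positive count but vanishing model probability yield a finite, heavily
#' penalised value during optimisation; set \code{floor = 0} to get
#' \code{-Inf} in that case.
#'
#' @param dataset A [pattern_dataset()].
#' @param layout A [chromosome_layout()] with matching interval count.
#' @param spec A [hypothesis_spec()].
#' @param lengths Per-interval lengths (Morgans), strictly positive.
#' @param tol Truncation tolerance.
#' @param floor Probability floor applied before the log.
#' @return The log-likelihood.
#' @export
log_likelihood <- function(dataset, layout, spec, lengths, tol = 1e-12,
                           floor = 1e-300) {
  stopifnot(inherits(dataset, "xoinv_dataset"))
  if (layout$n_intervals != dataset$n_intervals)
    stop("layout and dataset disagree on the number of intervals")
  ll_ctx(dataset$counts, eval_context(layout), spec, lengths, tol, floor)
}

## internal: log-likelihood given a precomputed evaluation context
ll_ctx <- function(counts, ctx, spec, lengths, tol, floor = 1e-300) {
  pr <- pattern_dist_ctx(ctx, spec, lengths, tol)
  obs <- counts > 0
  p <- pr[obs]
  if (floor > 0) p <- pmax(p, floor)
  if (any(p == 0)) return(-Inf)
  sum(counts[obs] * log(p))
}

## internal: observed recombinant fraction per marker interval
interval_recombinant_fractions <- function(dataset) {
  n <- dataset$n_intervals
  idx <- 0:(2^n - 1L)
  vapply(seq_len(n), function(k) {
    rec <- bitwAnd(bitwShiftR(idx, k - 1L), 1L) == 1L
    sum(dataset$counts[rec]) / dataset$N
  }, numeric(1))
}

## internal: free interference-strength parameter count of a hypothesis
n_strength_params <- function(hypothesis) if (hypothesis == "H2") 2L else 1L

#' Maximum-likelihood fit of an interference hypothesis
#'
#' Multi-start Nelder-Mead maximisation of the viability-conditioned
#' multinomial likelihood over the interference strength(s) and the
#' per-interval heterokaryotype genetic lengths.  Lengths are searched on the
#' log scale and strengths through a scaled logistic onto [0, \code{qmax}],
#' so the simplex runs unconstrained.  Starting lengths are drawn around the
#' Haldane-inverted observed recombinant fractions (jittered by a factor
#' U[0.5, 2]); starting strengths are U[0, 10].
#'
#' @param dataset A [pattern_dataset()].
#' @param layout A [chromosome_layout()].
#' @param hypothesis \code{"H0"}, \code{"H1"} or \code{"H2"}.
#' @param n_restarts Number of random restarts (the best optimum wins, ties
#'   broken by first occurrence).
#' @param seed Optional seed.
#' @param qmax Strength upper bound (default 30).
#' @param tol Truncation tolerance for the pattern probabilities.
#' @param reltol Relative convergence tolerance of the simplex.
#' @param maxit Maximum simplex iterations per restart.
#' @return Object of class \code{"xoinv_fit"}: estimates \code{qc},
#'   \code{qb}, \code{lengths} (Morgans, named by interval), \code{lnL},
#'   \code{k} (free-parameter count), \code{AIC}, fitted pattern
#'   distribution, and convergence metadata.
#' @export
fit_recombination <- function(dataset, layout,
                              hypothesis = c("H1", "H0", "H2"),
                              n_restarts = 100, seed = NULL, qmax = 30,
                              tol = 1e-12, reltol = 1e-8, maxit = 5000) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(dataset, "xoinv_dataset"),
            inherits(layout, "xoinv_layout"))
  if (layout$n_intervals != dataset$n_intervals)
    stop("layout and dataset disagree on the number of intervals")
  if (layout$karyotype == "homo" && hypothesis != "H0")
    stop("a homokaryotype has no breakpoints; fit it under H0")
  if (!is.null(seed)) set.seed(seed)
  n <- layout$n_intervals
  nq <- if (layout$karyotype == "homo") 1L else n_strength_params(hypothesis)

  build <- function(th) {
    qs <- qmax * stats::plogis(th[seq_len(nq)])
    lens <- exp(th[nq + seq_len(n)])
    spec <- if (layout$karyotype == "homo" || hypothesis != "H2")
      hypothesis_spec(hypothesis, qc = qs[1L])
    else
      hypothesis_spec("H2", qc = qs[1L], qb = qs[2L])
    list(spec = spec, lengths = lens)
  }
  ctx <- eval_context(layout)
  ## no marker interval is remotely near 5 Morgans; steering the simplex away
  ## from such lengths keeps the event-space truncation grids small
  len_cap <- 5
  negll <- function(th) {
    p <- build(th)
    if (any(p$lengths > len_cap))
      return(1e9 + sum(p$lengths))
    ll <- tryCatch(ll_ctx(dataset$counts, ctx, p$spec, p$lengths, tol),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  rf <- pmin(interval_recombinant_fractions(dataset), 0.49)
  l_base <- pmax(-0.5 * log(1 - 2 * rf), 1e-4)   # Haldane-inverted starts

  best <- NULL
  for (r in seq_len(n_restarts)) {
    q0 <- stats::runif(nq, 0, 10)
    l0 <- l_base * stats::runif(n, 0.5, 2)
    th0 <- c(stats::qlogis(pmin(pmax(q0 / qmax, 1e-4), 1 - 1e-4)), log(l0))
    opt <- tryCatch(
      stats::optim(th0, negll, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- c(opt, list(restart = r))
  }
  if (is.null(best) || best$value >= 1e10)
    stop("all restarts failed to converge")
  ## polish: restarting the simplex from the winning optimum escapes the
  ## shrunken-simplex stalls Nelder-Mead is prone to in 8+ dimensions; stop
  ## once a round no longer improves the deviance by a meaningful amount
  for (round in 1:10) {
    pol <- stats::optim(best$par, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    gain <- best$value - pol$value
    if (pol$value < best$value) {
      best$par <- pol$par; best$value <- pol$value
      best$counts <- best$counts + pol$counts
    }
    if (gain < 1e-3) break
  }
  p <- build(best$par)
  lnL <- -best$value
  k <- n + nq
  fitted <- marker_pattern_distribution(layout, p$spec, p$lengths, tol)
  structure(list(hypothesis = if (layout$karyotype == "homo") "homokaryotype"
                 else hypothesis,
                 qc = p$spec$qc, qb = p$spec$qb,
                 lengths = stats::setNames(
                   p$lengths,
                   paste(layout$markers[-length(layout$markers)],
                         layout$markers[-1L], sep = "-")),
                 lnL = lnL, k = k, AIC = 2 * k - 2 * lnL,
                 fitted = fitted, N = dataset$N,
                 restart = best$restart, counts = best$counts,
                 n_restarts = n_restarts, qmax = qmax,
                 boundary = any(abs(c(p$spec$qc, p$spec$qb) - qmax) < 1e-3)),
            class = "xoinv_fit")
}

#' @export
print.xoinv_fit <- function(x, ...) {
  cat("ML fit,", x$hypothesis, "model:",
      sprintf("lnL = %.2f, k = %d, AIC = %.2f\n", x$lnL, x$k, x$AIC))
  cat(sprintf("  qc = %.3f", x$qc))
  if (!is.null(x$qb)) cat(sprintf("  qb = %.3f", x$qb))
  cat("\n  map (cM):",
      paste(sprintf("%s %.1f", names(x$lengths), 100 * x$lengths),
            collapse = ", "), "\n")
  if (isTRUE(x$boundary))
    cat("  warning: a strength estimate sits at the upper bound qmax =",
        x$qmax, "\n")
  invisible(x)
}

#' AIC comparison of fits on the same dataset
#'
#' @param fits List of [fit_recombination()] results on one dataset.
#' @return Data frame with model, k, lnL, AIC and \eqn{\Delta}AIC relative to
#'   the best model, ordered as given.
#' @export
compare_aic <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits")
  Ns <- vapply(fits, `[[`, numeric(1), "N")
  if (length(unique(Ns)) != 1L)
    warning("fits appear to come from different datasets (unequal N)")
  d <- data.frame(model = vapply(fits, `[[`, character(1), "hypothesis"),
                  k = vapply(fits, `[[`, numeric(1), "k"),
                  lnL = vapply(fits, `[[`, numeric(1), "lnL"),
                  AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  d$dAIC <- d$AIC - min(d$AIC)
  d
}

#' Likelihood-ratio test of equal breakpoint and chiasma interference
#'
#' H1 (one shared strength) is nested in H2 (separate qb); the statistic
#' \eqn{\chi^2 = 2(\ln L_{H2} - \ln L_{H1})} (floored at 0) is referred to a
#' chi-square law with 1 degree of freedom.
#'
#' @param fit_null H1 fit.
#' @param fit_alt H2 fit on the same dataset.
#' @return List with \code{chi2}, \code{df} and \code{p}.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "xoinv_fit"), inherits(fit_alt, "xoinv_fit"))
  if (fit_alt$k != fit_null$k + 1L)
    stop("fits are not nested with one extra parameter")
  if (fit_null$N != fit_alt$N)
    stop("fits are not on the same dataset")
  chi2 <- max(0, 2 * (fit_alt$lnL - fit_null$lnL))
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Parametric-bootstrap confidence intervals
#'
#' Refits the model to multinomial resamples of size N drawn from the fitted
#' viable-pattern distribution; per-parameter 95% intervals discard the most
#' extreme 5% of resampled values, read two-sided (2.5% in each tail).
#'
#' @param dataset A [pattern_dataset()].
#' @param layout A [chromosome_layout()].
#' @param hypothesis Hypothesis name.
#' @param n_boot Number of resamples (the reference analysis uses 99).
#' @param n_restarts Restarts per resample fit.
#' @param seed Seed; resample b uses \code{seed + b}.
#' @param qmax,tol Passed through to [fit_recombination()].
#' @param fit Optional precomputed fit of the same model (skips the initial
#'   fit).
#' @return Object of class \code{"xoinv_bootstrap"}: the point fit, a matrix
#'   of resample estimates, a data frame \code{ci} of per-parameter 2.5% and
#'   97.5% quantiles, and the number of failed (excluded) resamples.
#' @export
parametric_bootstrap <- function(dataset, layout, hypothesis = "H1",
                                 n_boot = 99, n_restarts = 100, seed = 1,
                                 qmax = 30, tol = 1e-12, fit = NULL) {
  if (is.null(fit))
    fit <- fit_recombination(dataset, layout, hypothesis,
                             n_restarts = n_restarts, seed = seed,
                             qmax = qmax, tol = tol)
  pr <- fit$fitted
  est_names <- c("qc", if (!is.null(fit$qb)) "qb", names(fit$lengths))
  draws <- matrix(NA_real_, n_boot, length(est_names),
                  dimnames = list(NULL, est_names))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(seed + b)
    cnt <- as.numeric(stats::rmultinom(1, size = fit$N, prob = pr))
    ds_b <- pattern_dataset(dataset$markers,
                            stats::setNames(cnt, names(pr)))
    fb <- tryCatch(
      fit_recombination(ds_b, layout, hypothesis, n_restarts = n_restarts,
                        seed = seed + b, qmax = qmax, tol = tol),
      error = function(e) NULL)
    if (is.null(fb)) { failed <- failed + 1L; next }
    draws[b, ] <- c(fb$qc, if (!is.null(fb$qb)) fb$qb, fb$lengths)
  }
  if (failed > 0.05 * n_boot)
    warning(failed, " of ", n_boot, " resample fits failed and were excluded")
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  ci <- data.frame(parameter = est_names,
                   estimate = c(fit$qc, if (!is.null(fit$qb)) fit$qb,
                                fit$lengths),
                   lower = qs[1L, ], upper = qs[2L, ], row.names = NULL)
  structure(list(fit = fit, draws = draws[ok, , drop = FALSE], ci = ci,
                 n_boot = n_boot, failed = failed),
            class = "xoinv_bootstrap")
}

#' @export
print.xoinv_bootstrap <- function(x, ...) {
  cat("Parametric bootstrap,", x$fit$hypothesis, "model:",
      nrow(x$draws), "of", x$n_boot, "resamples retained\n")
  ci <- x$ci
  ci$estimate <- signif(ci$estimate, 4)
  ci$lower <- signif(ci$lower, 4); ci$upper <- signif(ci$upper, 4)
  print(ci, row.names = FALSE)
  invisible(x)
}
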