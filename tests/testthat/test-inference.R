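test_that("pattern datasets validate and impute missing patterns", {
  ds <- pattern_dataset(c("a", "b", "c"), c("00" = 10, "10" = 5, "01" = 3))
  expect_equal(ds$N, 18)
  expect_equal(unname(ds$counts["11"]), 0)
  expect_error(pattern_dataset(c("a", "b", "c"), c("0x" = 1)), "malformed")
  expect_error(pattern_dataset(c("a", "b", "c"), c("00" = -1)), "negative")
  expect_error(pattern_dataset(c("a", "b", "c"), c("00" = 1, "00" = 2)),
               "duplicated")
})

test_that("log-likelihood reduces to the multinomial kernel", {
  lay <- toy_layout()
  spec <- hypothesis_spec("H1", qc = 4)
  pr <- marker_pattern_distribution(lay, spec)
  # all N counts on one pattern
  ds <- pattern_dataset(lay$markers, c("100" = 50))
  expect_equal(log_likelihood(ds, lay, spec, lay$lengths),
               50 * log(pr[["100"]]))
  # doubling all counts doubles lnL
  cnt <- round(1000 * pr) + 1
  names(cnt) <- names(pr)
  ds1 <- pattern_dataset(lay$markers, cnt)
  ds2 <- pattern_dataset(lay$markers, cnt * 2)
  expect_equal(2 * log_likelihood(ds1, lay, spec, lay$lengths),
               log_likelihood(ds2, lay, spec, lay$lengths))
})

test_that("log-likelihood matches a direct enumeration oracle", {
  lay <- chromosome_layout(c("a", "b", "c"), lengths = c(0.35, 0.3),
                           left_bp = list(interval = 1, fraction = 0.4),
                           centromere = list(interval = 2, fraction = 0.3),
                           right_bp = list(interval = 2, fraction = 0.9))
  spec <- hypothesis_spec("H1", qc = 4)
  ds <- synthesize_pattern_dataset(lay, spec, 500, seed = 6)
  m <- xoinv:::required_m(spec)
  gam <- gamma_from_strength(4, m)
  d <- decompose_layout(lay)
  ll_oracle <- oracle_loglik(ds$counts, d$chains, as.numeric(gam), gam,
                             lay$lengths)
  expect_equal(log_likelihood(ds, lay, spec, lay$lengths), ll_oracle,
               tolerance = 1e-8)
})

test_that("ML fitting recovers the interference strength of a
           homokaryotype chain", {
  # a multi-interval chain identifies q through coincidence patterns
  lay <- chromosome_layout(letters[1:5], lengths = c(0.2, 0.15, 0.25, 0.2),
                           karyotype = "homo")
  spec <- hypothesis_spec("H1", qc = 4)
  ds <- synthesize_pattern_dataset(lay, spec, 20000, seed = 14)
  fit <- fit_recombination(ds, lay, "H0", n_restarts = 6, seed = 15,
                           qmax = 12)
  expect_equal(fit$qc, 4, tolerance = 0.15)
  expect_equal(unname(fit$lengths), lay$lengths, tolerance = 0.1)
  expect_equal(fit$k, 5)                         # 4 lengths + 1 strength
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$lnL)
  expect_gte(fit$lnL, log_likelihood(ds, lay, spec, lay$lengths) - 1e-4)
})

test_that("ML fitting recovers the identified parameters of a
           heterokaryotype", {
  # 7 intervals as in the fly crosses; multi-subinterval outer chains carry
  # the interference signal.  Inner subinterval lengths sit on a known
  # near-flat likelihood ridge and are not asserted.
  l <- c(0.162, 0.214, 0.010, 0.007, 0.215, 0.210, 0.113)
  lay <- chromosome_layout(c("ve", "h", "th", "cu", "bx", "e", "ro", "ca"),
                           lengths = l,
                           left_bp = list(interval = 2, fraction = 0.5),
                           centromere = list(interval = 3, fraction = 0.5),
                           right_bp = list(interval = 4, fraction = 0.5))
  spec <- hypothesis_spec("H1", qc = 8.57)
  ds <- synthesize_pattern_dataset(lay, spec, 5000, seed = 42)
  fit <- fit_recombination(ds, lay, "H1", n_restarts = 6, seed = 15)
  expect_equal(fit$qc, 8.57, tolerance = 0.15)
  expect_equal(unname(fit$lengths[c(1, 5, 6, 7)]), l[c(1, 5, 6, 7)],
               tolerance = 0.12)
  expect_equal(fit$k, 8)
  expect_gte(fit$lnL, log_likelihood(ds, lay, spec, l) - 1e-4)
})

test_that("H2 never fits worse than H1 and parameter counts line up", {
  lay <- toy_layout()
  ds <- synthesize_pattern_dataset(lay, hypothesis_spec("H1", qc = 4), 4000,
                                   seed = 21)
  f1 <- fit_recombination(ds, lay, "H1", n_restarts = 6, seed = 22, qmax = 12)
  f2 <- fit_recombination(ds, lay, "H2", n_restarts = 6, seed = 23, qmax = 12)
  expect_equal(f1$k + 1L, f2$k)
  expect_gte(f2$lnL, f1$lnL - 1e-6)
  lrt <- likelihood_ratio_test(f1, f2)
  expect_gte(lrt$chi2, 0)
  expect_lte(lrt$p, 1)
})

test_that("AIC comparison penalises parameters by 2 each", {
  f <- list(hypothesis = "H1", k = 8, lnL = -100, AIC = 216, N = 10)
  g <- list(hypothesis = "H2", k = 9, lnL = -100, AIC = 218, N = 10)
  tab <- compare_aic(list(f, g))
  expect_equal(tab$dAIC, c(0, 2))
  tab2 <- compare_aic(list(f, f))
  expect_equal(tab2$dAIC, c(0, 0))
})

test_that("the likelihood-ratio test uses the 1-df chi-square law", {
  mk_fit <- function(lnL, k) structure(list(lnL = lnL, k = k, N = 100),
                                       class = "xoinv_fit")
  lrt <- likelihood_ratio_test(mk_fit(-50, 8), mk_fit(-50, 9))
  expect_equal(lrt$chi2, 0)
  expect_equal(lrt$p, 1)
  # chi2 = 0.22 corresponds to p about 0.64
  lrt2 <- likelihood_ratio_test(mk_fit(-50.11, 8), mk_fit(-50, 9))
  expect_equal(lrt2$chi2, 0.22)
  expect_equal(lrt2$p, 0.64, tolerance = 0.005)
  expect_error(likelihood_ratio_test(mk_fit(-50, 8), mk_fit(-50, 10)),
               "nested")
})

test_that("parametric bootstrap brackets the generating strength", {
  lay <- chromosome_layout(c("a", "b", "c", "d"), lengths = c(0.3, 0.2, 0.3),
                           karyotype = "homo")
  spec <- hypothesis_spec("H1", qc = 4)
  ds <- synthesize_pattern_dataset(lay, spec, 3000, seed = 31)
  bs <- parametric_bootstrap(ds, lay, "H0", n_boot = 12, n_restarts = 4,
                             seed = 32, qmax = 12)
  expect_equal(nrow(bs$draws) + bs$failed, 12)
  ci_q <- bs$ci[bs$ci$parameter == "qc", ]
  expect_lte(ci_q$lower, ci_q$upper)
  # the interval straddles the point estimate and covers the truth here
  expect_lte(ci_q$lower, bs$fit$qc + 1e-9)
  expect_gte(ci_q$upper, bs$fit$qc - 1e-9)
  expect_true(ci_q$lower <= 4 && ci_q$upper >= 4)
})
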