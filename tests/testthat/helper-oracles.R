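# Independent oracles kept deliberately separate from the package's code
# paths: plain-loop recursions, direct enumeration, and a step-by-step
# phase-walk Monte Carlo.

# renewal coefficients by the textbook double loop
oracle_renewal <- function(gamma, tmax) {
  m <- length(gamma) - 1
  b <- rep(0, tmax + 1)
  b[1] <- 1
  t <- 1
  while (t <= tmax) {
    acc <- 0
    for (a in 0:(t - 1)) {
      g <- t - 1 - a
      if (g <= m) acc <- acc + b[a + 1] * gamma[g + 1]
    }
    b[t + 1] <- acc
    t <- t + 1
  }
  b
}

# Monte-Carlo tally of the one-interval phase transition: starting from phase
# i, walk K ~ Pois(lambda) events event by event (stepping the countdown-to-
# next-chiasma state); returns empirical H and G matrices (no chiasma /
# >= 1 chiasma, by exit phase)
oracle_phase_walk <- function(lambda, gamma, m, n) {
  Hc <- matrix(0, m + 1, m + 1)
  Gc <- matrix(0, m + 1, m + 1)
  for (i in 0:m) {
    K <- rpois(n, lambda)
    cd <- rep(i, n)      # dummy events remaining before the next chiasma
    saw <- rep(FALSE, n)
    for (step in seq_len(max(K, 0))) {
      act <- K >= step
      hit <- act & cd == 0
      if (any(hit)) {
        saw[hit] <- TRUE
        cd[hit] <- sample(seq_along(gamma) - 1L, sum(hit),
                          replace = TRUE, prob = gamma)
      }
      dec <- act & !hit
      cd[dec] <- cd[dec] - 1L
    }
    tal <- function(sel) tabulate(cd[sel] + 1L, nbins = m + 1)
    Gc[i + 1, ] <- tal(saw & cd <= m)
    Hc[i + 1, ] <- tal(!saw & cd <= m)
  }
  list(H = Hc / n, G = Gc / n)
}

# Haldane recombination fraction for a length in Morgans
haldane <- function(l) 0.5 * (1 - exp(-2 * l))

# Conditioned marker-pattern distribution for the no-interference case by
# direct enumeration: subintervals recombine independently with Haldane
# probabilities; keep balanced subpatterns; XOR onto marker intervals.
oracle_haldane_conditioned <- function(sub_len, parent, inner_flags,
                                       n_intervals, condition = TRUE) {
  S <- length(sub_len)
  p_rec <- haldane(sub_len)
  out <- rep(0, 2^n_intervals)
  for (idx in 0:(2^S - 1)) {
    bits <- as.integer(intToBits(idx)[1:S])
    pr <- prod(ifelse(bits == 1, p_rec, 1 - p_rec))
    par_il <- sum(bits[inner_flags == 1]) %% 2
    par_ir <- sum(bits[inner_flags == 2]) %% 2
    if (condition && par_il != par_ir) next
    mk <- 0
    for (k in 1:n_intervals)
      mk <- mk + (sum(bits[parent == k]) %% 2) * 2^(k - 1)
    out[mk + 1] <- out[mk + 1] + pr
  }
  out / sum(out)
}

# log-likelihood by direct per-pattern enumeration over region subpatterns,
# built from the primitive matrices only (no shared code with the
# kronecker/fold path inside the package)
oracle_loglik <- function(counts, chains, omega, gamma, lengths) {
  # chains: list of data.frames (parent, share); counts: full 2^n vector
  n <- round(log2(length(counts)))
  S_sizes <- vapply(chains, nrow, integer(1))
  S <- sum(S_sizes)
  parent <- unlist(lapply(chains, function(d) d$parent))
  region <- rep(seq_along(chains), S_sizes)
  lam <- unlist(lapply(chains, function(d)
    interval_rate(d$share * lengths[d$parent], gamma)))
  probs <- rep(0, 2^n)
  for (idx in 0:(2^S - 1)) {
    bits <- as.integer(intToBits(idx)[1:S])
    pr <- 1
    for (r in seq_along(chains)) {
      sel <- region == r
      pr <- pr * pattern_probability(omega, lam[sel], bits[sel], gamma)
    }
    il <- sum(bits[region == 2]) %% 2   # chains ordered OL, IL, IR, OR
    ir <- sum(bits[region == 3]) %% 2
    if (il != ir) next
    mk <- 0
    for (k in 1:n) mk <- mk + (sum(bits[parent == k]) %% 2) * 2^(k - 1)
    probs[mk + 1] <- probs[mk + 1] + pr
  }
  probs <- probs / sum(probs)
  sum(counts[counts > 0] * log(probs[counts > 0]))
}

# small reusable layouts
toy_layout <- function(lengths = c(0.3, 0.2, 0.25)) {
  chromosome_layout(c("a", "b", "c", "d"), lengths = lengths,
                    left_bp = list(interval = 1, fraction = 0.5),
                    centromere = list(interval = 2, fraction = 0.5),
                    right_bp = list(interval = 3, fraction = 0.5))
}

boundary_layout <- function(lengths = c(0.2, 0.15, 0.25, 0.1)) {
  # breakpoints and centromere exactly at marker boundaries: no splits
  chromosome_layout(c("a", "b", "c", "d", "e"), lengths = lengths,
                    left_bp = list(interval = 2, fraction = 0),
                    centromere = list(interval = 3, fraction = 0),
                    right_bp = list(interval = 4, fraction = 0))
}
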