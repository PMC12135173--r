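---
title: "Counting-model inference for breakpoint-chiasma interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting-model inference for breakpoint-chiasma interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xoinv)
```

## The model

Chiasma interference is modelled by a single-pathway counting process: along
a bivalent, chiasma events are separated by a random number of unobserved
*dummy* events, with the count between consecutive chiasmata drawn
independently from a law $\gamma = (\gamma_0, \ldots, \gamma_m)$.  Under the
*gamma-model* parametrisation the whole law is controlled by one
non-negative, possibly non-integer strength $q$: the dummy count is
$\lfloor q \rfloor$ with probability $1 - \{q\}$ and $\lfloor q \rfloor + 1$
with probability $\{q\}$.  $q = 0$ gives independently placed chiasmata
(Haldane's model); larger $q$ forces chiasmata further apart.  Genetic
length enters through a change of variables to *event space*: an interval of
heterokaryotype length $l'$ Morgans carries an expected
$\lambda = 2\,l' \sum_s (s + 1)\gamma_s$ events (dummy plus chiasma), which
is $2 l' (q + 1)$ under the gamma model.  The factor 2 converts map length
(crossovers per gamete) to chiasmata per bivalent; every chiasma reaches the
sampled chromatid with probability $1/2$ (no chromatid interference).

The *phase* at a chromosomal location is the number of dummy events between
that location and the next chiasma.  Multilocus recombination-pattern
probabilities follow from a chain of phase-transition matrices: $H$ collects
the no-chiasma transitions (a Poisson count of dummy events), $G$ the
at-least-one-chiasma transitions (built from the renewal coefficients $b_t$,
the probability that an event a lag $t$ after a chiasma is itself a
chiasma), and the pattern probability is a row-vector/matrix/column-vector
product starting from the phase law $\Omega$ at the chain origin.
`h_matrix()`, `g_matrix()`, `renewal_coefficients()` and
`chain_pattern_distribution()` expose these pieces; a compiled kernel
carries the same computation inside the fitting loops, and the test suite
pins the two routes against each other to machine precision.

## Pericentric inversion heterokaryotypes

In a heterokaryotype for a pericentric inversion, the centromere blocks the
interference signal (as established for *Drosophila*), so the chromosome
decomposes into four regions that recombine independently: outer-left,
inner-left (left breakpoint to centromere), inner-right (right breakpoint
to centromere) and outer-right.  Each region is evaluated as a chain
starting at its adjoining breakpoint.  Three hypotheses set the starting
phase law $\Omega$ at the breakpoints:

* **H0** — breakpoints block but do not cause interference:
  $\Omega = \pi$, the stationary phase law
  $\pi_i = \sum_{s \ge i}\gamma_s / \sum_s (s+1)\gamma_s$;
* **H1** — breakpoints interfere exactly like chiasmata: $\Omega = \gamma$;
* **H2** — breakpoints interfere with their own strength $q_b$, giving
  $\Omega$ its own gamma-model law.

A gamete is *unbalanced* (inviable) if and only if it is recombinant in
exactly one of the two inner regions.  Observable data are marker
recombination patterns among surviving offspring, so
`marker_pattern_distribution()` enumerates the subinterval patterns of the
four regions, keeps the balanced ones, folds subinterval bits into
marker-interval bits by XOR, and renormalises.  The closed-form sterility
$\zeta = p_1(1 - p_2) + p_2(1 - p_1)$ (with $p_k$ the inner-region
recombination probabilities) is available through `sterility()` and is
bounded by $1/2$.

```{r sterility-example}
g4 <- gamma_from_strength(4)      # the canonical fly interference strength
g0 <- gamma_from_strength(0, m = 0)
c(H1   = sterility(1, 0.5, g4, as.numeric(g4)),
  none = sterility(1, 0.5, g0, 1),
  H0   = sterility(1, 0.5, g4, stationary_phase(g4)))
```

Breakpoint interference (H1) lowers sterility below the no-interference
level, while chiasma-only interference (H0) raises it — the double advantage
that makes breakpoint-chiasma interference adaptive for inversion spread.
This ordering holds in the small-to-moderate length regime (roughly
$I' \le 1$ Morgan at central $\rho$); close to the $1/2$ asymptote the H1
and no-interference curves cross, which the test suite acknowledges by
keeping its ordering grid in the moderate regime.

## Parameters and defaults

| parameter | meaning | unit | default / box |
|---|---|---|---|
| `qc` | chiasma-chiasma interference strength | dummy events | fitted in $[0, 30]$ |
| `qb` | breakpoint-chiasma strength (H2) | dummy events | fitted in $[0, 30]$ |
| `l'_k` | heterokaryotype interval lengths | Morgans | fitted, log scale |
| `d_k`, `d_I` | hetero/homo map ratio | — | derived; `d_I` fitted in $(0,1)$ for sterility |
| `rho` | relative centromere position | — | layout/table input |
| `tol` | series truncation tolerance | probability mass | `1e-12` |

The upper bound 30 on the strengths keeps the chiasma-only boundary
solution of the sterility analysis representable.  Split fractions — where a
breakpoint or the centromere falls strictly inside a marker interval — are
part of the layout configuration, not fitted: the likelihood carries one
length per marker interval, and the default apportioning is 1/2 and 1/2 (or
thirds for a triply split interval).  Regions distal to the terminal markers
are unobservable and marginalise out exactly, so no distal length parameter
exists.

## Numerical choices

* The infinite $t$-sum in the $G$ matrix is truncated adaptively: because
  $b_t \le 1$, the neglected mass is bounded by the Poisson upper tail
  beyond the smallest count still to be added; terms accumulate until that
  tail falls below `tol` (default $10^{-12}$), with a hard cap
  $t \le 10(m+1) + \lambda + 10\sqrt\lambda$ that raises an error rather
  than returning an unconverged sum.
* Phase vectors are sized to the actual support of $\gamma$ and $\Omega$
  ($m = \lfloor \max(q_c, q_b)\rfloor + 1$) rather than padded to a global
  maximum: entries beyond the gamma-model support are exactly zero, so the
  result is identical and each likelihood evaluation stays small.
* All probabilities are computed in linear space (the matrices are small
  and well scaled); the log-likelihood floors each pattern probability at
  $10^{-300}$ before taking logs, so observed patterns with vanishing model
  probability yield a finite, heavily penalised value during optimisation.
* The likelihood is maximised by multi-start Nelder-Mead (the reference
  analysis uses 100 restarts): lengths are searched on the log scale and
  strengths through a scaled logistic onto $[0, 30]$, so the simplex is
  unconstrained.  Starting lengths are Haldane-inverted observed recombinant
  fractions jittered by $U[0.5, 2]$; starting strengths are $U[0, 10]$.
  After the best restart, the simplex is re-launched from the optimum until
  a round improves the deviance by less than $10^{-3}$ (at most 10 rounds),
  which guards against the shrunken-simplex stalls Nelder-Mead exhibits in
  eight or more dimensions.  Interval lengths above 5 Morgans are excluded
  by a smooth penalty: no marker interval approaches that size, and the cap
  keeps the event-space truncation grids small.
* The likelihood omits the multinomial coefficient (constant in the
  parameters); $\Delta$AIC, likelihood-ratio statistics and estimates are
  invariant to this choice.
* Bootstrap intervals read "discard the most extreme 5%" two-sidedly:
  2.5% in each tail of the resampled parameter values.

## The synthetic-data generator

`simulate_gametes()` realises the counting process exactly, in event space:
events form a unit-rate Poisson stream on the cumulative $\lambda$ axis of
each region chain, the first chiasma arrives after an $\Omega$-distributed
number of dummy events and each later one after a $\gamma$-distributed
number, chiasmata are thinned by $1/2$ into crossovers, and balance follows
the inner-parity rule.  Viability is handled by rejection, and the realised
acceptance rate is reported — it estimates $1 - \zeta$ and provides a free
cross-check of the sterility formula.  Because the simulator shares no code
with the matrix computation, it serves as the package's independent oracle:
the suite requires agreement within three binomial standard errors at one
million gametes for unconditioned chains, viability-conditioned marker
distributions and sterility.

What the generator does *not* emulate: real crosses have phenotype-to-gamete
ambiguities, viability differences among recombinant classes beyond the
balanced/unbalanced rule, and finite-oocyte clustering; passing recovery
tests on synthetic data therefore demonstrates correctness of the inference
machinery under the model, not robustness to those departures.

## Identifiability

Two structural flatnesses of the likelihood deserve attention.  First, the
H2 sterility objective depends on $q_b$ only through the starting phase law
of the two inner regions, and many $(q_c, q_b)$ pairs realise the same pair
$(p_1, p_2)$; the H2 optimum ties the H1 optimum and is non-unique, which
`fit_sterility()` reports.  Second, under strong interference the lengths of
subintervals adjacent to a breakpoint are nearly unidentifiable: a chiasma
there requires an improbable burst of events regardless of the length, so
widely different inner-interval lengths produce viable-pattern distributions
a few thousandths apart in total variation.  Finite samples can then favour
modes with badly inflated inner lengths at a gain of one or two log-likelihood
units.  Designs with several subintervals per outer chain (as in the
seven-interval fly crosses) identify $q$ and the outer lengths well; recovery
tests and reported map errors therefore focus on those quantities, and
confidence intervals for inner lengths should be expected to be wide —
consistent with published intervals for centromere-adjacent intervals that
reach zero.

## Problem sizes

The test suite and the acceptance script run everything at sizes chosen to
exercise the full stack on a single core: simulator-versus-analytic checks
at $10^6$ gametes; synthetic crosses of $N = 5000$ to $20000$ surviving
offspring on the seven-interval design; 6-30 Nelder-Mead restarts in tests
(the command-line tool defaults to the reference 100); bootstrap
demonstrations at 12-20 resamples.  A single likelihood evaluation on the
seven-interval heterokaryotype takes a fraction of a millisecond, so a
100-restart fit completes in minutes.

## Limitations

Paracentric inversions (where the interaction of the two breakpoint signals
inside the inversion is unresolved), two-pathway chiasma formation, obligate
chiasmata, chromatid interference and explicit modelling of pericentromeric
negative interference are out of scope; the last is detectable indirectly as
map ratios $d_k > 1$ in intervals holding both a breakpoint and the
centromere.  The published *Drosophila* recombination counts and the
30-inversion sterility table live in journal supplementary material and are
not redistributed here; the acceptance tests that reproduce the published
fits read user-supplied transcriptions from
`inst/extdata/drosophila/` (see the README for the formats).
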