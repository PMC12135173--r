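# xoinv — breakpoint–chiasma interference in pericentric inversion heterokaryotypes

Heterozygous inversion breakpoints suppress chiasma formation in their
vicinity, and one candidate mechanism is that breakpoints interfere with
chiasmata the same way chiasmata interfere with each other.  `xoinv`
implements a single-pathway counting model of chiasma interference for
chromosomes carrying a pericentric inversion in heterozygous state, and the
full inference stack needed to test that hypothesis on recombination and
sterility data — the kind collected in classical *Drosophila melanogaster*
inversion crosses.

## The model in brief

Consecutive chiasmata are separated by a γ-distributed number of unobserved
*dummy* events; under the gamma-model parametrisation a single strength
`q ≥ 0` fixes γ (mass `1 − {q}` on `⌊q⌋` and `{q}` on `⌊q⌋ + 1`; `q = 0` is
the no-interference Haldane limit).  An interval of heterokaryotype length
`l′` Morgans carries `λ = 2 l′ (q + 1)` expected events.  Multilocus
recombination-pattern probabilities follow from phase-transition matrices

    Pr(r) = Ω (∏ₖ Mₖ(rₖ)) 1ᵀ,   M(1) = G/2,  M(0) = G/2 + H,

with `H` the no-chiasma (Poisson dummy) transitions and `G` the
at-least-one-chiasma transitions built from the renewal coefficients of γ.
Because the centromere blocks the interference signal, a pericentric
heterokaryotype decomposes into four regions evaluated independently from
the adjoining breakpoint, with the starting phase law Ω encoding the
competing hypotheses:

* **H0** – breakpoints block but do not cause interference (Ω = π, the
  stationary phase law);
* **H1** – breakpoints interfere exactly like chiasmata (Ω = γ);
* **H2** – breakpoint interference has its own strength `qb`.

Gametes recombinant in exactly one inner region are unbalanced and die, so
observed pattern counts are modelled conditional on viability, and the
closed-form sterility is `ζ = p₁(1 − p₂) + p₂(1 − p₁) ≤ ½`.  Hypotheses are
fitted by multi-start Nelder-Mead maximum likelihood (multinomial), compared
by AIC and a 1-df likelihood-ratio test (H1 ⊂ H2), with parametric-bootstrap
confidence intervals; sterility across many inversions is fitted by least
squares for `(q, d_I)`, where `d_I = I′/I` measures suppression not caused by
breakpoint interference.  An exact event-space meiosis simulator doubles as
the independent test oracle and the synthetic-data generator.

## Worked example

Simulate a cross on the bundled In(3LR)190-style layout (breakpoints in
h–th and cu–bx, centromere in th–cu) at the canonical fly strength `q = 4`,
then ask which hypothesis the data support:

```r
library(xoinv)
lay <- read_layout(system.file("extdata", "layouts", "inversion_190.yaml",
                               package = "xoinv"))
gen <- c(0.162, 0.214, 0.010, 0.007, 0.215, 0.210, 0.113)  # Morgans
ds  <- synthesize_pattern_dataset(lay, hypothesis_spec("H1", qc = 4), 20000,
                                  lengths = gen, seed = 42)
f1 <- fit_recombination(ds, lay, "H1", n_restarts = 20, seed = 1)
f0 <- fit_recombination(ds, lay, "H0", n_restarts = 20, seed = 2)
f2 <- fit_recombination(ds, lay, "H2", n_restarts = 20, seed = 3)
print(f1)
compare_aic(list(f0, f1, f2))
likelihood_ratio_test(f1, f2)
```

```
ML fit, H1 model: lnL = -24674.63, k = 8, AIC = 49365.26
  qc = 3.896  qb = 3.896
  map (cM): ve-h 16.5, h-th 19.5, th-cu 0.0, cu-bx 0.0, bx-e 21.6, e-ro 20.9, ro-ca 11.3
  model k       lnL      AIC      dAIC
1    H0 8 -24688.37 49392.74 27.477539
2    H1 8 -24674.63 49365.26  0.000000
3    H2 9 -24674.62 49367.25  1.984201
LRT H1 vs H2: chi2 = 0.02, p = 0.90
```

The generating hypothesis H1 wins the AIC comparison outright (ΔAIC 27.5
over H0), the strength is recovered (3.90 vs 4), and the outer-interval map
matches the generating lengths to a few tenths of a centiMorgan.  The two
inner intervals pin to zero: lengths of subintervals adjacent to a
breakpoint sit on a near-flat likelihood ridge under strong interference
(see the methods vignette), which is why published confidence intervals for
centromere-adjacent intervals reach zero.  The sterility surface shows the
characteristic ordering at `q = 4`, `I′ = 1`, central centromere:

```r
g4 <- gamma_from_strength(4); g0 <- gamma_from_strength(0, m = 0)
c(H1   = sterility(1, 0.5, g4, as.numeric(g4)),
  none = sterility(1, 0.5, g0, 1),
  H0   = sterility(1, 0.5, g4, stationary_phase(g4)))
#>    H1  none    H0
#> 0.403 0.432 0.485
```

Breakpoint interference makes inversions markedly less sterilising than
they would be with chiasma-only interference.

## Command line

A thin front end over the same functions lives in `inst/scripts/xoinv.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "xoinv.R", package = "xoinv"))')" \
    compare --data counts.tsv --layout inversion_190.yaml \
    --restarts 100 --seed 1 --out results/
```

Subcommands: `fit-recombination`, `compare` (AIC table, LRT, per-interval
maps with `d_k`), `bootstrap`, `fit-sterility`, `simulate`.  All outputs are
TSV, lengths in cM; runs are deterministic given `--seed`.

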