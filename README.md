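# AlignTails

Rare-event estimation of local alignment score distributions for protein
sequence comparison — including the far tail (probabilities below
10⁻⁶⁰) where p-values of interesting database hits actually live.

## What it does, for whom

The significance of a Smith–Waterman score depends on its null
distribution Pr(S = s), which simple sampling of random sequence pairs can
only resolve down to ~10⁻⁴–10⁻⁶. AlignTails is for people calibrating
alignment statistics beyond that: it samples *sequence pairs* with a
Metropolis–Hastings chain whose stationary law is biased by adaptive
score weights (Wang–Landau flat-histogram estimation), then reweights a
fixed-weight production run back to the null model. Any score bin of a
chosen window [S_min, S_max] is visited regularly, so tail probabilities
are estimated with controlled relative error at any depth.

Three null models:

- **RQGS** — two random i.i.d. sequences (the classical
  Karlin–Altschul setting);
- **FQPS** — fixed query, random subject, with a bipartite
  position-specific scheme (a transmembrane-specific matrix on annotated
  helix positions of the query, BLOSUM elsewhere);
- **HMM** — queries drawn from a transmembrane-topology hidden Markov
  model, with a joint estimate Pr(S = s, N_TM = n) per predicted helix
  count (forward algorithm in the acceptance ratio, Viterbi decoding for
  the class).

Estimated distributions are summarised by the modified Gumbel law

log Pr(S = s) = log λ − λ(s − s₀) − λ₂(s − s₀)²,

an extreme-value tail with a Gaussian finite-size correction, from which
p-values (tail sums, analytically continued beyond the window), E-values
(E = N·p) and the amplitude K = exp(λ·s₀)/(L_Q·L_S) are derived.
Per-bin errors come from Flyvbjerg–Petersen blocking; fits are
error-weighted least squares.

## Worked example

Calibrate the classical null (two random length-348 proteins, BLOSUM62,
affine gaps 12/1) in its bulk with simple sampling:

```r
library(AlignTails)
set.seed(1)
model  <- iidModel()                       # SwissProt background
scheme <- scoringScheme(blosum62(), gapOpen = 12L, gapExtend = 1L,
                        gapConvention = "open_plus_len_minus_1")
h <- sampleScoreDistribution(model, scheme, n = 60000, LQ = 348, LS = 348)
bulkLambdaFit(h, LQ = 348, LS = 348)
#> ModifiedGumbelFit: s0 = 30.359, lambda = 0.2639 (+/- 0.0057),
#>   lambda2 fixed at 0, K = 0.02492, reduced chi^2 = 1.22
```

The decay rate λ ≈ 0.264 (per score unit) is the slope of the score law's
exponential flank; published calibrations for this scoring put it near
0.268. Reaching the tail takes the sampler:

```r
win <- scoreWindow(23, 200)
wl  <- wlEstimate(model, scheme, win, LQ = 348, LS = 348,
                  flatCriterion = "roundtrips", minRoundTrips = 2)
h   <- productionRun(model, scheme, win, wl@logW, nSamples = 4e4,
                     LQ = 348, LS = 348, thinning = 8,
                     state = wl@finalState)
est <- reweight(h)                      # probabilities down to ~1e-21
fit <- fitModifiedGumbel(est, LQ = 348, LS = 348)
pValue(fit, 500)                        # ~1e-65 by analytic continuation
```

A YAML-driven pipeline (`readRunConfig()` + `runPipeline()`) wires these
stages together with checkpointing and hash-stamped TSV artifacts; a thin
command-line wrapper lives in `exec/aligntails`. Tiny fully-enumerable
universes (`toyUniverse()`, `exactScoreDistribution()`,
`chainTransitionMatrix()`) provide exact oracles for every stochastic
component — see the vignette for the model, its assumptions and the
numerical choices.

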