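---
title: "Rare-event estimation of local alignment score distributions"
author: "AlignTails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-event estimation of local alignment score distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AlignTails)
```

## The problem

A database search reports a raw Smith-Waterman score $S(x, y)$ for a query
$x$ and subject $y$. The score only becomes interpretable through its null
distribution: the p-value $\mathrm{pval}(s) = \Pr(S \ge s)$ under a model
of unrelated sequences. The scores that matter in practice sit far out in
the right tail — probabilities of $10^{-20}$ to $10^{-70}$ — where direct
("simple") sampling of random sequence pairs can never reach: estimating a
probability of $10^{-9}$ by counting events needs on the order of
$10^{12}$ draws.

AlignTails estimates the *entire* score distribution, including that tail,
by Markov-chain Monte Carlo in the space of sequence pairs combined with
importance sampling. Three null models are supported:

* **RQGS** — both sequences i.i.d. with background amino-acid frequencies
  (the classical setting of Karlin-Altschul statistics);
* **FQPS** — the query fixed, the subject i.i.d.; the natural null for
  position-specific (bipartite) scoring schemes;
* **HMM** — the query drawn from a transmembrane-topology hidden Markov
  model, classified by the number of predicted membrane helices; the
  estimate is then a joint law $\Pr(S = s, N_{\mathrm{TM}} = n)$.

## Sampler

The chain moves through configurations $(x, y)$ with five length-preserving
edits: substitution at a position (probability $1/2$) and four
insert/delete-with-shift moves (probability $1/8$ each); each edit removes
one symbol and introduces a new one drawn from the background frequencies
(or uniformly, for HMM-generated queries). For i.i.d. sequences this
proposal exactly cancels the null-probability ratio in the
Metropolis-Hastings acceptance, so acceptance depends only on the score
weights; for the HMM query the forward-algorithm probability enters the
ratio and the helix class is re-evaluated by Viterbi decoding after every
query edit (subject edits leave the class unchanged and skip the decode).

The chain targets $q(x, y) \propto w(S(x, y), n)\, p(x, y)$. With
$w \approx 1/P$ the score histogram is flat and every score bin of a
window $[S_{\min}, S_{\max}]$ is visited regularly. The weights are
learned by the Wang-Landau iteration: each visit to bin $(s, n)$
multiplies its sampling weight by $1/\phi$ (equivalently, the
density-of-states estimate by $\phi$), with $\phi$ reduced as
$\phi \gets \sqrt{\phi}$ every time the visit histogram is flat, from
$e^{0.1}$ down to $e^{0.0002}$ (nine reduction levels). Flatness means
every bin exceeds 0.6 of the mean bin count; alternatively a level can be
ended after the walker has completed a chosen number of *round trips*
between the window edges — the cheaper criterion used for large windows,
since weight adaptation, not strict flatness, is what matters before the
production phase. Because the adaptive phase violates detailed balance,
all reported estimates come from a subsequent fixed-weight
(detailed-balance) production run, importance-reweighted as
$\hat P(s, n) \propto \mathrm{counts}(s, n)/w(s, n)$, entirely in log
space (the estimates span more than 60 decades).

Numerical choices worth knowing:

* proposals whose score or class leaves the window are rejected and the
  current bin re-counted (the standard flat-histogram boundary rule);
* the initial configuration is drawn from the null model and, if below the
  window, greedily hill-climbed into it;
* Viterbi ties break deterministically towards the lower state index;
* a proposal may redraw the current symbol; it counts as an accepted
  no-op, which preserves detailed balance;
* window bins that remain unvisited when a level exceeds its step budget
  (after the first, purely exploratory level) are treated as unsupported
  under the model and excluded from the flatness test — integer score
  supports can have holes.

Statistical errors are estimated by the Flyvbjerg-Petersen blocking
method: the recorded series is repeatedly halved by pairwise averaging and
the plateau of the naive standard error is the estimate. The plateau is
read as the mean over the levels with 32-128 blocks; shorter series fall
back to the naive error and are flagged.

## The modified Gumbel law

The estimated log-pmf is summarised by
$$\log \Pr(S = s) = \log\lambda - \lambda (s - s_0) - \lambda_2 (s - s_0)^2,$$
an extreme-value (Gumbel) tail with a Gaussian finite-size correction
$\lambda_2 \ge 0$ that matters only far in the tail and vanishes for long
sequences. Fits are weighted least squares with per-bin errors from the
blocking analysis; bins with relative error above 50% are excluded. The
nested pure-Gumbel fit ($\lambda_2 = 0$) is available for comparison and
can never achieve a lower weighted residual sum than the free fit. The
classical amplitude is derived from the fit as
$K = e^{\lambda s_0}/(L_Q L_S)$, the identification that makes
$c = K L_Q L_S$ in the Gumbel form $\Pr(S > s) = 1 - \exp(-c\,
e^{-\lambda s})$ consistent with the centred parameterization above.

Two caveats are built into the fitting interface:

* The formula above omits the Gumbel law's double-exponential factor,
  which is substantial near and left of the peak. `bulkLambdaFit()`
  therefore fits the decay rate on the right flank only, starting at
  $s_0 + 3/\lambda$ (where that factor is below 5%), in two passes, and
  with $\lambda_2$ fixed at zero — on the short score range reachable by
  simple sampling the curvature is collinear with $\lambda$ and not
  identifiable. Full Wang-Landau windows fit both parameters.
* Fits of full windows deliberately mirror the estimation range; when the
  window includes the peak the reduced $\chi^2$ is inflated by the
  near-peak misfit of the parametric form. This is expected and reported,
  not hidden.

p-values are tail sums of the estimated pmf, analytically continued with
the fitted law beyond the estimated window; E-values use the linear
convention $E = N \cdot p$ (indistinguishable from
$1 - (1-p)^N$ at the small p-values of interest, and additive over
database partitions). For subject lengths between simulated grids,
`interpolateParams()` interpolates $\lambda$, $\lambda_2$ and $K$
piecewise-linearly in $L_S$ (variances propagated with the interpolation
weights) and recomputes $s_0$; extrapolation more than 20% beyond the
grid is flagged.

## Scoring scheme

Scores are integer substitution matrices (NCBI tabular format; BLOSUM62
bundled) with affine gaps, optionally bipartite: query positions inside
annotated transmembrane helices use a helix-specific matrix, which is
typically non-symmetric, so symmetry is deliberately not enforced by the
reader. The bundled `tm_synthetic.mat` is a synthetic hydrophobicity-biased
stand-in with the shape of such matrices (non-symmetric, negative expected
score); it is *not* a published matrix.

The gap cost convention deserves a word. "Gap-open 12, gap-extension 1"
is ambiguous: a length-$\ell$ gap may cost $12 + \ell$ or
$12 + (\ell - 1)$. Both conventions are implemented
(`gapConvention = "open_plus_len"` / `"open_plus_len_minus_1"`). The
published BLOSUM62 calibrations with these names (decay rate
$\lambda \approx 0.268$ for random length-348 pairs) are reproduced by the
second convention — the first gapped position costs the full 12 — which
matches BLAST's $(11, 1)$ calibration; the package default follows the
literal "plus a constant" reading, and the calibration scripts set the
convention explicitly.

## The transmembrane HMM layout

The original 216-parameter transmembrane-topology model's probability
values are not redistributable here, so `tmhmmLayout()` assembles the
*architecture* with documented synthetic values (hydrophobicity-biased
emissions, plausible length distributions): membrane helices as a 25-state
core entered at one of 21 depths (core lengths 5-25) between fixed 5-state
caps; loops as two 10-state ladders with early exits around a self-looping
globular state (one cytoplasmic module, short and long non-cytoplasmic
modules); a branch choosing the short or long non-cytoplasmic return path;
and a 3-entry initial distribution. Emissions are tied in seven groups
(helix core, two cap groups, three loop groups, globular); the core-entry
jump distribution is tied across the two helix directions.

`freeParameterCount()` audits the assembled graph and counts one free
parameter per simplex dimension: $7 \times (20-1) = 133$ emissions,
$3 \times 20$ loop transitions, $20$ core-entry jumps, $1$ branch and $2$
initial probabilities — 216 in total, matching the published count. The
counting convention (tied distributions counted once, fixed-length chains
contributing nothing) is part of the package's contract and is what the
introspection helper implements.

## What the synthetic-data generator does and does not show

All tests run on fixtures generated in code: toy alphabets of two or three
symbols with sequence lengths up to six, for which *every* sequence pair
can be enumerated, exact score distributions computed, and the full
Metropolis-Hastings transition matrix assembled. Against these oracles the
suite verifies detailed balance to $10^{-12}$, stationary laws, and
recovery of exact pmfs within blocking errors. Production-scale behaviour
(dynamic ranges of 60+ decades, round-trip times of $10^5$ steps) is
exercised on random protein-length problems, at window sizes chosen so the
whole suite completes in tens of minutes on one core: the calibration
tests sample 30,000 random length-348 pairs for the bulk decay rate and
run one full Wang-Landau + production chain over the score window
[23, 200] (probabilities to $\sim 10^{-21}$), reaching the published
$P(S = 500) \sim 10^{-65}$ by analytic continuation of the fitted law.
What the toys cannot show: real-protein composition effects, the behaviour
of 478-bin windows (mixing times scale with the squared window width), and
toy-scale warm-start timing — on enumerable toys level times are dominated
by histogram fluctuations rather than weight learning, so warm- and
cold-start round-trip times are instead checked on the production-scale
chain against the published dynamics scaled by the squared window width,
within an order of magnitude. At reduced window widths the weight-fill
time no longer dominates the diffusive round-trip time, so the warm-start
effect appears there as an absolute round-trip scale rather than as a
dramatic cold/warm ratio.

## Limitations

* HMM-mode sampling recomputes the forward probability and Viterbi class
  after every query edit ($O(L\,|\Gamma|^2)$); with the full 133-state
  layout this dominates the step cost, as it did in the original study.
* The modified Gumbel form is a heuristic summary; no claim is made about
  the true asymptotic law, and fits including the distribution peak
  report their (expectedly inflated) reduced $\chi^2$.
* The curvature parameter $\lambda_2$ is only identifiable from windows
  extending several hundred score units; reduced windows carry a
  systematic uncertainty of roughly a factor two, reflected in the
  calibration tolerances.
* Flat-histogram sampling assumes the within-bin conditional distribution
  mixes; pathological scoring schemes with strong entropic bottlenecks
  (rare high-score configurations reachable only through rarer ones) mix
  slowly at any weight setting.

## A worked toy session

```{r toy, eval = FALSE}
model <- iidModel(c(A = 0.6, B = 0.4))
mat <- scoringMatrix(matrix(c(2L, -1L, -1L, 1L), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B"))))
scheme <- scoringScheme(mat, gapOpen = 1L, gapExtend = 1L)
win <- scoreWindow(0, 4)

wl <- wlEstimate(model, scheme, win, LQ = 2, LS = 2)
hist <- productionRun(model, scheme, win, wl@logW, nSamples = 1e5,
                      LQ = 2, LS = 2, thinning = 5L,
                      state = wl@finalState)
est <- reweight(hist)
exp(est@logProbMarginal)   # compare with exactScoreDistribution()
```
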