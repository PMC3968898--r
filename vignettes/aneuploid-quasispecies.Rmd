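---
title: "Aneuploid quasispecies: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aneuploid quasispecies: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuqs)
```

## The model

Classical quasispecies theory describes a population of replicators whose
per-symbol copying error rate determines whether a fittest ("master")
sequence can maintain itself at mutation–selection balance. The dynamics of
the relative frequency $x_m$ of type $m$ follow the replicator–mutator
equation

$$\frac{dx_m}{dt} = (W_{mm} - \bar E(t))\,x_m + \sum_{k \ne m} W_{mk} x_k,$$

with $W_{mm} = Q_{mm}A_m - D_m$ (growth rate $A_m$, death rate $D_m$,
probability of precise reproduction $Q_{mm}$), $W_{mk}$ the rate of
production of type $m$ by erroneous reproduction of type $k$, and
$\bar E(t)$ the population-mean excess production $\sum_k (A_k - D_k)x_k$
acting as a dilution flux that keeps $\sum_k x_k = 1$. At steady state, and
neglecting inflow from other types, the master persists iff
$\bar\sigma_m Q_{mm} > 1$, where $\bar\sigma_m = A_m/(D_m + \bar E_{k\ne m})$
is its superiority over the average competitor. With $Q_{mm} = \bar q^{\,v}$
for a length-$v$ sequence, this yields the error threshold
$\ln\bar\sigma_m / v \ge 1 - \bar q$.

`aneuqs` transplants this machinery from nucleotide sequences to
karyotypes. The *chromosomal master sequence* is the collection of
physically distinct whole or fragmented chromosomes of a cell; its length
$c_m$ is the **sum of copy numbers** over declared chromosome units (46 in
a normal diploid human cell). The per-symbol error is the *aneuploidy
rate* $E = 1-\bar A$: the probability that a given chromosome copy is not
reproduced exactly once per division. Exact reproduction of the whole
karyotype then has probability $Q_{mm} = \bar A^{c_m}$, and substituting
into the threshold gives the *aneuploid error threshold*

$$T = \frac{\ln \bar\sigma_m}{c_m} \;\ge\; 1 - \bar A_m .$$

At the karyotype level the numbers land in an interesting regime: with
$\bar\sigma \in [10^2, 10^3]$ and $c_m \approx 10^2$ the bound is of order
$10^{-2}$, inside the empirically measured per-chromosome missegregation
range of chromosomally unstable cancer cells ($10^{-3}$–$10^{-1}$). The
same arithmetic applied at the nucleotide level fails dramatically for
mismatch-repair-deficient (MSI) tumours — their elevated point-mutation
rates violate the nucleotide bound by orders of magnitude, yet such
tumours exist — which is the motivation for moving the quasispecies to the
karyotype level in the first place (`msiViabilityReport()` tabulates this
inconsistency over the standard constant grid in `regimeDefaults()`).

```{r thresholds}
aneuploidThreshold(1e2, 1e2)     # ln(100)/100
aneuploidThreshold(1e3, 1e2)
```

## The per-copy replication kernel

The analytic theory only fixes the aggregate fidelity
$Q_{mm} = \bar A^{c_m}$. To obtain full karyotype-to-karyotype transition
probabilities we complete it minimally: each chromosome copy,
independently, is inherited exactly once with probability $1-E$; with
probability $E$ it is either duplicated in the daughter (probability
`gainBias`, default 0.5 — symmetric missegregation) or dropped. Per-unit
counts then convolve a trinomial over the parental copies, and the full
kernel is the product over units. Two consequences worth knowing:

* the *no-error path* has probability exactly $(1-E)^{c_m}$, matching
  `replicationFidelity()`; but the *diagonal* transition
  $P(\text{parent}\to\text{parent})$ can exceed it, because a gain and a
  loss of the same unit in one division cancel;
* on a truncated state space (`enumerateKaryotypeSpace()` caps copies at
  `maxCopy`), columns of the transition matrix are deliberately
  sub-stochastic: the deficit is reported as escape mass, never
  renormalized, since renormalization would silently inflate fidelity.
  In the ODE the dilution flux is the realized production $\sum_m (Wx)_m$,
  which treats escaped offspring as dead and is the only choice that keeps
  trajectories on the simplex.

## Numeric threshold detection: two routes

`thresholdScan()` computes the stationary master frequency (dominant
eigenvector of $W$, deterministic LAPACK path, no randomized solvers) on a
grid of error rates and reports two operational readings of the collapse
point: the first grid point where the master frequency falls below the
neutral expectation $1/(\text{number of viable states})$ (headline), and
the steepest-descent point. The scan offers two model routes, and the
difference between them is scientifically meaningful:

* **exact** — full enumerated dynamics. This keeps *every* return path
  into the master. In low-dimensional unit sets (a single unit with many
  copies) return flux is large: a one-step neighbour reverts with
  probability $\mathcal{O}(nE)$, and within-unit cancellations inflate the
  diagonal. The master then delocalizes slowly or not at all, and the scan
  honestly reports an absent threshold. This is not a numerical artifact:
  a sharp error threshold requires back mutation to be negligible.
* **error-class** — states binned by L1 distance from the master, new
  defects per division Binomial($c_m$, $E$), back mutation neglected, and
  the last class absorbing (columns remain stochastic). This is precisely
  the separability regime in which the threshold formula is derived: when
  defects can hit many distinct units, reverting to the exact master
  configuration is vanishingly unlikely. On this route the master
  frequency follows the classical $(\bar\sigma Q - 1)/(\bar\sigma - 1)$
  form and collapses sharply at $\bar\sigma(1-E)^{c_m} = 1$, so the
  detected threshold converges to $\ln\bar\sigma/c_m$ as $c_m$ grows (the
  suite checks $c_m \in \{10, 20, 46\}$, all within 25% of the analytic
  bound). The class route cannot track nullisomy, which is a within-class
  property.

```{r scan}
scan <- thresholdScan(NULL, karyotype(46L, defaultUnits(1)),
    seq(0.005, 0.05, length.out = 40), AMaster = exp(1), AMutant = 1,
    method = "error-class")
scan
```

Other numerical contracts: the integrator (`deSolve::lsoda`,
`rtol = 1e-10`, `atol = 1e-12`) must stay within $10^{-8}$ of the simplex
or it errors; the dominant eigenpair must be real and sign-consistent
within $10^{-8}$ relative tolerance or a degeneracy error is raised;
stationary/ODE agreement is asserted at $10^{-6}$ total variation on
random instances of up to 125 states.

## Superiority: a deliberate normalization

We define $\bar E_{k\ne m}$ as the *competitor-frequency-normalized* mean
excess production, $\sum_{k\ne m}E_k x_k / \sum_{k\ne m} x_k$. The
unnormalized sum appears in some presentations, but it vanishes (and the
superiority diverges) as competitors disappear; the normalized form is the
standard quasispecies definition, dimensionally stable, and invariant to
rescaling all rates by a common constant. For a single-peak landscape with
uniform death rate it reduces to $A_{\text{master}}/A_{\text{mutant}}$
independent of the population state.

The exact threshold form $E \le 1 - \bar\sigma^{-1/c_m}$ is available via
`exact = TRUE`; the linearized $\ln\bar\sigma/c_m$ is the default output
because it is the form in which the bound is usually quoted. They agree to
first order in $E$ (within 5% for $E \le 0.05$, $c_m \le 200$) and the
difference only matters near the threshold.

## The synthetic two-site generator

`generateTwoSiteDataset()` emulates the observational setting behind the
adaptive-aneuploidy argument: a primary tumour population grown from a
single founder clone, and a metastasis grown from one viable aneuploid
cell of that primary population, with the two sites evolving at different
per-copy error rates. The simulator is Wright–Fisher (non-overlapping
generations, fitness-weighted multinomial parent sampling) — cheaper than
a Moran process and equivalent for our purposes, since nothing here
depends on overlapping generations. Cells that lose all copies of a unit,
or exceed `maxCopy = 8` copies of any unit, get fitness zero: nullisomy of
an essential chromosome is not viable, and treating above-cap cells as
lethal rather than clipping them avoids silently distorting the copy
distribution.

Reference study conditions (the package defaults): diploid founder over 23
whole-chromosome units ($c_m = 46$), populations of $N = 500$ cells, 12
generations per site, 100 cells sampled per site,
$E_{\text{primary}} = 0.02$ and $E_{\text{metastatic}} = 0.1$ — a ratio of
5 with both rates inside the measured cancer range. No published
population sizes or generation counts exist for this setting, so these
were chosen once for detectability of the rate contrast (the generator's
stated purpose), not for biological fidelity: longer histories let
boundary effects (nullisomy lethality acting as a reflecting barrier)
drift the high-rate population upward and flatten its content
distribution, which degrades every summary statistic while adding no
information about the rate contrast. Everything is reproducible
byte-for-byte from the seed, and the truth metadata records the generating
parameters for recovery tests.

What the generator does *not* emulate: measurement noise of single-cell
CNV calling, stromal contamination beyond an optional diploid spike-in,
dissemination timing (parallel vs linear progression), whole-genome
doubling as a distinct event, and focal breakpoints below the declared
unit resolution. Passing tests on this generator therefore demonstrate
properties of the inference machinery under the stated model, not claims
about any real tumour.

## Population statistics: choices and honest caveats

* **Variance test.** Brown–Forsythe (absolute deviations from group
  *medians*, one-way F) is the default variant: the distance
  distributions karyotype evolution produces are right-skewed, and median
  centering is robust to that. A label-permutation p-value
  ($p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})$) is available and agrees
  with the F approximation within Monte-Carlo error on Gaussian data. On
  Gaussian nulls the F approximation holds its nominal size
  (the suite checks $0.05 \pm 0.01$ at $\alpha = 0.05$ over $10^4$
  replicates).
* **Clonal pseudoreplication.** On *simulated tumour samples* the
  variance test is anti-conservative even when both sites evolve at the
  same rate, because cells within a site share Wright–Fisher genealogy
  and their root distances are positively correlated — the effective
  sample size is far below the cell count. This is a property of the data
  structure, not of the test, and it equally affects variance comparisons
  on real single-cell trees. The pipeline suite therefore asserts the
  monotone dose–response of the rejection rate with the rate ratio rather
  than nominal size at ratio 1, and between-site conclusions should be
  read as "the contrast is detectable", not as calibrated p-values.
* **Root profiles.** The headline analysis measures distances to a
  *common* root (the founder when known, else the pooled integer median
  profile). A common root conflates the metastatic clone's fixed offset
  from that root with its dispersion; per-site centering is available by
  passing an explicit root per site via `distanceToRoot()`.
* **Ploidy tails.** `ploidyTailWeight()` reports the fraction of cells
  beyond $(1+\delta)$ times the ploidy peak, $\delta = 0.2$ by default.
  The peak is located by the *median* rather than a histogram mode: on
  discrete, sometimes plateaued content distributions the
  Freedman–Diaconis mode is erratic (a one-bin shift moves the tail
  boundary by a whole bin), while the median is stable; the FD-mode
  variant (with Sturges fallback for zero IQR) remains available via
  `peak = "mode"`. Ties between equally tall bins resolve to the
  lowest-content bin.
* **Rate estimator.** $\hat E$ divides the summed parent–child L1 change
  by the summed parental copies, with a Wilson score interval. It is a
  *lower bound*: a gain and a loss of the same unit in one division
  cancel in the L1 count. At $E = 0.02$ on diploid parents the bias is
  about 1% relative and the 95% interval covers the truth in $\ge 93\%$
  of replicates.

## Problem sizes

The test suite and the acceptance script run exact dynamics on spaces of
at most 125 states, defect-class scans up to $c_m = 100$, Gaussian
calibration at $10^4$ (suite) / $2\times10^3$ (script) replicates,
estimator recovery at $10^4$ parental copies, and 200 (suite) / 100
(script) two-site replicates at the reference study conditions. These
sizes were chosen so the whole analysis reruns from scratch in minutes on
one core while keeping Monte-Carlo error well inside the asserted
margins.

## Known limitations

The unit set is frozen at configuration time — fragments arising *during*
evolution do not enlarge it (declare arms as units up front if arm-level
events matter). The error model is i.i.d. per copy; copy-number-dependent
missegregation, whole-genome doubling and chromothripsis are out of
scope. The error-class scan neglects back mutation by construction and
should not be used to study regimes where return flux matters (few units,
many copies — use the exact route there and expect a soft transition).
Superiority values are inputs, never inferred from data.
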