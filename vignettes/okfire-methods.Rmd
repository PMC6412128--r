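---
title: "Models and methods behind okfire"
author: "okfire authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind okfire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okfire)
```

## The replication model

Okazaki fragments (OFs) are synthesized on the lagging strand, so
strand-specific OF sequencing reads out, per genomic position, the fraction
of cells in which that position was replicated by a rightward- versus
leftward-moving fork. okfire models this signal over a *triplet* of
neighbouring replication origins $O_1 < O_2 < O_3$ at positions
$x_1, x_2, x_3$ (0-based bp), with inter-origin distances $N_1 = x_2 - x_1$
and $N_2 = x_3 - x_2$.

In each cell cycle:

* origin $i$ is **licenced** with probability $q_i$ (independently across
  origins and cells);
* a licenced origin has a potential **firing time**
  $t_i \sim N(\mu_i, \sigma_i^2)$;
* forks move at a common constant speed, so time is measured in
  **replicated base pairs** (rbp): 1 rbp is the time a fork needs to copy
  1 bp. Physical time enters only at reporting, through a fork velocity
  $\nu$ (kb/min);
* a licenced origin is **obscured** (passively replicated) if a fork from a
  neighbour reaches it before it fires; an origin is **realized** — actually
  produces bidirectional forks — iff it is licenced and not obscured;
* converging forks from adjacent realized origins $i < j$ terminate at the
  collision point $x_{ij} = (x_i + x_j + t_j - t_i)/2$.

No forks enter from outside the triplet (a stated model assumption), so the
end origins can only be obscured from the inside: $O_1$ from the right,
$O_3$ from the left.

A single cell yields a binary profile over the region — 1 where a
rightward fork replicated the position — and the population profile
$F^{ave} = \frac{1}{M}\sum_k F^k$ averages $M$ such cells. Cells in which a
single end origin's forks overrun the whole region produce a constant
profile indistinguishable from background; these *double-overrun* states
(together with cells in which no origin fires) are prohibited and the
generator resamples them. This is exact rejection conditioning of the
generative model on admissible states; such states are rare in all regimes
of interest, and the parameter updates of the sampler ignore the resulting
normalization constant $Z(\theta)^{-M}$ (its effect is correspondingly
negligible, but it is a declared approximation, not an oversight).

Only firing-time *differences* are observable, so $\mu$ is recentred to
$\sum_i \mu_i = 0$; `firingParams()` enforces this and the sampler recentres
after every sweep (subtracting the same constant from all latent times,
which leaves every profile unchanged).

## Observation model

The data are strand-specific counts summed into $s_{box} = 50$ bp boxes over
$[x_1, x_3)$ and locally normalized (see below). The model for normalized
box counts is

$$X^f_j \sim \big((1-b)\,F^{ave}_j + \tfrac{b}{2}\big)\,
  e^{N(-\frac{1}{2\tau},\, \frac{1}{\tau})}, \qquad
  X^r_j \sim \big((1-b)(1-F^{ave}_j) + \tfrac{b}{2}\big)\,
  e^{N(-\frac{1}{2\tau},\, \frac{1}{\tau})},$$

independently across boxes and strands. Here $b \in [0,1]$ weights a uniform
random-fragmentation background and $\tau$ is the precision of multiplicative
log-normal measurement noise, constructed with mean $-\tfrac{1}{2\tau}$ so
that the noise factor has unit mean and $E[X^f_j + X^r_j] = 1$. One $(b,
\tau)$ pair is shared by both strands; a per-strand generalization changes
the other posteriors negligibly and is not implemented. Expected intensities
conserve $m^f_j + m^r_j = 1$ exactly per box.

Because the log-normal density is undefined at zero, normalized counts of
zero are floored at half the smallest positive count in the region before
the likelihood is evaluated (`floorCounts()`); how the reference analysis
handled zero boxes is not stated anywhere we could rely on, so this is a
declared package choice. Residual autocorrelation across boxes is not
modelled; boxes are treated as independent, as in the counts model above.

## Preprocessing

`readStrandedCoverage()` ingests one bedGraph per strand (0-based,
half-open). Coverage is assumed to come from alignments already filtered to
mapping quality > 10, with paired-end fragments length-filtered to the OF
window 120–200 bp (`filterFragments()`, both bounds inclusive); alignment
itself is out of scope. The chromosome-wide strand bias
$b_{chr} = \sum_i c^f_i / \sum_i c^r_i$ corrects the reverse strand, and
`boxAndNormalize()` divides box sums by $s_{box}\, n$ with

$$n = \frac{1}{x_3 - x_1} \sum_{i = x_1}^{x_3 - 1} (c^f_i + b_{chr} c^r_i),$$

so that the mean of (forward + reverse) normalized counts over boxes is 1.
The per-bp window for $n$ is taken half-open, $[x_1, x_3)$, consistent with
every other coordinate convention in the package; this makes the
normalization identity exact whenever $x_3 - x_1$ is a multiple of
$s_{box}$ (an inclusive-endpoint window would leave a systematic
$O(1/(x_3-x_1))$ defect). A trailing partial box is dropped, matching the
$\lfloor (x_3-x_1)/s_{box} \rfloor$ box count. When overlapping triplets of
a four-origin window are compared, `normRange` normalizes both runs by the
common $n(O_1, O_4)$.

## Posterior sampling

The latent state is the full population: per cell, the licenced set and the
firing times of licenced origins. The model dimension therefore varies with
the number of licenced origins, which is handled by a reversible-jump
sampler. Each sweep performs:

1. **Firing-time updates** — Gaussian random-walk proposals on $t_i$ for a
   fraction (default 10%) of cells; the likelihood change is evaluated only
   on boxes whose profile value changed. Proposals that create a prohibited
   cell are rejected (conditioning on admissibility).
2. **Licencing birth/death** — toggling one origin's licence in one cell.
   Birth proposes the new firing time from its conditional prior
   $N(\mu_i, \sigma_i^2)$, so the Jacobian is 1 and the acceptance ratio is
   $\frac{q_i}{1-q_i}$ (death: its inverse) times the likelihood ratio.
3. **Conjugate Gibbs updates** — $\mu_i \mid t \sim N(\bar t_i,
   \sigma_i^2/n_i)$ (flat prior), $\sigma_i^2 \mid t \sim$
   InverseGamma$(0.01 + n_i/2,\; 0.01 + \tfrac12\sum (t-\mu_i)^2)$,
   $q_i \mid$ licencing counts $\sim$ Beta$(1 + L_i,\; 1 + M - L_i)$.
4. **Group moves** — two non-centred Metropolis moves per origin that break
   the slow coupling between the firing-time hyperparameters and the latent
   times: a *rescaling* move $\sigma_i' = \sigma_i e^\varepsilon$ with all of
   origin $i$'s times rescaled about $\mu_i$ (the time-prior terms and the
   Jacobian collapse to $-2a\varepsilon - b(\sigma_i'^{-2} -
   \sigma_i^{-2})$ plus the likelihood ratio), and a *translation* move
   shifting $\mu_i$ and all of origin $i$'s times together (acceptance =
   likelihood ratio). Without these, $\hat R$ for $\sigma$ stays well above
   1.1 at any feasible run length because $\sigma_i$ can only track the
   slowly-diffusing spread of the latent times.
5. **Noise updates** — Metropolis on $\log \tau$ (Gamma(0.01, 0.01) prior)
   and on $\mathrm{logit}\, b$ (uniform prior), with the appropriate
   Jacobians.
6. **Recentring** of $\mu$ and all latent times to $\sum_i \mu_i = 0$.

Proposal scales adapt toward 30% acceptance by Robbins–Monro during burn-in
only and are frozen afterwards, preserving the stationary distribution. The
incremental per-box tallies of the latent profile are audited against a
from-scratch recount every 1000 sweeps (exact integer match, enforced in the
sampler itself).

The sampler is validated two ways rather than by claiming move-for-move
fidelity to any reference implementation: on a toy instance (8 cells, 2
boxes, only the middle origin's licencing unknown) the MCMC marginal of
$q_2$ matches a brute-force discretized posterior to within 0.02 total
variation; and a replicated simulation study checks that 95% credible
intervals cover the generating parameters at the nominal rate.

**Convergence** uses multiple chains and the Gelman–Rubin statistic
$\hat R = \sqrt{((n-1)W/n + B/n)/W}$ with threshold 1.1 on all of
$\{\mu_i, \sigma_i, q_i, b, \tau\}$; degenerate posteriors (e.g. $q$ pinned
at 1) are reported as such rather than given an $\hat R$.

## Defaults and problem sizes

* $M = 4992$ cells is the production population size (`simConfig()`
  default); the sampler's desk-scale default is $M = 512$ with a message
  noting that small $M$ discretizes the profile in steps of $1/M$.
* $s_{box} = 50$ bp throughout; histograms of collision points use the same
  bin width.
* The test-suite recovery study uses a staggered-firing truth (differences
  700 and 300 rbp, $\sigma$ of 100–264 rbp over 1300 bp spacings,
  $q = (0.95, 0.8, 0.95)$, $b = 0.1$, $\tau = 10$), $M = 512$, 3 chains of
  20&nbsp;000 sweeps (10&nbsp;000 burn-in), and 4 replicate data sets — sizes
  chosen so the whole study reflects a realistic desk-scale analysis; the
  full-scale protocol (burn-in and retention of $10^5$ sweeps each,
  $M = 4992$) is what the defaults document.
* Fork velocity for replication-time reporting: $\nu = 1.6$ kb/min is the
  reference value for budding yeast, 3.3 kb/min for human cells.

## Numerical choices

* Boxes are evaluated at their midpoints against the piecewise-constant
  single-cell profile; breakpoints are therefore localized to within
  $s_{box}/2$, which is cheaper than exact fractional overlap and
  immaterial at 50 bp resolution.
* A fork arriving exactly at an origin's firing time counts as obscuring
  (a probability-zero tie for continuous times); a box midpoint exactly at
  a collision point belongs to the leftward fork, matching the half-open
  $[{\rm origin},\, {\rm collision})$ convention.
* Quantiles and quartiles use linear interpolation (R's type 7).
* `estimateTau()` initializes $\tau$ from first differences of log counts
  ($\mathrm{var}(\Delta \log c) \approx 2/\tau$ when the profile varies
  slowly relative to the box width).
* Degenerate parameter regimes in which admissible cells are vanishingly
  rare (e.g. $q = (1, 0, 0)$) are detected by a rejection-count guard and
  raised as errors.

## What the synthetic data do and do not emulate

The generator reproduces the model faithfully: Bernoulli licencing, Gaussian
firing, equal-speed forks, passive collision, prohibition of double-overrun
states, unit-mean log-normal noise and uniform background. Real OK-seq data
additionally contain features outside the model — origin-position error,
fork-speed variability, copy-number and mappability artefacts, residual
autocorrelation between neighbouring boxes, and forks entering from outside
weak end origins. Passing tests therefore certify the inference machinery
under the model's own assumptions, not robustness to these violations;
choosing triplets with strong end origins is what justifies the no-external
-forks assumption in practice.

## Known limitations

* **Licencing vs obscuring is not always identifiable.** When an origin's
  realized-firing fraction is near zero, "rarely licenced" and "licenced but
  always obscured (late $\mu$)" produce identical profiles, and under the
  flat $\mu$ prior the posterior can wander along this ridge: $q_i$ is then
  unidentified even though the realized fraction — the quantity the data
  actually constrain — is pinned near zero. Summaries therefore report
  realized and obscuring fractions alongside $q$, and conclusions about
  weak origins should be drawn from those. The same confusion arises in
  real analyses when a triplet lacks the information to separate the two
  explanations.
* At most three origins per analysis unit; longer stretches are analysed as
  overlapping triplets and compared on their overlap.
* Constant fork speed; no fork stalling; no external incoming forks; no
  count-based (Poisson/negative-binomial) observation model.
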