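# okfire

Bayesian inference of DNA replication-origin firing statistics from
Okazaki-fragment (OK-seq) sequencing profiles.

## The problem

DNA replication starts at origins that must be licenced in G1 and then fire
stochastically in S phase. Strand-specific sequencing of Okazaki fragments
measures, at every genomic position, the fraction of cells in which that
position was replicated by a leftward- versus rightward-moving fork. Over a
triplet of neighbouring origins `O1 < O2 < O3` this profile is shaped by
three quantities per origin *i*:

- the licencing probability `q_i`,
- the Gaussian firing-time distribution `t_i ~ N(mu_i, sigma_i^2)` (in rbp,
  replicated base pairs — time units under a constant fork speed), and
- **origin obscuring**: a licenced origin is passively replicated, and
  inactivated, when a neighbour's fork arrives before it fires.

Both partial licencing and obscuring shrink the step in the profile at an
origin (the step equals the fraction of cells in which the origin actually
produces forks), so separating them requires fitting the full stochastic
model. okfire does this with a reversible-jump MCMC sampler over the model
parameters *and* the per-cell latent states (licenced sets, firing times),
using an approximate likelihood for boxed strand counts:

```
X_j^f ~ ((1-b) F_j + b/2) * exp(N(-1/(2 tau), 1/tau))
X_j^r ~ ((1-b)(1-F_j) + b/2) * exp(N(-1/(2 tau), 1/tau))
```

where `F_j` is the M-cell average profile at 50-bp box `j`, `b` weights a
uniform random-fragmentation background and `tau` is the precision of the
unit-mean log-normal measurement noise. Outputs include posterior quartiles
of licencing and directed obscuring rates, fork collision-point densities,
firing-time-difference densities, Gaussian firing-order probabilities
`pi(t_{i+1} < t_i)` and reconstructed median replication times.

It is aimed at researchers analysing OK-seq / OF-seq data in yeast or human
cells who have strand-specific coverage tracks and a list of origin
positions.

## Worked example

Simulate a partially licenced middle origin (`q2 = 0.3`, equal firing
times — the weak-origin scenario) and re-infer its parameters:

```r
library(okfire)

trip   <- originTriplet(c(200, 1500, 2800), chrom = "chrVII")
truth  <- firingParams(mu = c(100, 100, 100), sigma = c(100, 100, 100),
                       q = c(1, 0.3, 1))
prof   <- averageProfile(truth, trip, simConfig(M = 512, seed = 1))
counts <- generateCounts(prof, noiseParams(b = 0.1, tau = 10), seed = 2)

fit <- samplePosterior(counts, trip,
         mcmcConfig(nChains = 3, M = 512, nSweeps = 20000,
                    burnIn = 10000, thin = 10, seed = 3))
fit
#> ChainSet: 3 chains x 1000 retained samples (M = 512 cells)
#>   Gelman-Rubin R-hat: max 1.019 (converged at 1.1 threshold)

summarizeLicencing(fit)
#>   origin     lower    median     upper
#> 1     O1 0.9960525 0.9979696 0.9991460
#> 2     O2 0.3326837 0.3644552 0.4005998
#> 3     O3 0.9956066 0.9978367 0.9991365
```

The licencing posterior of the middle origin concentrates near the
generating value 0.3 while the strong end origins are pinned at ~1
(quartiles are reported because these distributions are typically skewed).
Firing order and replication timing follow from the same fit:

```r
s   <- posteriorSamples(fit)
med <- apply(s, 2, median)
probFiresEarlier(med["mu2"] - med["mu1"],
                 sqrt(med["sigma1"]^2 + med["sigma2"]^2))
#> 0.32   # pi(t2 < t1): near-simultaneous firing, as simulated

medianReplicationTime(firingParams(med[1:3], med[4:6], med[7:9]),
                      trip, nu = 1.6)  # yeast fork speed, kb/min
#> ReplicationTimeProfile: 52 boxes, nu = 1.6 kb/min, anchor = 0 min
#>   median time range [0.02, 0.81] min
```

Real data enter through `readStrandedCoverage()` (a bedGraph per strand),
`strandBias()` and `boxAndNormalize()`; fragment BED files can be length
filtered to the 120–200 bp Okazaki window with `filterFragments()`. A thin
command-line wrapper with `simulate | preprocess | infer | summarize`
subcommands lives at `inst/cli/okfire.R`:

```sh
Rscript inst/cli/okfire.R simulate --config sim.yaml --seed 1 --out out/
```

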