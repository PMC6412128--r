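#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core S4 classes. All genomic coordinates are 0-based; boxes are half-open
# [start, start + sBox). Firing times are in rbp (replicated base pairs):
# with fork speed fixed at 1 bp per time unit, 1 rbp is the time a fork needs
# to replicate 1 bp.
# ---------------------------------------------------------------------------

#' OriginTriplet: three neighbouring replication origins
#'
#' Holds the genomic positions of three consecutive replication origins
#' \eqn{O_1 < O_2 < O_3} on one chromosome. The inter-origin distances
#' \eqn{N_1 = x_2 - x_1} and \eqn{N_2 = x_3 - x_2} set the obscuring
#' thresholds of the fork-collision model: a fork from a neighbour at distance
#' \eqn{N} obscures an origin whose firing is delayed by more than \eqn{N} rbp.
#'
#' @slot positions numeric(3), strictly increasing 0-based coordinates in bp.
#' @slot originNames character(3), origin labels.
#' @slot chrom character(1), chromosome identifier.
#' @export
setClass("OriginTriplet",
  representation(positions = "numeric", originNames = "character",
                 chrom = "character"))

setValidity("OriginTriplet", function(object) {
  p <- object@positions
  if (length(p) != 3L) return("positions must have length 3")
  if (any(!is.finite(p)) || any(p < 0)) return("positions must be finite and >= 0")
  if (!all(diff(p) > 0)) return("positions must be strictly increasing (x1 < x2 < x3)")
  if (length(object@originNames) != 3L) return("originNames must have length 3")
  if (length(object@chrom) != 1L) return("chrom must be a single string")
  TRUE
})

#' FiringParams: per-origin firing-time and licencing parameters
#'
#' Gaussian firing-time means \code{mu} and standard deviations \code{sigma}
#' (both in rbp) and per-cell-cycle licencing probabilities \code{q} for the
#' three origins of a triplet. Only firing-time differences are identifiable
#' from strand profiles, so \code{mu} is stored recentred to sum to zero.
#'
#' @slot mu numeric(3), firing-time means in rbp, sum(mu) == 0.
#' @slot sigma numeric(3), positive firing-time s.d. in rbp.
#' @slot q numeric(3), licencing probabilities in [0, 1].
#' @export
setClass("FiringParams",
  representation(mu = "numeric", sigma = "numeric", q = "numeric"))

setValidity("FiringParams", function(object) {
  if (length(object@mu) != 3L || length(object@sigma) != 3L || length(object@q) != 3L)
    return("mu, sigma and q must each have length 3")
  if (any(!is.finite(object@mu))) return("mu must be finite")
  if (abs(sum(object@mu)) > 1e-6 * max(1, max(abs(object@mu))))
    return("mu must sum to zero (use firingParams() which recentres)")
  if (any(!is.finite(object@sigma)) || any(object@sigma <= 0))
    return("sigma must be positive")
  if (any(is.na(object@q)) || any(object@q < 0) || any(object@q > 1))
    return("q must lie in [0, 1]")
  TRUE
})

#' SimConfig: population-simulation settings
#'
#' @slot M integer(1), number of cells averaged into the population profile.
#' @slot sBox numeric(1), box width in bp.
#' @slot seed integer(1), RNG seed (NA = use the current RNG state).
#' @slot maxResample integer(1), rejection-sampling guard per cell.
#' @slot strandConvention logical(1), TRUE maps rightward-moving forks to
#'   forward-strand Okazaki-fragment synthesis (profile value 1).
#' @export
setClass("SimConfig",
  representation(M = "integer", sBox = "numeric", seed = "integer",
                 maxResample = "integer", strandConvention = "logical"))

setValidity("SimConfig", function(object) {
  if (object@M < 1L) return("M must be >= 1")
  if (object@sBox < 1) return("sBox must be >= 1")
  if (object@maxResample < 1L) return("maxResample must be >= 1")
  TRUE
})

#' NoiseParams: observation-model parameters
#'
#' The boxed strand counts are modelled as the expected strand intensity times
#' unit-mean multiplicative log-normal noise \code{exp(N(-0.5/tau, 1/tau))},
#' mixed with a uniform random-fragmentation background of weight \code{b}.
#'
#' @slot b numeric(1), background weight in [0, 1].
#' @slot tau numeric(1), log-normal precision (> 0); var(log noise) = 1/tau.
#' @export
setClass("NoiseParams", representation(b = "numeric", tau = "numeric"))

setValidity("NoiseParams", function(object) {
  if (length(object@b) != 1L || is.na(object@b) || object@b < 0 || object@b > 1)
    return("b must be a single value in [0, 1]")
  if (length(object@tau) != 1L || is.na(object@tau) || object@tau <= 0)
    return("tau must be a single positive value")
  TRUE
})

#' CellState: one cell's latent replication realization
#'
#' @slot licenced logical(3), which origins were licenced this cycle.
#' @slot times numeric(3), firing times in rbp (NA where unlicenced).
#' @slot realized logical(3), origins that actually produced bidirectional
#'   forks (licenced and not obscured).
#' @slot obscuredBy integer(3), 0 if not obscured, else the 1-based index of
#'   the origin whose fork arrived first.
#' @slot collisions data.frame with columns i, j, position: collision points of
#'   positionally adjacent realized origins.
#' @slot prohibited logical(1), TRUE for inadmissible double-overrun/empty
#'   states (such states are resampled by the generator).
#' @export
setClass("CellState",
  representation(licenced = "logical", times = "numeric", realized = "logical",
                 obscuredBy = "integer", collisions = "data.frame",
                 prohibited = "logical"))

#' AveragedProfile: M-cell averaged forward-strand replication profile
#'
#' Values are \eqn{F^{ave}_j}, the fraction of the M simulated cells whose
#' forward strand at box j was replicated as Okazaki fragments; each value is a
#' multiple of 1/M.
#'
#' @slot values numeric, per-box profile values in [0, 1].
#' @slot boxStart numeric, 0-based box start coordinates in bp.
#' @slot sBox numeric(1), box width in bp.
#' @slot M integer(1), number of cells averaged.
#' @slot triplet OriginTriplet.
#' @export
setClass("AveragedProfile",
  representation(values = "numeric", boxStart = "numeric", sBox = "numeric",
                 M = "integer", triplet = "OriginTriplet"))

setValidity("AveragedProfile", function(object) {
  if (length(object@values) != length(object@boxStart))
    return("values and boxStart must have equal length")
  if (any(object@values < -1e-12 | object@values > 1 + 1e-12))
    return("profile values must lie in [0, 1]")
  TRUE
})

#' BoxedCounts: normalized strand-specific counts per box
#'
#' The observation vector of the likelihood: normalized forward and reverse
#' strand counts per 50-bp box over \eqn{[O_1, O_3)}, scaled so that the mean
#' of (forward + reverse) over boxes is 1.
#'
#' @slot forward numeric, normalized forward-strand counts (>= 0).
#' @slot reverse numeric, normalized reverse-strand counts (>= 0).
#' @slot boxStart numeric, 0-based box start coordinates in bp.
#' @slot sBox numeric(1), box width in bp.
#' @slot nNorm numeric(1), local normalization constant n(O1,O3) in counts/bp
#'   (NA for synthetic counts generated on the normalized scale).
#' @slot bChr numeric(1), strand-bias factor applied to the reverse strand.
#' @slot triplet OriginTriplet.
#' @export
setClass("BoxedCounts",
  representation(forward = "numeric", reverse = "numeric", boxStart = "numeric",
                 sBox = "numeric", nNorm = "numeric", bChr = "numeric",
                 triplet = "OriginTriplet"))

setValidity("BoxedCounts", function(object) {
  if (length(object@forward) != length(object@reverse) ||
      length(object@forward) != length(object@boxStart))
    return("forward, reverse and boxStart must have equal length")
  if (any(object@forward < 0) || any(object@reverse < 0))
    return("counts must be non-negative")
  TRUE
})

#' StrandedCoverage: per-bp strand-specific read coverage
#'
#' Run-length encoded per-base counts for the forward and reverse strands over
#' positions 0 .. length-1 (0-based) of one chromosome.
#'
#' @slot chrom character(1).
#' @slot forward Rle of non-negative per-bp counts.
#' @slot reverse Rle of the same length.
#' @importClassesFrom S4Vectors Rle
#' @export
setClass("StrandedCoverage",
  representation(chrom = "character", forward = "Rle", reverse = "Rle"))

setValidity("StrandedCoverage", function(object) {
  if (length(object@forward) != length(object@reverse))
    return("both strands must span the same range")
  if (min(S4Vectors::runValue(object@forward)) < 0 ||
      min(S4Vectors::runValue(object@reverse)) < 0)
    return("coverage must be non-negative")
  TRUE
})

#' MCMCConfig: sampler settings
#'
#' @slot nChains integer(1), number of independent chains (>= 3 recommended
#'   for Gelman-Rubin diagnostics).
#' @slot M integer(1), latent population size.
#' @slot nSweeps integer(1), total sweeps per chain including burn-in.
#' @slot burnIn integer(1), sweeps discarded.
#' @slot thin integer(1), retain every thin-th post-burn-in sweep.
#' @slot cellFrac numeric(1), fraction of cells updated per sweep for each of
#'   the time-update and licencing-toggle move classes.
#' @slot seed integer(1), base seed; chain k uses seed + k - 1.
#' @slot scales numeric named: initial proposal scales t1,t2,t3 (rbp, NA =
#'   auto from data), tau (log scale), b (logit scale).
#' @slot priors numeric named: a_sigma,b_sigma (inverse-gamma on sigma^2),
#'   a_q,b_q (beta on q), a_tau,b_tau (gamma on tau).
#' @slot moves list of logical toggles: update_times, update_lic (3),
#'   sample_mu (3), sample_sigma (3), sample_q (3), sample_b, sample_tau,
#'   recentre, adapt.
#' @slot snapEvery integer(1), latent-state snapshot stride over retained
#'   samples (0 = no snapshots).
#' @slot nSub integer(1), cells per snapshot.
#' @slot checkEvery integer(1), sweeps between internal tally audits.
#' @slot maxResample integer(1), guard for latent-state initialization.
#' @export
setClass("MCMCConfig",
  representation(nChains = "integer", M = "integer", nSweeps = "integer",
                 burnIn = "integer", thin = "integer", cellFrac = "numeric",
                 seed = "integer", scales = "numeric", priors = "numeric",
                 moves = "list", snapEvery = "integer", nSub = "integer",
                 checkEvery = "integer", maxResample = "integer"))

setValidity("MCMCConfig", function(object) {
  if (object@nChains < 1L) return("nChains must be >= 1")
  if (object@nSweeps <= object@burnIn) return("nSweeps must exceed burnIn")
  if (object@thin < 1L) return("thin must be >= 1")
  if (object@cellFrac <= 0 || object@cellFrac > 1)
    return("cellFrac must be in (0, 1]")
  TRUE
})

#' ChainSet: posterior samples from multiple MCMC chains
#'
#' @slot samples list of per-chain matrices (mu1..3, sigma1..3, q1..3, b, tau,
#'   loglik), equal numbers of retained rows.
#' @slot derived list of per-chain matrices of population fractions computed
#'   from the latent cells: realized-firing fraction per origin and directed
#'   obscuring fractions obsc_ij (origin i obscured by origin j).
#' @slot snapshots list of per-chain latent-state snapshots (times, licenced,
#'   realized arrays over a fixed cell subsample).
#' @slot accept list of per-chain acceptance-rate vectors.
#' @slot config MCMCConfig used.
#' @slot triplet OriginTriplet analysed.
#' @slot convergence data.frame of Gelman-Rubin statistics per parameter.
#' @slot finalStates list of per-chain final latent states.
#' @export
setClass("ChainSet",
  representation(samples = "list", derived = "list", snapshots = "list",
                 accept = "list", config = "MCMCConfig",
                 triplet = "OriginTriplet", convergence = "data.frame",
                 finalStates = "list"))

setValidity("ChainSet", function(object) {
  ns <- vapply(object@samples, nrow, 1L)
  if (length(unique(ns)) > 1L) return("chains must have equal length")
  TRUE
})

#' ReplicationTimeProfile: reconstructed replication-time percentiles
#'
#' Per-box 5th/50th/95th percentile replication times in minutes, obtained by
#' simulating admissible cells at a parameter point estimate and converting
#' rbp to minutes through the fork velocity nu (kb/min).
#'
#' @slot position numeric, box midpoints in bp.
#' @slot p05,median,p95 numeric, replication-time percentiles in minutes.
#' @slot nu numeric(1), fork velocity in kb/min.
#' @slot anchor numeric(1), time in minutes assigned to the earliest mean
#'   firing time.
#' @export
setClass("ReplicationTimeProfile",
  representation(position = "numeric", p05 = "numeric", median = "numeric",
                 p95 = "numeric", nu = "numeric", anchor = "numeric"))

setValidity("ReplicationTimeProfile", function(object) {
  n <- length(object@position)
  if (length(object@p05) != n || length(object@median) != n || length(object@p95) != n)
    return("percentile vectors must match position length")
  if (any(object@p05 > object@median + 1e-9) || any(object@median > object@p95 + 1e-9))
    return("percentiles must be ordered p05 <= median <= p95")
  TRUE
})
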