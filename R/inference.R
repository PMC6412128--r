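#' @include AllClasses.R constructors.R simulate.R noise.R
NULL

#' Method-of-moments initializer for the noise precision
#'
#' Uses first differences of log counts between adjacent boxes: the profile
#' varies slowly relative to box width, so
#' \eqn{var(\Delta \log c) \approx 2/\tau} and
#' \eqn{\hat\tau = 2 / var(\Delta \log c)} pooled over both strands.
#'
#' @param counts a [BoxedCounts-class] with positive counts (floored first).
#' @return Positive scalar estimate of tau.
#' @export
estimateTau <- function(counts) {
  counts <- floorCounts(counts)
  v <- c(stats::var(diff(log(counts@forward))),
         stats::var(diff(log(counts@reverse))))
  if (anyNA(v) || mean(v) <= 0) return(1)  # too few boxes to estimate
  max(2 / mean(v), 1e-3)
}

#' Initialize the sampler state
#'
#' Firing means start at 0, s.d. at 0.15 max(N1, N2), licencing at 0.9,
#' background at 0.05 and tau from [estimateTau()]; the latent population is
#' drawn from the prior at these values, conditioned on admissibility by
#' rejection.
#'
#' @param counts [BoxedCounts-class].
#' @param triplet [OriginTriplet-class].
#' @param config [MCMCConfig-class].
#' @return list with elements \code{params} ([FiringParams-class]),
#'   \code{noise} ([NoiseParams-class]) and latent \code{licenced}/\code{times}
#'   matrices (M x 3).
#' @export
initState <- function(counts, triplet, config = mcmcConfig(quiet = TRUE)) {
  if (all(counts@forward <= 0) && all(counts@reverse <= 0))
    stop("degenerate counts: no signal on either strand")
  N <- interOriginDistances(triplet)
  params <- firingParams(mu = c(0, 0, 0), sigma = rep(0.15 * max(N), 3),
                         q = rep(0.9, 3))
  noise <- noiseParams(b = 0.05, tau = estimateTau(counts))
  cells <- simulateCells(params, triplet, config@M, config@maxResample)
  list(params = params, noise = noise,
       licenced = cells$licenced, times = cells$times)
}

.chainControl <- function(config, sigma_init) {
  sc <- config@scales
  st <- sc[c("t1", "t2", "t3")]
  st[is.na(st)] <- 0.5 * sigma_init[is.na(st)]
  m <- config@moves
  list(M = config@M, n_sweeps = config@nSweeps, burn_in = config@burnIn,
       thin = config@thin, cell_frac = config@cellFrac,
       adapt = isTRUE(m$adapt), update_times = isTRUE(m$update_times),
       recentre = isTRUE(m$recentre), snap_every = config@snapEvery,
       n_sub = config@nSub, check_every = config@checkEvery,
       sample_mu = as.logical(m$sample_mu),
       sample_sigma = as.logical(m$sample_sigma),
       sample_q = as.logical(m$sample_q),
       update_lic = as.logical(m$update_lic),
       sample_b = isTRUE(m$sample_b), sample_tau = isTRUE(m$sample_tau),
       scale_t = as.numeric(st), scale_tau = sc[["tau"]], scale_b = sc[["b"]])
}

.chainPriors <- function(config) as.list(config@priors)

#' Run a single MCMC chain
#'
#' One reversible-jump chain over (mu, sigma, q, b, tau) and the latent cell
#' population. Each sweep comprises random-walk firing-time updates for a
#' fraction of cells, licencing birth/death toggles (birth times proposed
#' from the conditional prior N(mu_i, sigma_i^2), so the acceptance ratio is
#' q_i/(1-q_i) times the likelihood ratio), conjugate Gibbs updates of mu_i,
#' sigma_i^2 and q_i, log/logit-scale Metropolis updates of tau and b, and
#' recentring of mu (and all latent times) to sum(mu) = 0. Proposal scales
#' adapt toward 30% acceptance during burn-in only.
#'
#' @param counts [BoxedCounts-class].
#' @param triplet [OriginTriplet-class].
#' @param config [MCMCConfig-class].
#' @param init optional initial state as returned by [initState()]; values
#'   present override the defaults (elements \code{params}, \code{noise},
#'   \code{licenced}, \code{times}).
#' @param seed RNG seed for this chain (default \code{config@seed}).
#' @return list with \code{samples} and \code{derived} matrices,
#'   latent \code{snapshots}, \code{accept}ance rates, adapted \code{scales}
#'   and the \code{final} latent state.
#' @export
runChain <- function(counts, triplet, config = mcmcConfig(quiet = TRUE),
                     init = NULL, seed = config@seed) {
  if (!is.na(seed)) set.seed(seed)
  st <- initState(counts, triplet, config)
  if (!is.null(init)) st[names(init)] <- init
  counts <- floorCounts(counts)
  cinit <- list(mu = st$params@mu, sigma = st$params@sigma, q = st$params@q,
                b = st$noise@b, tau = st$noise@tau,
                licenced = st$licenced,
                times = {
                  tm <- st$times
                  tm[is.na(tm)] <- Inf
                  tm
                })
  g <- list(mid = counts@boxStart + counts@sBox / 2)
  cpp_run_chain(counts@forward, counts@reverse, triplet@positions, g$mid,
                cinit, .chainPriors(config), .chainControl(config, st$params@sigma))
}

#' Sample the posterior with multiple chains
#'
#' Runs \code{config@nChains} independent chains (seeds
#' \code{config@seed + 0:(nChains-1)}), pools nothing, and attaches a
#' Gelman-Rubin convergence report over mu, sigma, q, b and tau. Chains whose
#' within-chain variance is zero (degenerate posteriors, e.g. q pinned at 1)
#' get an NA R-hat flagged as degenerate. Non-convergence at the 1.1
#' threshold raises a warning, not an error.
#'
#' @inheritParams runChain
#' @return A [ChainSet-class].
#' @examples
#' \donttest{
#' trip <- originTriplet(c(200, 1500, 2800))
#' truth <- firingParams(c(0, 700, 1000), c(100, 100, 264), c(1, 0.8, 1))
#' prof <- averageProfile(truth, trip, simConfig(M = 256, seed = 1))
#' cnt <- generateCounts(prof, noiseParams(0.1, 10), seed = 2)
#' fit <- samplePosterior(cnt, trip,
#'   mcmcConfig(nChains = 2, M = 128, nSweeps = 800, burnIn = 300, seed = 1,
#'              quiet = TRUE))
#' convergence(fit)
#' }
#' @export
samplePosterior <- function(counts, triplet,
                            config = mcmcConfig(quiet = TRUE), init = NULL) {
  runs <- lapply(seq_len(config@nChains), function(k) {
    runChain(counts, triplet, config, init = init,
             seed = config@seed + k - 1L)
  })
  samples <- lapply(runs, `[[`, "samples")
  pars <- c("mu1", "mu2", "mu3", "sigma1", "sigma2", "sigma3",
            "q1", "q2", "q3", "b", "tau")
  conv <- data.frame(parameter = pars, Rhat = NA_real_, degenerate = FALSE)
  if (config@nChains >= 2L) {
    for (i in seq_along(pars)) {
      mat <- vapply(samples, function(s) s[, pars[i]],
                    numeric(nrow(samples[[1]])))
      W <- mean(apply(mat, 2, stats::var))
      if (W <= .Machine$double.eps) {
        conv$degenerate[i] <- TRUE
      } else {
        conv$Rhat[i] <- gelmanRubin(mat)
      }
    }
    bad <- conv$parameter[!conv$degenerate & !is.na(conv$Rhat) & conv$Rhat >= 1.1]
    if (length(bad))
      warning("Gelman-Rubin R-hat >= 1.1 for: ", paste(bad, collapse = ", "),
              " (chains may not have converged)")
  }
  new("ChainSet", samples = samples,
      derived = lapply(runs, `[[`, "derived"),
      snapshots = lapply(runs, `[[`, "snapshots"),
      accept = lapply(runs, `[[`, "accept"),
      config = config, triplet = triplet, convergence = conv,
      finalStates = lapply(runs, `[[`, "final"))
}

#' Gelman-Rubin potential scale reduction
#'
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \; W + B/n}{W}}}
#' with W the mean within-chain variance and B the between-chain variance of
#' chain means times n. Identical non-constant chains give
#' \eqn{\sqrt{(n-1)/n}}.
#'
#' @param chains matrix (n samples x m chains) or list of equal-length
#'   numeric vectors, m >= 2.
#' @return Scalar R-hat.
#' @export
gelmanRubin <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L)
      stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2L) stop("need at least 2 chains")
  if (n < 2L) stop("need at least 2 samples per chain")
  W <- mean(apply(chains, 2, stats::var))
  if (W <= 0) stop("zero within-chain variance; R-hat undefined")
  B <- n * stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Recompute profile tallies from a latent state
#'
#' From-scratch recount of the per-box number of cells whose forward strand
#' was replicated as Okazaki fragments, used to audit the sampler's
#' incremental bookkeeping.
#'
#' @param state a final latent state from [runChain()] (elements
#'   \code{licenced}, \code{times}).
#' @param triplet [OriginTriplet-class].
#' @param boxMid numeric vector of box midpoints in bp.
#' @return Integer tally per box.
#' @export
recomputeTally <- function(state, triplet, boxMid) {
  tms <- state$times
  tms[is.na(tms)] <- Inf
  lic <- state$licenced
  M <- nrow(lic)
  fired <- matrix(0L, M, 3)
  for (c in seq_len(M)) {
    r <- cpp_resolve_cell(lic[c, ], tms[c, ], triplet@positions)
    if (isTRUE(r$prohibited)) stop("prohibited cell in latent state")
    fired[c, ] <- r$realized
  }
  cpp_profile_tally(tms, fired, triplet@positions, boxMid)
}
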