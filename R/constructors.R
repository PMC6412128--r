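#' @include AllClasses.R
NULL

#' Construct an origin triplet
#'
#' @param positions numeric(3), strictly increasing 0-based origin coordinates
#'   in bp on one chromosome.
#' @param names character(3), origin labels.
#' @param chrom chromosome identifier.
#' @return An [OriginTriplet-class] object.
#' @examples
#' trip <- originTriplet(c(200, 1500, 2800))
#' interOriginDistances(trip)
#' @export
originTriplet <- function(positions, names = c("O1", "O2", "O3"),
                          chrom = "chr") {
  new("OriginTriplet", positions = as.numeric(positions),
      originNames = as.character(names), chrom = as.character(chrom))
}

#' Construct firing parameters
#'
#' Means are recentred so that \code{sum(mu) == 0}: only firing-time
#' differences affect strand profiles, and the recentred parametrization is
#' the identifiable one.
#'
#' @param mu numeric(3), firing-time means in rbp (recentred unless
#'   \code{recentre = FALSE}, in which case they must already sum to zero).
#' @param sigma numeric(3), positive firing-time s.d. in rbp.
#' @param q numeric(3), licencing probabilities in [0, 1].
#' @param recentre logical, subtract \code{mean(mu)}.
#' @return A [FiringParams-class] object.
#' @examples
#' firingParams(mu = c(-602, 800, 100), sigma = c(196, 100, 100), q = c(1, 1, 1))
#' @export
firingParams <- function(mu, sigma, q = c(1, 1, 1), recentre = TRUE) {
  mu <- as.numeric(mu)
  if (recentre) mu <- mu - mean(mu)
  new("FiringParams", mu = mu, sigma = as.numeric(sigma), q = as.numeric(q))
}

#' Construct simulation settings
#'
#' @param M number of cells averaged (default 4992).
#' @param sBox box width in bp (default 50).
#' @param seed RNG seed, or NA to use the current RNG state.
#' @param maxResample rejection-sampling guard per cell.
#' @param strandConvention TRUE: rightward-moving forks synthesize
#'   forward-strand Okazaki fragments (profile value 1).
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(M = 4992, sBox = 50, seed = NA_integer_,
                      maxResample = 1000, strandConvention = TRUE) {
  new("SimConfig", M = as.integer(M), sBox = as.numeric(sBox),
      seed = as.integer(seed), maxResample = as.integer(maxResample),
      strandConvention = isTRUE(strandConvention))
}

#' Construct observation-noise parameters
#'
#' @param b background random-fragmentation weight in [0, 1].
#' @param tau log-normal precision (> 0).
#' @return A [NoiseParams-class] object.
#' @export
noiseParams <- function(b, tau) {
  new("NoiseParams", b = as.numeric(b), tau = as.numeric(tau))
}

#' Construct a boxed-counts object
#'
#' @param forward,reverse numeric, normalized per-box strand counts.
#' @param triplet the [OriginTriplet-class] the boxes cover.
#' @param sBox box width in bp.
#' @param boxStart 0-based box starts; defaults to consecutive boxes from x1.
#' @param nNorm local normalization constant in counts/bp (NA if synthetic).
#' @param bChr strand-bias factor applied to the reverse strand.
#' @return A [BoxedCounts-class] object.
#' @export
boxedCounts <- function(forward, reverse, triplet, sBox = 50,
                        boxStart = NULL, nNorm = NA_real_, bChr = 1) {
  if (is.null(boxStart))
    boxStart <- triplet@positions[1] + (seq_along(forward) - 1) * sBox
  new("BoxedCounts", forward = as.numeric(forward),
      reverse = as.numeric(reverse), boxStart = as.numeric(boxStart),
      sBox = as.numeric(sBox), nNorm = as.numeric(nNorm),
      bChr = as.numeric(bChr), triplet = triplet)
}

#' Construct sampler settings
#'
#' Defaults give a desk-scale run: a latent population of M = 512 cells (a
#' warning notes that production analyses should use M = 4992, since small M
#' discretizes the profile in steps of 1/M and can leave visible artefacts).
#'
#' @param nChains number of independent chains.
#' @param M latent population size.
#' @param nSweeps total sweeps per chain, including burn-in.
#' @param burnIn sweeps discarded from the start of each chain.
#' @param thin retain every thin-th post-burn-in sweep.
#' @param cellFrac fraction of cells touched per sweep by each of the
#'   firing-time and licencing move classes.
#' @param seed base seed; chain k uses seed + k - 1.
#' @param scales named numeric of initial proposal scales: t1, t2, t3 (rbp;
#'   NA = 0.5 * sigma init), tau (log scale), b (logit scale).
#' @param priors named numeric: a_sigma, b_sigma (inverse-gamma on sigma^2),
#'   a_q, b_q (beta on q), a_tau, b_tau (gamma on tau).
#' @param moves list of toggles overriding the defaults (all moves on):
#'   update_times, update_lic (length 3), sample_mu, sample_sigma, sample_q
#'   (length 3 each), sample_b, sample_tau, recentre, adapt.
#' @param snapEvery latent-snapshot stride over retained samples.
#' @param nSub cells stored per snapshot.
#' @param checkEvery sweeps between internal consistency audits.
#' @param maxResample guard for latent initialization.
#' @param quiet suppress the desk-scale M warning.
#' @return An [MCMCConfig-class] object.
#' @export
mcmcConfig <- function(nChains = 3, M = 512, nSweeps = 6000, burnIn = 2000,
                       thin = 10, cellFrac = 0.1, seed = 1L,
                       scales = c(t1 = NA, t2 = NA, t3 = NA, tau = 0.2, b = 0.3),
                       priors = c(a_sigma = 0.01, b_sigma = 0.01,
                                  a_q = 1, b_q = 1, a_tau = 0.01, b_tau = 0.01),
                       moves = list(), snapEvery = 5L, nSub = 128L,
                       checkEvery = 1000L, maxResample = 1000L,
                       quiet = FALSE) {
  def <- list(update_times = TRUE, update_lic = rep(TRUE, 3),
              sample_mu = rep(TRUE, 3), sample_sigma = rep(TRUE, 3),
              sample_q = rep(TRUE, 3), sample_b = TRUE, sample_tau = TRUE,
              recentre = TRUE, adapt = TRUE)
  unknown <- setdiff(names(moves), names(def))
  if (length(unknown)) stop("unknown move toggles: ", paste(unknown, collapse = ", "))
  def[names(moves)] <- moves
  sdef <- c(t1 = NA, t2 = NA, t3 = NA, tau = 0.2, b = 0.3)
  sdef[names(scales)] <- scales
  pdef <- c(a_sigma = 0.01, b_sigma = 0.01, a_q = 1, b_q = 1,
            a_tau = 0.01, b_tau = 0.01)
  pdef[names(priors)] <- priors
  if (!quiet && M < 4992)
    message("note: M = ", M, " cells is a desk-scale setting; production ",
            "analyses use M = 4992 (smaller M gives 1/M profile ",
            "discretization artefacts)")
  new("MCMCConfig", nChains = as.integer(nChains), M = as.integer(M),
      nSweeps = as.integer(nSweeps), burnIn = as.integer(burnIn),
      thin = as.integer(thin), cellFrac = as.numeric(cellFrac),
      seed = as.integer(seed), scales = sdef, priors = pdef, moves = def,
      snapEvery = as.integer(snapEvery), nSub = as.integer(nSub),
      checkEvery = as.integer(checkEvery),
      maxResample = as.integer(maxResample))
}
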