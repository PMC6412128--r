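# shared fixtures: the canonical simulated triplet (origins at 200, 1500,
# 2800 bp) and a few parameter scenarios used across tests

fixtureTriplet <- function() originTriplet(c(200, 1500, 2800))

# tight, fully licenced, near-simultaneous firing: sharp tanh transitions
paramsSharp <- function() firingParams(mu = c(0, 0, 0),
                                       sigma = c(100, 100, 100))

# staggered firing (differences 700 and 300 rbp with s.d. 141 / 282)
paramsStaggered <- function() firingParams(mu = c(0, 700, 1000),
                                           sigma = c(100, 100, 264))

# obscured middle origin: the left origin fires ~1.4 krbp earlier and its
# fork reaches the middle origin first in ~68% of cells
paramsObscured <- function() firingParams(mu = c(-602, 800, 100),
                                          sigma = c(196, 100, 100))

# build a ChainSet by hand from given sample/derived matrices (summaries
# operate on pooled samples, so tests can feed exact values)
fakeChainSet <- function(samples, derived = NULL, snapshots = NULL,
                         triplet = fixtureTriplet()) {
  if (is.null(derived))
    derived <- lapply(samples, function(s) {
      d <- matrix(0, nrow(s), 9)
      colnames(d) <- c("real1", "real2", "real3", "obsc12", "obsc13",
                       "obsc21", "obsc23", "obsc31", "obsc32")
      d
    })
  if (is.null(snapshots))
    snapshots <- rep(list(list(times = array(NA_real_, c(0, 0, 3)),
                               licenced = array(0L, c(0, 0, 3)),
                               realized = array(0L, c(0, 0, 3)),
                               sample_index = integer())),
                     length(samples))
  cfg <- mcmcConfig(nChains = length(samples), nSweeps = 200, burnIn = 100,
                    quiet = TRUE)
  new("ChainSet", samples = samples, derived = derived,
      snapshots = snapshots, accept = rep(list(numeric()), length(samples)),
      config = cfg, triplet = triplet,
      convergence = data.frame(parameter = character(), Rhat = numeric(),
                               degenerate = logical()),
      finalStates = list())
}

sampleMatrix <- function(n, mu = c(0, 0, 0), sigma = c(100, 100, 100),
                         q = c(1, 1, 1), b = 0.05, tau = 10) {
  s <- cbind(mu1 = rep(mu[1], n), mu2 = mu[2], mu3 = mu[3],
             sigma1 = sigma[1], sigma2 = sigma[2], sigma3 = sigma[3],
             q1 = q[1], q2 = q[2], q3 = q[3], b = b, tau = tau, loglik = 0)
  s
}
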