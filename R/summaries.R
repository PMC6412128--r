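#' @include AllClasses.R inference.R
NULL

# quartiles use linear interpolation (quantile type 7) throughout
.q3 <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                   names = FALSE)

.pairCode <- function(pair) {
  pair <- sort(as.integer(pair))
  pair[1] * 10L + pair[2]
}

# flatten all latent snapshots of a ChainSet into per-cell matrices
.pooledSnapshots <- function(chainset) {
  tl <- list(); ll <- list(); rl <- list()
  for (sn in chainset@snapshots) {
    d <- dim(sn$times)
    if (is.null(d) || d[1] == 0) next
    for (s in seq_len(d[1])) {
      tl[[length(tl) + 1L]] <- matrix(sn$times[s, , ], ncol = 3)
      ll[[length(ll) + 1L]] <- matrix(sn$licenced[s, , ], ncol = 3)
      rl[[length(rl) + 1L]] <- matrix(sn$realized[s, , ], ncol = 3)
    }
  }
  if (!length(tl)) return(NULL)
  list(times = do.call(rbind, tl), licenced = do.call(rbind, ll),
       realized = do.call(rbind, rl))
}

#' Posterior summary of licencing probabilities
#'
#' Medians and lower/upper quartiles of the pooled post-burn-in samples of
#' each q_i. Quartiles rather than standard deviations are reported because
#' licencing posteriors can be highly skewed; a degenerate posterior (all
#' samples equal, e.g. q pinned at 1) collapses all three to that value.
#'
#' @param chainset a [ChainSet-class].
#' @return data.frame with columns origin, lower, median, upper.
#' @export
summarizeLicencing <- function(chainset) {
  s <- posteriorSamples(chainset)
  out <- t(vapply(1:3, function(i) .q3(s[, paste0("q", i)]), numeric(3)))
  data.frame(origin = originNames(chainset@triplet), lower = out[, 1],
             median = out[, 2], upper = out[, 3])
}

#' Posterior summary of obscuring rates
#'
#' Medians and quartiles of the per-sample population obscuring fractions for
#' each directed origin pair (origin i obscured by the fork from origin j; end
#' origins are one-sided: O1 only from the right, O3 only from the left). A
#' Gaussian approximation fitted to the posterior mean and variance gives a
#' significance level against zero obscuring.
#'
#' @param chainset a [ChainSet-class].
#' @return data.frame with columns obscured, by, lower, median, upper,
#'   mean, sd, p_zero.
#' @export
summarizeObscuring <- function(chainset) {
  d <- derivedFractions(chainset)
  pairs <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  rows <- lapply(pairs, function(p) {
    col <- sprintf("obsc%d%d", p[1], p[2])
    v <- d[, col]
    qs <- .q3(v)
    m <- mean(v); sd <- stats::sd(v)
    p0 <- if (sd > 0) stats::pnorm(0, m, sd) else as.numeric(m <= 0)
    data.frame(obscured = p[1], by = p[2], lower = qs[1], median = qs[2],
               upper = qs[3], mean = m, sd = sd, p_zero = p0)
  })
  do.call(rbind, rows)
}

#' Collision-point density for an origin pair
#'
#' Pools collision points of the requested (unordered) origin pair across all
#' latent-state snapshots, bins them into sBox-wide bins over [x1, x3], and
#' reports the fraction of sampled cells in which that pair's collision is
#' realized (including non-adjacent pairs such as O1-O3 when O2 produced no
#' forks).
#'
#' @param chainset a [ChainSet-class] (sampler must have been run with
#'   snapshots enabled).
#' @param pair integer(2), e.g. c(1, 3).
#' @param binWidth bin width in bp (default: the counts box width, 50 bp).
#' @return list with \code{points} (numeric vector), \code{realizedFraction},
#'   \code{breaks} and \code{density} (per-bp histogram density; NULL when no
#'   collisions were realized).
#' @export
collisionDensity <- function(chainset, pair, binWidth = 50) {
  snaps <- .pooledSnapshots(chainset)
  if (is.null(snaps)) stop("chainset carries no latent snapshots")
  tms <- snaps$times
  tms[is.na(tms)] <- Inf
  coll <- cpp_collisions(tms, snaps$realized, chainset@triplet@positions)
  code <- .pairCode(pair)
  hit <- !is.na(coll$pair) & coll$pair == code
  pts <- coll$position[hit]
  frac <- mean(apply(matrix(hit, ncol = 2), 1, any))
  x <- chainset@triplet@positions
  breaks <- seq(x[1], x[3] + binWidth, by = binWidth)
  dens <- NULL
  if (length(pts)) {
    h <- graphics::hist(pmin(pmax(pts, x[1]), x[3]), breaks = breaks,
                        plot = FALSE)
    dens <- h$density
  }
  list(points = pts, realizedFraction = frac, breaks = breaks, density = dens)
}

#' Firing-time-difference density for an origin pair
#'
#' Pools latent firing-time differences t_j - t_i over snapshot cells in which
#' both origins are licenced, and annotates the obscuring thresholds +/- the
#' inter-origin distance: mass beyond +N corresponds to origin j being
#' obscured by origin i's fork, mass below -N to the converse.
#'
#' @param chainset a [ChainSet-class].
#' @param pair integer(2) (i, j), i < j.
#' @return list with \code{diffs}, \code{density} (a stats::density fit, NULL
#'   when empty), \code{thresholds} and logical \code{empty} (no cell had both
#'   origins licenced).
#' @export
firingDiffDensity <- function(chainset, pair) {
  pair <- sort(as.integer(pair))
  snaps <- .pooledSnapshots(chainset)
  if (is.null(snaps)) stop("chainset carries no latent snapshots")
  both <- snaps$licenced[, pair[1]] == 1 & snaps$licenced[, pair[2]] == 1
  diffs <- snaps$times[both, pair[2]] - snaps$times[both, pair[1]]
  x <- chainset@triplet@positions
  N <- x[pair[2]] - x[pair[1]]
  list(diffs = diffs,
       density = if (length(diffs) >= 2) stats::density(diffs) else NULL,
       thresholds = c(-N, N), empty = length(diffs) == 0L)
}

#' Gaussian plug-in probability that the later origin fires first
#'
#' \eqn{\pi(t_{i+1} < t_i) = \Phi(-\Delta\mu / s)} for a neighbouring origin
#' pair with mean firing-time difference \eqn{\Delta\mu = \mu_{i+1} - \mu_i}
#' and \eqn{s = \sqrt{\sigma_i^2 + \sigma_{i+1}^2}}, both in rbp.
#'
#' @param meanDiff mean firing-time difference in rbp.
#' @param sd combined s.d. in rbp (> 0).
#' @return Probability in (0, 1).
#' @examples
#' probFiresEarlier(4667, 10873)    # ~0.33
#' probFiresEarlier(-12205, 15050)  # ~0.79
#' @export
probFiresEarlier <- function(meanDiff, sd) {
  if (any(sd <= 0)) stop("sd must be positive")
  stats::pnorm(-meanDiff / sd)
}

#' Posterior-averaged firing-order probability
#'
#' Per-sample evaluation of \eqn{\Phi(-(\mu_j - \mu_i)/\sqrt{\sigma_i^2 +
#' \sigma_j^2})} averaged over the pooled posterior — the sample-averaged
#' alternative to the plug-in [probFiresEarlier()] evaluated at posterior
#' means (the two differ when the posterior is wide or skewed).
#'
#' @param chainset a [ChainSet-class].
#' @param pair integer(2) (i, j), i < j.
#' @return Scalar probability.
#' @export
probFiresEarlierPosterior <- function(chainset, pair) {
  pair <- sort(as.integer(pair))
  s <- posteriorSamples(chainset)
  dmu <- s[, paste0("mu", pair[2])] - s[, paste0("mu", pair[1])]
  sd <- sqrt(s[, paste0("sigma", pair[1])]^2 + s[, paste0("sigma", pair[2])]^2)
  mean(stats::pnorm(-dmu / sd))
}

#' Median replication-time reconstruction
#'
#' Simulates K admissible cells at a parameter point estimate (typically the
#' per-parameter posterior medians); each box's replication time in a cell is
#' the first fork arrival min_i over realized origins of (t_i + |x - x_i|)
#' rbp. Per-box 5th/50th/95th percentiles across cells are converted to
#' minutes as (T_rbp - min_i mu_i) / (1000 nu) + anchor, with fork velocity
#' nu in kb/min.
#'
#' @param params [FiringParams-class] point estimate.
#' @param triplet [OriginTriplet-class].
#' @param nu fork velocity in kb/min (> 0); 1.6 is the reference value for
#'   budding yeast, 3.3 for human cells.
#' @param anchor time in minutes assigned to the earliest mean firing time.
#' @param K number of cells (>= 100).
#' @param sBox box width in bp.
#' @param seed optional RNG seed.
#' @return A [ReplicationTimeProfile-class].
#' @export
medianReplicationTime <- function(params, triplet, nu, anchor = 0, K = 1000,
                                  sBox = 50, seed = NULL) {
  if (nu <= 0) stop("nu must be positive")
  if (K < 100) stop("K must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  g <- .boxGrid(triplet, sBox)
  sim <- simulateCells(params, triplet, K)
  x <- triplet@positions
  tms <- sim$times
  tms[is.na(tms)] <- Inf
  Tmat <- matrix(Inf, K, g$nb)
  for (i in 1:3) {
    arr <- outer(ifelse(sim$realized[, i] == 1, tms[, i], Inf),
                 abs(g$mid - x[i]), `+`)
    Tmat <- pmin(Tmat, arr)
  }
  qs <- apply(Tmat, 2, stats::quantile, probs = c(0.05, 0.5, 0.95), type = 7)
  tomin <- function(v) (v - min(params@mu)) / (1000 * nu) + anchor
  new("ReplicationTimeProfile", position = g$mid, p05 = tomin(qs[1, ]),
      median = tomin(qs[2, ]), p95 = tomin(qs[3, ]), nu = nu,
      anchor = anchor)
}

#' Write a posterior summary report
#'
#' JSON (licencing, obscuring, firing-order probabilities, convergence) plus
#' a TSV of the replication-time profile when requested.
#'
#' @param chainset a [ChainSet-class].
#' @param file output JSON path.
#' @param replicationTime optional [ReplicationTimeProfile-class]; written as
#'   \code{<file>_reptime.tsv}.
#' @return Invisibly, the JSON path.
#' @export
writeSummaryReport <- function(chainset, file, replicationTime = NULL) {
  s <- posteriorSamples(chainset)
  med <- apply(s, 2, stats::median)
  plug <- function(i, j)
    probFiresEarlier(med[paste0("mu", j)] - med[paste0("mu", i)],
                     sqrt(med[paste0("sigma", i)]^2 + med[paste0("sigma", j)]^2))
  rep <- list(
    licencing = summarizeLicencing(chainset),
    obscuring = summarizeObscuring(chainset),
    posterior_medians = as.list(med),
    firing_order = list(
      plug_in = list(pi_t2_lt_t1 = unname(plug(1, 2)),
                     pi_t3_lt_t2 = unname(plug(2, 3))),
      posterior_average = list(
        pi_t2_lt_t1 = probFiresEarlierPosterior(chainset, c(1, 2)),
        pi_t3_lt_t2 = probFiresEarlierPosterior(chainset, c(2, 3)))),
    convergence = convergence(chainset))
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  if (!is.null(replicationTime)) {
    tsv <- sub("\\.json$", "", file)
    utils::write.table(
      data.frame(position = replicationTime@position,
                 p05 = replicationTime@p05,
                 median = replicationTime@median,
                 p95 = replicationTime@p95),
      paste0(tsv, "_reptime.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(file)
}

#' Plot data, fit and collision densities
#'
#' Base-graphics overview: boxed strand counts with the posterior-median
#' reconstructed profile, and (optionally) collision-point densities.
#'
#' @param counts [BoxedCounts-class].
#' @param chainset optional [ChainSet-class] for the fitted overlay.
#' @param main plot title.
#' @return Invisibly NULL.
#' @export
plotProfileFit <- function(counts, chainset = NULL, main = "OF profile") {
  mid <- boxMids(counts)
  graphics::plot(mid, forwardCounts(counts), type = "h", col = "steelblue",
                 xlab = "position (bp)", ylab = "normalized count",
                 main = main,
                 ylim = c(0, max(forwardCounts(counts), reverseCounts(counts))))
  graphics::points(mid, reverseCounts(counts), type = "h", col = "firebrick")
  graphics::abline(v = originPositions(counts@triplet), lty = 2)
  if (!is.null(chainset)) {
    s <- posteriorSamples(chainset)
    med <- apply(s, 2, stats::median)
    params <- firingParams(med[c("mu1", "mu2", "mu3")],
                           med[c("sigma1", "sigma2", "sigma3")],
                           med[c("q1", "q2", "q3")])
    prof <- averageProfile(params, chainset@triplet,
                           simConfig(M = 2000, sBox = counts@sBox, seed = 1))
    m <- expectedIntensity(prof, noiseParams(med["b"], med["tau"]))
    graphics::lines(boxMids(prof), m$forward, col = "goldenrod", lwd = 2)
    graphics::lines(boxMids(prof), m$reverse, col = "purple", lwd = 2)
  }
  invisible(NULL)
}
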