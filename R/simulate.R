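#' @include AllClasses.R constructors.R
NULL

.boxGrid <- function(triplet, sBox) {
  x <- triplet@positions
  nb <- floor((x[3] - x[1]) / sBox)
  if (nb < 1) stop("region shorter than one box")
  start <- x[1] + (seq_len(nb) - 1) * sBox
  list(start = start, mid = start + sBox / 2, nb = nb)
}

.cellStateFromCpp <- function(res, licenced, times, triplet) {
  realized <- as.logical(res$realized)
  coll <- cpp_collisions(matrix(ifelse(is.na(times), Inf, times), nrow = 1),
                         matrix(as.integer(realized), nrow = 1),
                         triplet@positions)
  keep <- !is.na(coll$pair[1, ])
  collisions <- data.frame(i = coll$pair[1, keep] %/% 10L,
                           j = coll$pair[1, keep] %% 10L,
                           position = coll$position[1, keep])
  new("CellState", licenced = as.logical(licenced), times = as.numeric(times),
      realized = realized, obscuredBy = as.integer(res$obscured_by),
      collisions = collisions, prohibited = isTRUE(res$prohibited))
}

#' Resolve the replication outcome of one cell deterministically
#'
#' Given licencing indicators and potential firing times, determines which
#' origins actually produce bidirectional forks (realized), which are obscured
#' by an incoming fork (and by whom), and the fork collision points. An origin
#' i is obscured iff a fork launched at a realized origin j at time t_j,
#' travelling at 1 bp per rbp and not blocked by an intermediate realized
#' origin, reaches x_i at a time <= t_i. Adjacent realized origins i < j
#' collide at \eqn{x_{ij} = (x_i + x_j + t_j - t_i)/2}.
#'
#' @param times numeric(3), firing times in rbp; entries for unlicenced
#'   origins are ignored.
#' @param licenced logical(3).
#' @param triplet an [OriginTriplet-class].
#' @return A [CellState-class]; its \code{prohibited} slot is TRUE for the
#'   inadmissible states (no realized origin, or a single realized end origin
#'   whose forks overrun the whole region).
#' @examples
#' trip <- originTriplet(c(200, 1500, 2800))
#' st <- resolveCell(c(0, 300, 200), c(TRUE, TRUE, TRUE), trip)
#' st@collisions  # collisions at 1000 and 2100 bp
#' @export
resolveCell <- function(times, licenced = c(TRUE, TRUE, TRUE), triplet) {
  stopifnot(length(times) == 3L, length(licenced) == 3L)
  t2 <- ifelse(licenced, times, Inf)
  if (any(licenced & !is.finite(t2))) stop("licenced origins need finite times")
  res <- cpp_resolve_cell(as.integer(licenced), as.numeric(t2),
                          triplet@positions)
  .cellStateFromCpp(res, licenced, ifelse(licenced, times, NA_real_), triplet)
}

#' Simulate one admissible cell
#'
#' Draws licencing per origin as Bernoulli(q_i) and firing times from
#' N(mu_i, sigma_i^2) for licenced origins, then resolves obscuring and
#' collisions; cells in prohibited states are rejected and redrawn, so the
#' returned state is always admissible.
#'
#' @param params [FiringParams-class].
#' @param triplet [OriginTriplet-class].
#' @param maxResample rejection guard; exceeded only in degenerate regimes
#'   (e.g. q = (1, 0, 0), where the single end origin always overruns).
#' @return An admissible [CellState-class].
#' @export
simulateCell <- function(params, triplet, maxResample = 1000) {
  sim <- cpp_simulate_cells(params@mu, params@sigma, params@q,
                            triplet@positions, 1L, as.integer(maxResample))
  res <- list(realized = sim$realized[1, ], obscured_by = sim$obscured_by[1, ],
              prohibited = FALSE)
  .cellStateFromCpp(res, as.logical(sim$licenced[1, ]), sim$times[1, ], triplet)
}

#' Simulate a batch of admissible cells
#'
#' Vectorized version of [simulateCell()] returning the latent population as
#' matrices (one row per cell), the columnar form used for debugging and for
#' Monte-Carlo summaries.
#'
#' @inheritParams simulateCell
#' @param n number of cells.
#' @return A list with matrices \code{licenced}, \code{times} (NA where
#'   unlicenced), \code{realized}, \code{obscured_by} (0 = not obscured, else
#'   obscuring origin index) and the per-cell rejection \code{attempts}.
#' @export
simulateCells <- function(params, triplet, n, maxResample = 1000) {
  cpp_simulate_cells(params@mu, params@sigma, params@q, triplet@positions,
                     as.integer(n), as.integer(maxResample))
}

#' Single-cell binary box profile
#'
#' Evaluates the piecewise-constant single-cell replication profile at box
#' midpoints: 1 where the box was replicated by a rightward-moving fork (the
#' forward-strand Okazaki-fragment convention), 0 otherwise. Midpoint
#' evaluation localizes breakpoints to within sBox/2.
#'
#' @param state an admissible [CellState-class].
#' @param triplet [OriginTriplet-class].
#' @param sBox box width in bp.
#' @param strandConvention FALSE flips the profile (leftward forks mapped to
#'   the forward strand instead).
#' @return Integer vector of 0/1 per box with attribute \code{boxStart}.
#' @export
cellProfile <- function(state, triplet, sBox = 50, strandConvention = TRUE) {
  if (state@prohibited)
    stop("prohibited cell states have no defined profile")
  g <- .boxGrid(triplet, sBox)
  t2 <- ifelse(state@realized, state@times, Inf)
  p <- cpp_cell_profiles(matrix(t2, nrow = 1),
                         matrix(as.integer(state@realized), nrow = 1),
                         triplet@positions, g$mid)[1, ]
  if (!strandConvention) p <- 1L - p
  attr(p, "boxStart") <- g$start
  p
}

#' Averaged replication profile over M cells
#'
#' Simulates \code{M} admissible cells and averages their binary box profiles
#' into \eqn{F^{ave}}, the fraction of cells whose forward strand at each box
#' was replicated as Okazaki fragments. Deterministic for a fixed seed.
#'
#' @param params [FiringParams-class].
#' @param triplet [OriginTriplet-class].
#' @param config [SimConfig-class]; its \code{seed} (if not NA) seeds the RNG.
#' @return An [AveragedProfile-class].
#' @examples
#' trip <- originTriplet(c(200, 1500, 2800))
#' par2c <- firingParams(mu = c(0, 700, 1000), sigma = c(100, 100, 264))
#' prof <- averageProfile(par2c, trip, simConfig(M = 1000, seed = 7))
#' head(profileValues(prof))
#' @export
averageProfile <- function(params, triplet, config = simConfig()) {
  if (!is.na(config@seed)) set.seed(config@seed)
  g <- .boxGrid(triplet, config@sBox)
  sim <- cpp_simulate_cells(params@mu, params@sigma, params@q,
                            triplet@positions, config@M, config@maxResample)
  tms <- sim$times
  tms[is.na(tms)] <- Inf
  tally <- cpp_profile_tally(tms, sim$realized, triplet@positions, g$mid)
  vals <- tally / config@M
  if (!config@strandConvention) vals <- 1 - vals
  new("AveragedProfile", values = vals, boxStart = g$start,
      sBox = config@sBox, M = config@M, triplet = triplet)
}

#' Closed-form two-origin profile
#'
#' For two fully licenced origins i < j and no third origin, the probability
#' that position x is replicated by origin i's rightward fork is
#' \deqn{\Phi\left(\frac{\mu_j - \mu_i + x_i + x_j - 2x}{\sqrt{\sigma_i^2 +
#'   \sigma_j^2}}\right),}
#' the tanh-like transition used as an analytic oracle for the simulator.
#'
#' @param x positions in bp (vectorized).
#' @param xi,xj origin positions, xi < xj.
#' @param mui,muj firing-time means in rbp.
#' @param sigmai,sigmaj positive firing-time s.d. in rbp.
#' @return Probabilities in (0, 1).
#' @export
twoOriginProfile <- function(x, xi, xj, mui, muj, sigmai, sigmaj) {
  if (sigmai <= 0 || sigmaj <= 0) stop("sigma values must be positive")
  stats::pnorm((muj - mui + xi + xj - 2 * x) / sqrt(sigmai^2 + sigmaj^2))
}

#' Closed-form one-sided obscuring probability
#'
#' Probability that a fully licenced neighbour's fork (launched at
#' t ~ N(muNeighbour, sigmaNeighbour^2), travelling at 1 bp/rbp over
#' \code{distance} bp) arrives before the origin's own firing time
#' t ~ N(muSelf, sigmaSelf^2):
#' \deqn{\Phi\left(\frac{\mu_{self} - \mu_{neighbour} - d}
#'   {\sqrt{\sigma_{self}^2 + \sigma_{neighbour}^2}}\right).}
#' Valid when no third origin can interfere with the event.
#'
#' @param muNeighbour,sigmaNeighbour neighbour firing-time mean/s.d. (rbp).
#' @param muSelf,sigmaSelf own firing-time mean/s.d. (rbp).
#' @param distance inter-origin distance in bp (> 0).
#' @return Obscuring probability.
#' @examples
#' # obscured-middle-origin scenario: ~0.679
#' obscuringProbability(-602, 196, 800, 100, 1300)
#' @export
obscuringProbability <- function(muNeighbour, sigmaNeighbour, muSelf,
                                 sigmaSelf, distance) {
  if (any(distance <= 0)) stop("distance must be positive")
  if (sigmaNeighbour <= 0 || sigmaSelf <= 0) stop("sigma values must be positive")
  stats::pnorm((muSelf - muNeighbour - distance) /
                 sqrt(sigmaSelf^2 + sigmaNeighbour^2))
}

#' Export an averaged profile
#'
#' Writes the profile as a 4-column bedGraph (0-based half-open intervals) or
#' as a plain two-column table (box_start, F_ave).
#'
#' @param profile an [AveragedProfile-class].
#' @param file output path.
#' @param format "bedGraph" or "table".
#' @return Invisibly, the file path.
#' @export
exportProfile <- function(profile, file, format = c("bedGraph", "table")) {
  format <- match.arg(format)
  if (format == "bedGraph") {
    gr <- GenomicRanges::GRanges(
      seqnames = profile@triplet@chrom,
      ranges = IRanges::IRanges(start = profile@boxStart + 1,
                                width = profile@sBox),
      score = profile@values)
    rtracklayer::export(gr, file, format = "bedGraph")
  } else {
    utils::write.table(
      data.frame(box_start = profile@boxStart, F_ave = profile@values),
      file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Collision points of a batch of cells
#'
#' For each cell, the collision points of positionally adjacent realized
#' origins, \eqn{x_{ij} = (x_i + x_j + t_j - t_i)/2}; up to two per cell.
#'
#' @param cells list from [simulateCells()] (or a latent snapshot with
#'   elements \code{times} and \code{realized} as cell-by-origin matrices).
#' @param triplet [OriginTriplet-class].
#' @return list with NA-padded cell-by-2 matrices \code{pair} (codes 12, 23,
#'   13) and \code{position} (bp).
#' @export
collisionPoints <- function(cells, triplet) {
  tms <- cells$times
  tms[is.na(tms)] <- Inf
  cpp_collisions(tms, cells$realized, triplet@positions)
}

#' Tabulate a batch of simulated cells
#'
#' Flattens the matrices from [simulateCells()] into one long data.frame (one
#' row per cell and origin) for inspection or export.
#'
#' @param cells list from [simulateCells()].
#' @return data.frame with columns cell, origin, licenced, time, realized,
#'   obscured_by.
#' @export
cellTable <- function(cells) {
  n <- nrow(cells$licenced)
  data.frame(cell = rep(seq_len(n), 3),
             origin = rep(1:3, each = n),
             licenced = as.logical(cells$licenced),
             time = as.numeric(cells$times),
             realized = as.logical(cells$realized),
             obscured_by = as.integer(cells$obscured_by))
}
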