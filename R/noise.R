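#' @include AllClasses.R simulate.R
NULL

#' Expected strand intensities under the counts model
#'
#' Maps an averaged profile to the expected normalized intensities of the two
#' strands: \eqn{m^f = (1-b) F^{ave} + b/2} and
#' \eqn{m^r = (1-b)(1 - F^{ave}) + b/2}, which sum to 1 exactly per box. The
#' background weight b mixes the replication signal with uniform random
#' fragmentation.
#'
#' @param profile an [AveragedProfile-class] or a numeric vector of profile
#'   values in [0, 1].
#' @param noise [NoiseParams-class].
#' @return list with numeric vectors \code{forward} and \code{reverse}.
#' @examples
#' expectedIntensity(0.75, noiseParams(b = 0.2, tau = 5))  # 0.70 / 0.30
#' @export
expectedIntensity <- function(profile, noise) {
  f <- if (is(profile, "AveragedProfile")) profile@values else as.numeric(profile)
  if (any(f < -1e-12 | f > 1 + 1e-12)) stop("profile values must lie in [0, 1]")
  mf <- (1 - noise@b) * f + 0.5 * noise@b
  list(forward = mf, reverse = 1 - mf)
}

#' Generate synthetic boxed counts
#'
#' Multiplies the expected strand intensities by independent unit-mean
#' log-normal noise \code{exp(N(-0.5/tau, 1/tau))} per box and strand.
#'
#' @inheritParams expectedIntensity
#' @param seed optional RNG seed.
#' @return A [BoxedCounts-class] (with \code{nNorm = NA}: counts are generated
#'   directly on the normalized scale).
#' @export
generateCounts <- function(profile, noise, seed = NULL) {
  if (!is(profile, "AveragedProfile"))
    stop("generateCounts needs an AveragedProfile (use boxedCounts() to wrap raw vectors)")
  if (!is.null(seed)) set.seed(seed)
  m <- expectedIntensity(profile, noise)
  nb <- length(m$forward)
  sdlog <- 1 / sqrt(noise@tau)
  mlog <- -0.5 / noise@tau
  cf <- m$forward * exp(stats::rnorm(nb, mlog, sdlog))
  cr <- m$reverse * exp(stats::rnorm(nb, mlog, sdlog))
  boxedCounts(cf, cr, profile@triplet, sBox = profile@sBox,
              boxStart = profile@boxStart)
}

#' Floor counts away from zero
#'
#' The log-normal density is undefined at zero, so before evaluating the
#' likelihood any zero (or negative) normalized count is replaced by half the
#' smallest positive count in the region.
#'
#' @param counts a [BoxedCounts-class].
#' @return A [BoxedCounts-class] with strictly positive counts.
#' @export
floorCounts <- function(counts) {
  all_pos <- c(counts@forward, counts@reverse)
  pos <- all_pos[all_pos > 0]
  if (!length(pos)) stop("no positive counts in region")
  eps <- min(pos) / 2
  counts@forward <- pmax(counts@forward, eps)
  counts@reverse <- pmax(counts@reverse, eps)
  counts
}

#' Log-likelihood of boxed counts
#'
#' Sum over boxes and both strands of the log-normal log-density
#' \deqn{\log p(x \mid m) = \tfrac12\log\frac{\tau}{2\pi} - \log x -
#'   \frac{\tau}{2}\left(\log x - \log m + \tfrac{1}{2\tau}\right)^2,}
#' where m is the expected strand intensity of the box. Boxes are treated as
#' independent.
#'
#' @param counts [BoxedCounts-class]; zero counts are floored via
#'   [floorCounts()] first.
#' @param profile [AveragedProfile-class] or numeric profile vector of equal
#'   length.
#' @param noise [NoiseParams-class].
#' @return Finite scalar log-likelihood.
#' @export
logLikelihood <- function(counts, profile, noise) {
  m <- expectedIntensity(profile, noise)
  if (length(m$forward) != length(counts@forward))
    stop("profile and counts must cover the same boxes")
  if (any(m$forward <= 0) || any(m$reverse <= 0))
    stop("expected intensities must be positive (profile at 0/1 with b = 0)")
  counts <- floorCounts(counts)
  tau <- noise@tau
  ll1 <- .lnormLogDensity(counts@forward, m$forward, tau)
  ll2 <- .lnormLogDensity(counts@reverse, m$reverse, tau)
  out <- sum(ll1) + sum(ll2)
  if (!is.finite(out)) stop("non-finite log-likelihood")
  out
}

.lnormLogDensity <- function(x, m, tau) {
  z <- log(x) - log(m) + 0.5 / tau
  0.5 * log(tau / (2 * pi)) - log(x) - 0.5 * tau * z^2
}

#' Read/write boxed counts as a tab-separated table
#'
#' Columns box_start, c_f, c_r; header comment lines carry the box width,
#' normalization constant, strand-bias factor and triplet geometry so the
#' object round-trips.
#'
#' @param counts [BoxedCounts-class].
#' @param file path.
#' @return \code{writeBoxedCounts}: invisibly the path; \code{readBoxedCounts}:
#'   a [BoxedCounts-class].
#' @export
writeBoxedCounts <- function(counts, file) {
  t <- counts@triplet
  hdr <- c(sprintf("# sBox=%.10g nNorm=%s bChr=%.10g", counts@sBox,
                   ifelse(is.na(counts@nNorm), "NA",
                          sprintf("%.10g", counts@nNorm)),
                   counts@bChr),
           sprintf("# chrom=%s positions=%s names=%s", t@chrom,
                   paste(sprintf("%.10g", t@positions), collapse = ","),
                   paste(t@originNames, collapse = ",")))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(box_start = counts@boxStart, c_f = counts@forward,
               c_r = counts@reverse),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeBoxedCounts
#' @export
readBoxedCounts <- function(file) {
  hdr <- readLines(file, n = 2)
  kv <- function(line, key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", line)
  sBox <- as.numeric(kv(hdr[1], "sBox"))
  nNorm <- suppressWarnings(as.numeric(kv(hdr[1], "nNorm")))
  bChr <- as.numeric(kv(hdr[1], "bChr"))
  chrom <- kv(hdr[2], "chrom")
  pos <- as.numeric(strsplit(kv(hdr[2], "positions"), ",")[[1]])
  nms <- strsplit(kv(hdr[2], "names"), ",")[[1]]
  tab <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  trip <- originTriplet(pos, nms, chrom)
  boxedCounts(tab$c_f, tab$c_r, trip, sBox = sBox, boxStart = tab$box_start,
              nNorm = nNorm, bChr = bChr)
}

#' Export boxed counts as a bedGraph pair
#'
#' @param counts [BoxedCounts-class].
#' @param forwardFile,reverseFile output paths.
#' @return Invisibly, both paths.
#' @export
exportBoxedCounts <- function(counts, forwardFile, reverseFile) {
  mk <- function(v) GenomicRanges::GRanges(
    seqnames = counts@triplet@chrom,
    ranges = IRanges::IRanges(start = counts@boxStart + 1, width = counts@sBox),
    score = v)
  rtracklayer::export(mk(counts@forward), forwardFile, format = "bedGraph")
  rtracklayer::export(mk(counts@reverse), reverseFile, format = "bedGraph")
  invisible(c(forwardFile, reverseFile))
}
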