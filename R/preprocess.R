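#' @include AllClasses.R constructors.R
NULL

# Preprocessing contract: inputs are strand-specific per-bp coverage tracks
# (bedGraph, 0-based half-open) built from aligned reads that already passed
# mapping-quality filtering (> 10 in the reference pipeline); alignment and
# BAM handling are upstream of this package.

#' Read a pair of strand-specific bedGraph coverage tracks
#'
#' @param forwardFile,reverseFile bedGraph paths (0-based half-open
#'   intervals), one per strand.
#' @param chrom chromosome to extract.
#' @return A [StrandedCoverage-class] spanning positions 0..L-1 where L is the
#'   largest interval end seen on either strand.
#' @export
readStrandedCoverage <- function(forwardFile, reverseFile, chrom) {
  rd <- function(f) {
    gr <- rtracklayer::import(f, format = "bedGraph")
    gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  }
  grf <- rd(forwardFile)
  grr <- rd(reverseFile)
  if (!length(grf) && !length(grr))
    stop("no intervals on chromosome ", chrom, " in either strand file")
  len <- max(GenomicRanges::end(grf), GenomicRanges::end(grr))
  cov <- function(gr) {
    GenomicRanges::coverage(gr, weight = "score",
                            width = stats::setNames(len, chrom))[[chrom]]
  }
  new("StrandedCoverage", chrom = chrom, forward = cov(grf),
      reverse = cov(grr))
}

#' Build stranded coverage from a vector pair
#'
#' Convenience constructor for tests and simulations: per-bp counts for
#' positions 0..length-1.
#'
#' @param forward,reverse numeric vectors of equal length, per-bp counts.
#' @param chrom chromosome label.
#' @return A [StrandedCoverage-class].
#' @export
strandedCoverage <- function(forward, reverse, chrom = "chr") {
  new("StrandedCoverage", chrom = chrom,
      forward = S4Vectors::Rle(as.numeric(forward)),
      reverse = S4Vectors::Rle(as.numeric(reverse)))
}

#' Read origin positions from a BED file
#'
#' Takes the (0-based) start coordinate of each BED interval as the origin
#' position.
#'
#' @param file BED path with at least three origins on one chromosome.
#' @param chrom chromosome to extract (default: the only one present).
#' @param which indices of the three origins to use, in order.
#' @return An [OriginTriplet-class].
#' @export
readOrigins <- function(file, chrom = NULL, which = 1:3) {
  gr <- rtracklayer::import(file, format = "BED")
  if (is.null(chrom)) {
    chrom <- unique(as.character(GenomicRanges::seqnames(gr)))
    if (length(chrom) != 1L)
      stop("origins span several chromosomes; pass chrom explicitly")
  } else {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  }
  gr <- gr[order(GenomicRanges::start(gr))]
  if (length(gr) < max(which)) stop("fewer origins than requested in ", file)
  gr <- gr[which]
  nm <- if (!is.null(gr$name) && !anyNA(gr$name)) gr$name else
    paste0("O", seq_along(which))
  originTriplet(GenomicRanges::start(gr) - 1, nm, chrom)
}

#' Read paired-end fragment intervals from BED
#'
#' @param file BED path of fragment intervals (0-based half-open).
#' @return A GRanges of fragments; widths equal fragment lengths in bp.
#' @export
readFragments <- function(file) {
  rtracklayer::import(file, format = "BED")
}

#' Filter fragments by length
#'
#' Keeps fragments whose length lies in [minLen, maxLen] (both inclusive),
#' the Okazaki-fragment length window; order is preserved and the operation
#' is idempotent.
#'
#' @param fragments GRanges (widths are fragment lengths in bp) or a numeric
#'   vector of lengths.
#' @param minLen,maxLen inclusive bounds in bp.
#' @return The surviving fragments (same type as the input).
#' @export
filterFragments <- function(fragments, minLen = 120, maxLen = 200) {
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  len <- if (is.numeric(fragments)) fragments else
    GenomicRanges::width(fragments)
  fragments[len >= minLen & len <= maxLen]
}

#' Per-strand coverage from fragment intervals
#'
#' @param fragments GRanges with strand information.
#' @param chrom chromosome to extract.
#' @param len chromosome length in bp (default: max fragment end).
#' @return A [StrandedCoverage-class].
#' @export
fragmentCoverage <- function(fragments, chrom = NULL, len = NULL) {
  if (is.null(chrom)) {
    chrom <- unique(as.character(GenomicRanges::seqnames(fragments)))
    if (length(chrom) != 1L) stop("pass chrom explicitly")
  }
  fragments <- fragments[as.character(GenomicRanges::seqnames(fragments)) == chrom]
  if (is.null(len)) len <- max(GenomicRanges::end(fragments))
  cov <- function(gr) GenomicRanges::coverage(
    gr, width = stats::setNames(len, chrom))[[chrom]]
  new("StrandedCoverage", chrom = chrom,
      forward = cov(fragments[GenomicRanges::strand(fragments) == "+"]),
      reverse = cov(fragments[GenomicRanges::strand(fragments) == "-"]))
}

#' Chromosome-wide strand bias
#'
#' Ratio of total forward-strand to total reverse-strand counts over the whole
#' chromosome, \eqn{b_{chr} = \sum_i c^f_i / \sum_i c^r_i}, used to correct
#' the reverse strand for the measurement bias between strands.
#'
#' @param coverage a [StrandedCoverage-class].
#' @return Scalar strand-bias factor.
#' @export
strandBias <- function(coverage) {
  tot_r <- sum(as.numeric(S4Vectors::runValue(coverage@reverse) *
                            S4Vectors::runLength(coverage@reverse)))
  if (tot_r <= 0) stop("reverse-strand total is zero; strand bias undefined")
  tot_f <- sum(as.numeric(S4Vectors::runValue(coverage@forward) *
                            S4Vectors::runLength(coverage@forward)))
  tot_f / tot_r
}

#' Box and locally normalize stranded coverage over a triplet
#'
#' Sums per-bp counts into half-open boxes of \code{sBox} bp over
#' \eqn{[x_1, x_3)} (a trailing partial box is dropped) and divides by
#' \eqn{s_{box} \cdot n}, where
#' \eqn{n = \frac{1}{x_3 - x_1}\sum_{i=x_1}^{x_3 - 1}(c^f_i + b_{chr} c^r_i)}
#' is the local mean count per bp; reverse-strand box sums are weighted by
#' \code{bChr}. The normalized counts then satisfy
#' mean(forward + reverse) = 1 over the boxes, exactly when \eqn{x_3 - x_1}
#' is a multiple of \code{sBox}.
#'
#' @param coverage [StrandedCoverage-class] covering the region.
#' @param triplet [OriginTriplet-class] (0-based positions).
#' @param sBox box width in bp.
#' @param bChr strand-bias factor; default computed from the whole coverage
#'   via [strandBias()].
#' @param normRange optional numeric(2): 0-based [start, end) window over
#'   which n is computed instead of [x1, x3) — used to normalize overlapping
#'   triplets by a common four-origin window n(O1, O4).
#' @return A [BoxedCounts-class].
#' @export
boxAndNormalize <- function(coverage, triplet, sBox = 50, bChr = NULL,
                            normRange = NULL) {
  x <- triplet@positions
  L <- length(coverage@forward)
  if (x[3] > L) stop("coverage does not span the triplet region")
  if (is.null(bChr)) bChr <- strandBias(coverage)
  if (bChr <= 0) stop("bChr must be positive")
  if (is.null(normRange)) normRange <- c(x[1], x[3])
  # 0-based position p lives at Rle index p + 1
  w_idx <- (normRange[1] + 1):normRange[2]
  wsum <- sum(as.numeric(coverage@forward[w_idx])) +
    bChr * sum(as.numeric(coverage@reverse[w_idx]))
  n <- wsum / (normRange[2] - normRange[1])
  if (n <= 0) stop("no signal in normalization window (n = 0)")
  nb <- floor((x[3] - x[1]) / sBox)
  start <- x[1] + (seq_len(nb) - 1) * sBox
  boxsum <- function(rle) {
    v <- as.numeric(rle[(x[1] + 1):(x[1] + nb * sBox)])
    colSums(matrix(v, nrow = sBox))
  }
  cf <- boxsum(coverage@forward) / (sBox * n)
  cr <- bChr * boxsum(coverage@reverse) / (sBox * n)
  boxedCounts(cf, cr, triplet, sBox = sBox, boxStart = start, nNorm = n,
              bChr = bChr)
}
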