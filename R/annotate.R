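# Interpret linked-search chains as Cassandra element models: LTR versus
# internal-domain segmentation, PBS placement, and unit-period statistics
# of tandem arrays.

.chainSite <- function(chain, k) {
  S4Vectors::mcols(chain)$sites[[1L]][k]
}

#' Annotate a chain as a Cassandra element
#'
#' Interprets a chain from the Cassandra query (boxA, boxC, PBS in order)
#' structurally: the 5' LTR extends from \code{ltr5Flank} nucleotides
#' before the boxA start to just before the PBS start (the LTR 5' edge is
#' not inferable from the motif chain alone, so the default flank is 0 and
#' the LTR is reported from the boxA start); the internal domain begins at
#' the PBS start.  \code{pbsOffset} is the intervening distance from the
#' boxC end to the PBS start.  All intervals are on the plus strand; for a
#' minus-strand chain the element reads right to left.
#'
#' @param chain A single chain (length-1 \link[GenomicRanges]{GRanges}
#'   from [searchLinked()] with three motif sites).
#' @param ltr5Flank Nucleotides of LTR assumed upstream of boxA. Default 0.
#' @return A [CassandraElement-class].
#' @export
annotateElement <- function(chain, ltr5Flank = 0L) {
  stopifnot(is(chain, "GRanges"), length(chain) == 1L)
  sites <- S4Vectors::mcols(chain)$sites
  if (is.null(sites) || length(sites[[1L]]) != 3L)
    stop("incompatible query: a chain with boxA, boxC and PBS sites is required")
  ltr5Flank <- as.integer(ltr5Flank)
  boxA <- .chainSite(chain, 1L)
  boxC <- .chainSite(chain, 2L)
  pbs <- .chainSite(chain, 3L)
  sd <- as.character(GenomicRanges::strand(chain))
  if (sd == "+") {
    ltr5 <- IRanges::IRanges(IRanges::start(boxA) - ltr5Flank,
                             IRanges::start(pbs) - 1L)
    internal <- IRanges::IRanges(IRanges::start(pbs),
                                 GenomicRanges::end(chain))
    pbsOffset <- IRanges::start(pbs) - IRanges::end(boxC) - 1L
  } else {
    ltr5 <- IRanges::IRanges(IRanges::end(pbs) + 1L,
                             IRanges::end(boxA) + ltr5Flank)
    internal <- IRanges::IRanges(GenomicRanges::start(chain),
                                 IRanges::end(pbs))
    pbsOffset <- IRanges::start(boxC) - IRanges::end(pbs) - 1L
  }
  new("CassandraElement",
      seqId = as.character(GenomicRanges::seqnames(chain)),
      strand = sd, ltr5 = ltr5, internal = internal,
      ltr3 = IRanges::IRanges(), pbs = pbs, boxA = boxA, boxC = boxC,
      pbsOffset = pbsOffset)
}

#' Locate the 3' LTR of an isolated element
#'
#' Scans downstream of an element's internal domain for the next
#' boxA--boxC promoter pair (gap range as in the Cassandra query) and, if
#' found, records a 3' LTR of the same width as the 5' LTR starting at
#' that boxA.  Intended for isolated complete elements
#' (LTR-internal-LTR); inside a tandem array the next LTR belongs to the
#' following unit.
#'
#' @param element A [CassandraElement-class].
#' @param seq The source sequence (plus strand).
#' @param maxGap Maximum intervening distance from the internal domain end
#'   to the next boxA start. Default 1000.
#' @param boxGap Gap range between boxA and boxC. Default \code{c(15, 25)}.
#' @return The element with \code{ltr3} filled in when found.
#' @export
locateLtr3 <- function(element, seq, maxGap = 1000L, boxGap = c(15L, 25L)) {
  stopifnot(is(element, "CassandraElement"))
  if (element@strand != "+")
    stop("locateLtr3 currently supports plus-strand elements")
  q <- linkedQuery(c(.CASSANDRA_BOXA, .CASSANDRA_BOXC),
                   gapMin = boxGap[1L], gapMax = boxGap[2L],
                   name = "ltr_promoter")
  hits <- searchLinked(seq, q, strand = "+", seqId = element@seqId)
  lo <- IRanges::end(element@internal) - nchar(.CASSANDRA_PBS)
  hits <- hits[GenomicRanges::start(hits) > lo &
                 GenomicRanges::start(hits) <= lo + maxGap + 1L]
  if (length(hits) == 0L) return(element)
  a <- GenomicRanges::start(hits)[1L]
  element@ltr3 <- IRanges::IRanges(a, a + IRanges::width(element@ltr5) - 1L)
  ## the internal domain ends where the 3' LTR begins
  element@internal <- IRanges::IRanges(IRanges::start(element@internal),
                                       a - 1L)
  element
}

#' Decompose a tandem-array hit into alternating segments
#'
#' Maps an array of \code{n} unit chains onto the alternating
#' LTR-internal-domain structure: one LTR per unit chain (boxA start to
#' just before the PBS) and one internal domain between each pair of
#' consecutive LTRs, so \code{nLtrs == n} and \code{nInternal == n - 1}.
#' The unit period is the median distance between consecutive LTR starts.
#' When the true repeat-region extent is supplied (for example from
#' generator truth), a terminal unit shorter than \code{truncFrac} times
#' the median period is flagged as truncated; without it the terminal
#' flag is \code{NA}.
#'
#' @param array A single array hit (length-1 \link[GenomicRanges]{GRanges}
#'   from [searchTandem()]).
#' @param elements Optional list of [CassandraElement-class], one per unit
#'   chain; derived with [annotateElement()] when omitted.
#' @param arrayExtent Optional \link[IRanges]{IRanges} of the full repeat
#'   region, used to measure the terminal unit.
#' @param truncFrac Fraction of the median period below which a terminal
#'   unit is called truncated. Default 0.8.
#' @param ltr5Flank Passed to [annotateElement()].
#' @return A [TandemArrayModel-class].
#' @export
decomposeArray <- function(array, elements = NULL, arrayExtent = NULL,
                           truncFrac = 0.8, ltr5Flank = 0L) {
  stopifnot(is(array, "GRanges"), length(array) == 1L)
  chains <- S4Vectors::mcols(array)$unitChains[[1L]]
  n <- length(chains)
  if (is.null(elements))
    elements <- lapply(seq_len(n), function(i)
      annotateElement(chains[i], ltr5Flank = ltr5Flank))
  if (length(elements) != n)
    stop("annotation error: one element per unit chain is required")
  sd <- as.character(GenomicRanges::strand(array))
  seqId <- as.character(GenomicRanges::seqnames(array))
  ## order elements along the plus strand
  aStart <- vapply(elements, function(e) IRanges::start(e@boxA), integer(1L))
  o <- order(aStart)
  elements <- elements[o]; aStart <- aStart[o]
  ltr <- lapply(elements, function(e) e@ltr5)
  segStart <- integer(0L); segEnd <- integer(0L); segType <- character(0L)
  for (i in seq_len(n)) {
    segStart <- c(segStart, IRanges::start(ltr[[i]]))
    segEnd <- c(segEnd, IRanges::end(ltr[[i]]))
    segType <- c(segType, "long_terminal_repeat")
    if (i < n) {
      a <- IRanges::end(ltr[[i]]) + 1L
      b <- IRanges::start(ltr[[i + 1L]]) - 1L
      if (b < a) stop("annotation error: non-alternating segmentation")
      segStart <- c(segStart, a); segEnd <- c(segEnd, b)
      segType <- c(segType, "internal_domain")
    }
  }
  if (n >= 2L) {
    d <- diff(aStart)
    period <- stats::median(d)
    spread <- max(d) - min(d)
  } else {
    period <- NA_real_; spread <- NA_real_
  }
  truncated <- rep(FALSE, length(segType))
  lastIdx <- length(segType)   # terminal LTR segment
  if (!is.null(arrayExtent) && n >= 2L) {
    lastUnit <- IRanges::end(arrayExtent) - aStart[n] + 1L
    truncated[lastIdx] <- lastUnit < truncFrac * period
  } else {
    truncated[lastIdx] <- NA
  }
  segments <- GenomicRanges::GRanges(
    seqnames = seqId,
    ranges = IRanges::IRanges(segStart, segEnd),
    strand = sd, type = segType, truncated = truncated)
  new("TandemArrayModel", seqId = seqId, strand = sd, segments = segments,
      nLtrs = n, nInternal = n - 1L, unitPeriod = as.numeric(period),
      periodSpread = as.numeric(spread))
}

#' Unit period of a tandem array model
#'
#' Median and spread (max minus min) of the consecutive LTR-start
#' distances.  Errors for single-unit arrays, whose period is undefined.
#'
#' @param model A [TandemArrayModel-class].
#' @return Named numeric vector \code{c(period, spread)} in nucleotides.
#' @export
unitPeriod <- function(model) {
  stopifnot(is(model, "TandemArrayModel"))
  if (model@nLtrs < 2L)
    stop("unit period is undefined for a single-unit array")
  c(period = model@unitPeriod, spread = model@periodSpread)
}
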