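# Distance-constrained chained motif search ("linked search") and its
# tandem (repeated-unit) form.  Chains are enumerated by interval chaining
# over per-motif site lists; the gap between consecutive sites is the
# intervening nucleotide count (start2 - end1 - 1 in 1-based coordinates).

## Enumerate all site tuples satisfying the gap constraints.
## sites: list of data.frames (start, end, mm), one per motif, sorted by start.
## Returns a matrix of row indices (one column per motif).
.enumChains <- function(sites, gapMin, gapMax) {
  K <- length(sites)
  n1 <- nrow(sites[[1L]])
  if (n1 == 0L) return(matrix(integer(0L), ncol = K))
  part <- matrix(seq_len(n1), ncol = 1L)
  for (k in seq_len(K - 1L)) {
    nxt <- sites[[k + 1L]]
    if (nrow(nxt) == 0L) return(matrix(integer(0L), ncol = K))
    ends <- sites[[k]]$end[part[, k]]
    lo <- ends + gapMin[k] + 1L     # allowed start range of next site
    hi <- ends + gapMax[k] + 1L
    ## nxt$start is sorted: locate the window by binary search
    i1 <- findInterval(lo - 1L, nxt$start) + 1L
    i2 <- findInterval(hi, nxt$start)
    cnt <- pmax(0L, i2 - i1 + 1L)
    if (sum(cnt) == 0L) return(matrix(integer(0L), ncol = K))
    keep <- which(cnt > 0L)
    rows <- rep(keep, cnt[keep])
    nxtIdx <- unlist(lapply(keep, function(r) seq.int(i1[r], i2[r])),
                     use.names = FALSE)
    part <- cbind(part[rows, , drop = FALSE], nxtIdx)
  }
  part
}

## Collapse chains sharing any motif site: keep fewest mismatches, then
## leftmost start, then smallest span.  chains: data.frame with columns
## start, end, mm and a list-column of site keys.
.collapseChains <- function(start, end, mm, siteKeys) {
  o <- order(mm, start, end - start)
  used <- character(0L)
  keep <- logical(length(o))
  for (i in o) {
    if (any(siteKeys[[i]] %in% used)) next
    keep[i] <- TRUE
    used <- c(used, siteKeys[[i]])
  }
  keep
}

#' Execute a linked (associated) search
#'
#' Finds all chains of motif occurrences satisfying, in order, every gap
#' constraint of a [LinkedQuery-class].  The gap between consecutive sites
#' is the number of intervening nucleotides.  Chains sharing any motif
#' site are collapsed, keeping the chain with the fewest mismatches, then
#' the leftmost start, then the smallest span.  Minus-strand chains are
#' found by scanning the reverse complement and mapping coordinates back
#' to the plus strand.
#'
#' @param seq A single nucleotide string.
#' @param query A [LinkedQuery-class].
#' @param maxMismatch Mismatch budget per motif: a scalar recycled over
#'   motifs or a vector with one entry per motif. Default 0.
#' @param strand \code{"both"} (default) or \code{"+"}.
#' @param seqId Sequence name for the result. Default \code{"seq"}.
#' @return A \link[GenomicRanges]{GRanges} of chain spans (1-based
#'   inclusive, plus-strand coordinates), sorted by (start, strand), with
#'   metadata columns \code{totalMismatches}, \code{queryName} and
#'   \code{sites}, an \link[IRanges]{IRangesList} of the per-chain motif
#'   footprints in query motif order.
#' @examples
#' q <- cassandraQuery()
#' seq <- paste0("AGTTAAGTATGT", strrep("C", 18), "AAAATAGGTAACT",
#'               strrep("C", 30), "TGGTATCAGAGC")
#' searchLinked(seq, q, strand = "+")
#' @export
searchLinked <- function(seq, query, maxMismatch = 0L,
                         strand = c("both", "+"), seqId = "seq") {
  strand <- match.arg(strand)
  stopifnot(is(query, "LinkedQuery"))
  seq <- .normalizeSeq(seq)
  K <- length(query@motifs)
  mlen <- nchar(query@motifs)
  maxMismatch <- as.integer(rep(maxMismatch, length.out = K))
  if (any(maxMismatch < 0L)) stop("mismatch budgets must be non-negative")
  if (any(maxMismatch >= mlen))
    stop("mismatch budget must be smaller than the motif length")
  L <- nchar(seq)
  strands <- if (strand == "both") c("+", "-") else "+"

  out <- list()
  for (sd in strands) {
    oriented <- if (sd == "+") seq else revComp(seq)
    codes <- .seqCodes(oriented)
    sites <- vector("list", K)
    for (k in seq_len(K)) {
      hit <- .scanCodes(codes, .seqCodes(query@motifs[k]), maxMismatch[k])
      sites[[k]] <- data.frame(start = hit$start,
                               end = hit$start + mlen[k] - 1L,
                               mm = hit$mismatches)
    }
    idx <- .enumChains(sites, query@gapMin, query@gapMax)
    if (nrow(idx) == 0L) next
    ## per-chain footprints on the oriented sequence
    startsO <- sites[[1L]]$start[idx[, 1L]]
    endsO <- sites[[K]]$end[idx[, K]]
    mmTot <- rowSums(matrix(vapply(seq_len(K),
                                   function(k) sites[[k]]$mm[idx[, k]],
                                   numeric(nrow(idx))), nrow = nrow(idx)))
    siteStartO <- matrix(vapply(seq_len(K),
                                function(k) sites[[k]]$start[idx[, k]],
                                integer(nrow(idx))), nrow = nrow(idx))
    ## map to plus-strand coordinates
    if (sd == "+") {
      spanStart <- startsO; spanEnd <- endsO
      siteStart <- siteStartO
      siteEnd <- sweep(siteStartO, 2L, mlen - 1L, "+")
    } else {
      spanStart <- L - endsO + 1L; spanEnd <- L - startsO + 1L
      siteEnd <- L - siteStartO + 1L
      siteStart <- sweep(siteEnd, 2L, mlen - 1L, "-")
    }
    df <- data.frame(start = spanStart, end = spanEnd, mm = mmTot,
                     strand = sd)
    out[[sd]] <- list(df = df, siteStart = siteStart, siteEnd = siteEnd)
  }
  if (length(out) == 0L) return(.emptyChainGRanges())

  df <- do.call(rbind, lapply(out, `[[`, "df"))
  siteStart <- do.call(rbind, lapply(out, `[[`, "siteStart"))
  siteEnd <- do.call(rbind, lapply(out, `[[`, "siteEnd"))
  keys <- lapply(seq_len(nrow(df)), function(i)
    paste0(seq_len(K), ":", siteStart[i, ], ":", df$strand[i]))
  keep <- .collapseChains(df$start, df$end, df$mm, keys)
  df <- df[keep, , drop = FALSE]
  siteStart <- siteStart[keep, , drop = FALSE]
  siteEnd <- siteEnd[keep, , drop = FALSE]
  o <- order(df$start, df$strand)
  df <- df[o, , drop = FALSE]
  siteStart <- siteStart[o, , drop = FALSE]
  siteEnd <- siteEnd[o, , drop = FALSE]
  sitesList <- IRanges::IRangesList(lapply(seq_len(nrow(df)), function(i) {
    ir <- IRanges::IRanges(start = siteStart[i, ], end = siteEnd[i, ])
    names(ir) <- query@motifs
    ir
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = seqId,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    totalMismatches = as.integer(df$mm),
    queryName = query@name,
    sites = sitesList)
  gr
}

.emptyChainGRanges <- function() {
  GenomicRanges::GRanges(
    seqnames = character(0L), ranges = IRanges::IRanges(),
    strand = character(0L),
    totalMismatches = integer(0L), queryName = character(0L),
    sites = IRanges::IRangesList())
}

#' Search for tandem arrays of a repeated linked query
#'
#' Unit chains are found as in [searchLinked()], then chained greedily
#' left to right (per sequence and strand) into maximal runs whose
#' consecutive end-to-start gaps lie inside the query's unit gap range.
#' Runs with fewer than \code{minRepeats} unit chains are discarded.
#' Unit chains on opposite strands never join one array.
#'
#' @param seq A single nucleotide string.
#' @param query A [TandemQuery-class].
#' @param maxMismatch,strand,seqId As in [searchLinked()].
#' @param minRepeats Override of the query's minimum run length.
#' @return A \link[GenomicRanges]{GRanges} of array spans sorted by
#'   (seqnames, start), with metadata columns \code{nUnits},
#'   \code{interUnitGaps} (\link[IRanges]{IntegerList}) and
#'   \code{unitChains}, a \link[GenomicRanges]{GRangesList} holding each
#'   array's unit chains as returned by [searchLinked()].
#' @export
searchTandem <- function(seq, query, maxMismatch = 0L,
                         strand = c("both", "+"), seqId = "seq",
                         minRepeats = NULL) {
  strand <- match.arg(strand)
  stopifnot(is(query, "TandemQuery"))
  if (is.null(minRepeats)) minRepeats <- query@minRepeats
  minRepeats <- as.integer(minRepeats)
  if (minRepeats < 1L) stop("minRepeats must be >= 1")
  chains <- searchLinked(seq, query@unit, maxMismatch = maxMismatch,
                         strand = strand, seqId = seqId)
  .chainIntoArrays(chains, query@unitGapMin, query@unitGapMax, minRepeats)
}

## Greedy maximal runs of chains under the unit gap constraint.
.chainIntoArrays <- function(chains, gapMin, gapMax, minRepeats) {
  empty <- GenomicRanges::GRanges(
    seqnames = character(0L), ranges = IRanges::IRanges(),
    strand = character(0L), nUnits = integer(0L),
    interUnitGaps = IRanges::IntegerList(),
    unitChains = GenomicRanges::GRangesList())
  if (length(chains) == 0L) return(empty)
  runs <- list()
  for (sd in c("+", "-")) {
    idx <- which(as.character(GenomicRanges::strand(chains)) == sd)
    if (length(idx) == 0L) next
    idx <- idx[order(GenomicRanges::start(chains)[idx])]
    cur <- idx[1L]
    for (i in idx[-1L]) {
      gap <- GenomicRanges::start(chains)[i] -
        GenomicRanges::end(chains)[cur[length(cur)]] - 1L
      if (gap >= gapMin && gap <= gapMax) {
        cur <- c(cur, i)
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- i
      }
    }
    runs[[length(runs) + 1L]] <- cur
  }
  runs <- Filter(function(r) length(r) >= minRepeats, runs)
  if (length(runs) == 0L) return(empty)
  spanStart <- vapply(runs, function(r)
    min(GenomicRanges::start(chains)[r]), integer(1L))
  spanEnd <- vapply(runs, function(r)
    max(GenomicRanges::end(chains)[r]), integer(1L))
  sd <- vapply(runs, function(r)
    as.character(GenomicRanges::strand(chains))[r[1L]], character(1L))
  o <- order(spanStart)
  runs <- runs[o]; spanStart <- spanStart[o]; spanEnd <- spanEnd[o]
  sd <- sd[o]
  gaps <- IRanges::IntegerList(lapply(runs, function(r) {
    if (length(r) < 2L) return(integer(0L))
    GenomicRanges::start(chains)[r[-1L]] -
      GenomicRanges::end(chains)[r[-length(r)]] - 1L
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(chains))[vapply(
      runs, `[`, integer(1L), 1L)],
    ranges = IRanges::IRanges(start = spanStart, end = spanEnd),
    strand = sd,
    nUnits = lengths(runs),
    interUnitGaps = gaps,
    unitChains = GenomicRanges::GRangesList(lapply(runs, function(r)
      chains[r])))
  gr
}
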