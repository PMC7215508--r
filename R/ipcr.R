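# In silico PCR on tandem templates: primer binding sites with a 3'
# anchor rule, amplicon enumeration under the 5'-to-5' inclusive length
# convention, ladder fitting, and a plain-text virtual gel.

#' Find primer binding sites on a template
#'
#' Plus-strand sites are positions where the primer (5' to 3') matches the
#' template left to right; minus-strand sites are positions where the
#' reverse complement of the primer matches (the primer's 3' end then
#' points leftward).  A site is reported only when it has at most
#' \code{maxMismatch} mismatches in total and none in the 3'-terminal
#' \code{anchorLen} bases (polymerase extension requires a matched 3'
#' end).  Coordinates are the primer footprint on the plus strand,
#' 1-based inclusive.
#'
#' @param template A single nucleotide string.
#' @param primer Primer sequence, 5' to 3' (IUPAC codes allowed).
#' @param maxMismatch Total mismatch budget. Default 2.
#' @param anchorLen Length of the mismatch-free 3' anchor. Default 3.
#' @param seqId Template name. Default \code{"template"}.
#' @param primerId Identifier stored with the sites.
#' @return A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{mismatches} and \code{primer}.
#' @export
findBindingSites <- function(template, primer, maxMismatch = 2L,
                             anchorLen = 3L, seqId = "template",
                             primerId = "primer") {
  template <- .normalizeSeq(template, "template")
  primer <- .normalizeSeq(primer, "primer")
  m <- nchar(primer)
  anchorLen <- as.integer(anchorLen)
  maxMismatch <- as.integer(maxMismatch)
  if (anchorLen < 0L || anchorLen > m)
    stop("anchorLen must lie between 0 and the primer length")
  if (maxMismatch < 0L || maxMismatch >= m)
    stop("maxMismatch must be non-negative and smaller than the primer length")
  codes <- .seqCodes(template)

  scanWithAnchor <- function(pat, anchorIdx) {
    full <- .scanCodes(codes, pat, maxMismatch)
    if (length(full$start) == 0L || anchorLen == 0L) return(full)
    ok <- vapply(seq_along(full$start), function(i) {
      s <- full$start[i]
      b <- codes[s + anchorIdx - 1L]
      all(bitwAnd(pat[anchorIdx], b) == b)
    }, logical(1L))
    list(start = full$start[ok], mismatches = full$mismatches[ok])
  }

  patF <- .seqCodes(primer)
  fw <- scanWithAnchor(patF, seq.int(m - anchorLen + 1L, m))
  patR <- .seqCodes(revComp(primer))
  ## on the minus strand the primer's 3' end maps to the leftmost
  ## footprint positions
  rv <- scanWithAnchor(patR, seq_len(anchorLen))
  st <- c(fw$start, rv$start)
  mm <- c(fw$mismatches, rv$mismatches)
  sd <- c(rep("+", length(fw$start)), rep("-", length(rv$start)))
  o <- order(st, sd)
  GenomicRanges::GRanges(
    seqnames = if (length(o)) seqId else character(0L),
    ranges = IRanges::IRanges(start = st[o], width = m),
    strand = sd[o], mismatches = mm[o],
    primer = rep(primerId, length(o)))
}

#' Enumerate candidate PCR products
#'
#' One amplicon per pair of a plus-strand (forward-role) site and a
#' downstream minus-strand (reverse-role) site with non-overlapping
#' footprints.  The product length follows the 5'-to-5' inclusive
#' convention: reverse-primer 5' coordinate minus forward-primer 5'
#' coordinate plus one, so both primer footprints are included.
#'
#' @param fwdSites Plus-strand sites (\link[GenomicRanges]{GRanges}).
#' @param revSites Minus-strand sites on the same template.
#' @param maxLen Maximum product length retained (nt). Default 10000.
#' @param boundaries Optional integer vector of tandem-unit boundary
#'   positions used to annotate \code{junctions} (boundaries strictly
#'   inside each product).
#' @return A \link[GenomicRanges]{GRanges} of products with metadata
#'   columns \code{length} and \code{junctions}, sorted by length.
#' @export
enumerateAmplicons <- function(fwdSites, revSites, maxLen = 10000L,
                               boundaries = NULL) {
  fwdSites <- fwdSites[as.character(GenomicRanges::strand(fwdSites)) == "+"]
  revSites <- revSites[as.character(GenomicRanges::strand(revSites)) == "-"]
  empty <- GenomicRanges::GRanges(
    seqnames = character(0L), ranges = IRanges::IRanges(),
    strand = character(0L), length = integer(0L), junctions = integer(0L))
  if (length(fwdSites) == 0L || length(revSites) == 0L) return(empty)
  f <- GenomicRanges::start(fwdSites)
  fe <- GenomicRanges::end(fwdSites)
  r <- GenomicRanges::start(revSites)
  re <- GenomicRanges::end(revSites)
  pairs <- expand.grid(i = seq_along(f), j = seq_along(r))
  ok <- r[pairs$j] > fe[pairs$i]                 # non-overlapping footprints
  len <- re[pairs$j] - f[pairs$i] + 1L           # 5'-to-5' inclusive
  ok <- ok & len <= maxLen
  pairs <- pairs[ok, , drop = FALSE]; len <- len[ok]
  if (nrow(pairs) == 0L) return(empty)
  st <- f[pairs$i]; en <- re[pairs$j]
  jn <- if (is.null(boundaries)) rep(NA_integer_, length(st)) else
    vapply(seq_along(st), function(k)
      sum(boundaries > st[k] & boundaries <= en[k]), integer(1L))
  o <- order(len, st)
  GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(fwdSites))[1L],
    ranges = IRanges::IRanges(start = st[o], end = en[o]),
    strand = "+", length = len[o], junctions = jn[o])
}

#' Predict the amplicon ladder of a primer pair on a template
#'
#' Binding sites of both primers are found on both strands; every
#' plus-strand site (of either primer) is paired with every downstream
#' minus-strand site, products are deduplicated by length and sorted.
#' The base is the smallest rung and the period the median
#' consecutive-rung difference (0 with fewer than two rungs).  On a clean
#' tandem template the period equals the tandem unit length and the
#' formula renders as \code{"base + (period)_n"}.  A primer pair with no
#' products yields an empty ladder, not an error.
#'
#' @param template A single nucleotide string.
#' @param fwd,rev Primer sequences, 5' to 3'.
#' @param maxLen,maxMismatch,anchorLen As in [findBindingSites()] and
#'   [enumerateAmplicons()].
#' @param boundaries Optional unit boundary positions (see
#'   [enumerateAmplicons()]).
#' @param seqId Template name.
#' @return A [Ladder-class].
#' @export
predictLadder <- function(template, fwd, rev, maxLen = 10000L,
                          maxMismatch = 2L, anchorLen = 3L,
                          boundaries = NULL, seqId = "template") {
  sF <- findBindingSites(template, fwd, maxMismatch, anchorLen, seqId, "fwd")
  sR <- findBindingSites(template, rev, maxMismatch, anchorLen, seqId, "rev")
  plus <- c(sF[as.character(GenomicRanges::strand(sF)) == "+"],
            sR[as.character(GenomicRanges::strand(sR)) == "+"])
  minus <- c(sF[as.character(GenomicRanges::strand(sF)) == "-"],
             sR[as.character(GenomicRanges::strand(sR)) == "-"])
  amps <- enumerateAmplicons(plus, minus, maxLen = maxLen,
                             boundaries = boundaries)
  lens <- sort(unique(S4Vectors::mcols(amps)$length))
  if (length(lens) == 0L) {
    warning("no products predicted for this primer pair (empty ladder)")
    return(new("Ladder", lengths = integer(0L), base = NA_integer_,
               period = 0, formula = "(empty)", amplicons = amps))
  }
  base <- lens[1L]
  period <- if (length(lens) >= 2L) stats::median(diff(lens)) else 0
  new("Ladder", lengths = as.integer(lens), base = as.integer(base),
      period = as.numeric(period),
      formula = sprintf("%d + (%d)_n", base, as.integer(round(period))),
      amplicons = amps)
}

#' Render ladders as a plain-text virtual gel
#'
#' Draws one lane per ladder with bands placed monotonically by
#' log(length), largest fragments at the top, as on an agarose gel.
#' Bands outside \code{range} are clipped with a warning.  Output is
#' deterministic for fixed input.
#'
#' @param ladders A [Ladder-class] or list of ladders (lanes).
#' @param range Length range displayed. Default \code{c(100, 10000)}.
#' @param height Number of character rows. Default 30.
#' @param labels Optional lane labels.
#' @return Invisibly, the character vector of gel rows (also printed).
#' @export
renderGel <- function(ladders, range = c(100L, 10000L), height = 30L,
                      labels = NULL) {
  if (is(ladders, "Ladder")) ladders <- list(ladders)
  stopifnot(length(ladders) >= 1L)
  if (is.null(labels)) labels <- paste0("L", seq_along(ladders))
  laneW <- max(6L, nchar(labels) + 1L)
  rows <- matrix(" ", nrow = height, ncol = length(ladders))
  for (l in seq_along(ladders)) {
    lens <- ladderLengths(ladders[[l]])
    out <- lens[lens < range[1L] | lens > range[2L]]
    if (length(out))
      warning(length(out), " band(s) outside the displayed range clipped")
    lens <- lens[lens >= range[1L] & lens <= range[2L]]
    if (length(lens) == 0L) next
    ## top row = largest size
    rel <- (log(range[2L]) - log(lens)) / (log(range[2L]) - log(range[1L]))
    at <- pmin(height, pmax(1L, 1L + as.integer(round(rel * (height - 1L)))))
    rows[at, l] <- "="
  }
  pad <- function(x) formatC(x, width = laneW)
  lines <- c(paste(vapply(labels, pad, ""), collapse = ""),
             vapply(seq_len(height), function(i)
               paste(vapply(rows[i, ], pad, ""), collapse = ""), ""))
  cat(lines, sep = "\n")
  invisible(lines)
}
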