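# Nucleotide alphabet services: IUPAC degenerate codes as 4-bit masks
# (A=1, C=2, G=4, T=8); a subject letter matches a pattern code iff the
# subject's base set is a subset of the pattern's base set.

.IUPAC_LETTERS <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

.IUPAC_COMP_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_COMP_TO   <- "TGCAYRSWMKVHDBN"

.POPCOUNT4 <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 1L, `5` = 2L, `6` = 2L,
                `7` = 3L, `8` = 1L, `9` = 2L, `10` = 2L, `11` = 3L,
                `12` = 2L, `13` = 3L, `14` = 3L, `15` = 4L)

## Normalise a nucleotide string: upper-case, U coerced to T (RNA input),
## and reject anything outside the IUPAC alphabet, naming the first
## offending position.
.normalizeSeq <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x))
    stop(what, " must be a single character string")
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  if (nchar(x) == 0L) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!(ch %in% .IUPAC_LETTERS))
  if (length(bad))
    stop("invalid character '", ch[bad[1L]], "' in ", what,
         " at position ", bad[1L], " (IUPAC nucleotide codes expected)")
  x
}

.seqCodes <- function(x) {
  if (nchar(x) == 0L) return(integer(0L))
  unname(.IUPAC_MASK[strsplit(x, "", fixed = TRUE)[[1L]]])
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements every IUPAC code (\code{R} with \code{Y}, \code{K} with
#' \code{M}, \code{B} with \code{V}, \code{D} with \code{H}; \code{S},
#' \code{W} and \code{N} are self-complementary) and reverses the string.
#' Input is case-insensitive and \code{U} is accepted as \code{T}.
#'
#' @param seq A single nucleotide string over the IUPAC alphabet.
#' @return The reverse-complemented string, upper-cased.
#' @examples
#' revComp("TGGTATCAGAGC")
#' revComp("RGTTAAGYRHGY")
#' @export
revComp <- function(seq) {
  seq <- .normalizeSeq(seq)
  if (nchar(seq) == 0L) return(seq)
  comp <- chartr(.IUPAC_COMP_FROM, .IUPAC_COMP_TO, seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Degeneracy of an IUPAC motif
#'
#' Number of distinct concrete A/C/G/T strings matching a degenerate motif:
#' the product of the per-position code cardinalities.
#'
#' @param motif A single IUPAC nucleotide string.
#' @return A positive number (may exceed integer range for long motifs).
#' @examples
#' motifDegeneracy("ACGT")           # 1
#' motifDegeneracy("RGTTAAGYRHGY")   # 48
#' @export
motifDegeneracy <- function(motif) {
  motif <- .normalizeSeq(motif, "motif")
  if (nchar(motif) == 0L) stop("motif must be non-empty")
  prod(.POPCOUNT4[as.character(.seqCodes(motif))])
}

## Core scanner: positions (1-based) where the degenerate pattern matches
## the coded subject with at most maxMismatch positions violating their
## IUPAC code.  Returns list(start, mismatches).
.scanCodes <- function(codes, patMasks, maxMismatch) {
  n <- length(codes); m <- length(patMasks)
  if (n < m) return(list(start = integer(0L), mismatches = integer(0L)))
  starts <- seq_len(n - m + 1L)
  mm <- integer(length(starts))
  for (i in seq_len(m)) {
    b <- codes[starts + (i - 1L)]
    mm <- mm + as.integer(bitwAnd(patMasks[i], b) != b)
  }
  keep <- which(mm <= maxMismatch)
  list(start = starts[keep], mismatches = mm[keep])
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every occurrence of an IUPAC motif in a nucleotide sequence with
#' at most \code{maxMismatch} positions violating their code.  A degenerate
#' code matching its base set is not a mismatch.  Overlapping occurrences
#' are all reported.  Minus-strand occurrences are found by scanning for
#' the reverse complement of the motif; all coordinates are reported on the
#' plus strand of the input sequence (1-based, inclusive, as in
#' \link[GenomicRanges]{GRanges}).
#'
#' @param seq A single nucleotide string (IUPAC alphabet, case-insensitive).
#' @param motif A single IUPAC motif string.
#' @param maxMismatch Non-negative mismatch budget, strictly less than the
#'   motif length. Default 0.
#' @param strand \code{"both"} (default) or \code{"+"} for plus-strand only.
#' @param seqId Sequence name used in the result. Default \code{"seq"}.
#' @return A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{mismatches} and \code{motif}, sorted by (start, strand).
#' @examples
#' findMotif("AGTTAAGTATGT", "RGTTAAGYRHGY", strand = "+")
#' @export
findMotif <- function(seq, motif, maxMismatch = 0L, strand = c("both", "+"),
                      seqId = "seq") {
  strand <- match.arg(strand)
  seq <- .normalizeSeq(seq)
  motif <- .normalizeSeq(motif, "motif")
  m <- nchar(motif)
  if (m == 0L) stop("motif must be non-empty")
  if (nchar(seq) == 0L) stop("sequence must be non-empty")
  maxMismatch <- as.integer(maxMismatch)
  if (maxMismatch < 0L) stop("maxMismatch must be non-negative")
  if (maxMismatch >= m) stop("maxMismatch must be smaller than the motif length")
  codes <- .seqCodes(seq)
  fw <- .scanCodes(codes, .seqCodes(motif), maxMismatch)
  st <- fw$start; mm <- fw$mismatches; sd <- rep("+", length(st))
  if (strand == "both") {
    rv <- .scanCodes(codes, .seqCodes(revComp(motif)), maxMismatch)
    st <- c(st, rv$start); mm <- c(mm, rv$mismatches)
    sd <- c(sd, rep("-", length(rv$start)))
  }
  o <- order(st, sd)
  gr <- GenomicRanges::GRanges(
    seqnames = if (length(o)) seqId else character(0L),
    ranges = IRanges::IRanges(start = st[o], width = m),
    strand = sd[o],
    mismatches = mm[o],
    motif = rep(motif, length(o)))
  gr
}
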