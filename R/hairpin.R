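# Palindromic stem potential: a quantitative, alignment-based stand-in
# for thermodynamic folding of LTR transcripts.  A sequence is globally
# aligned against its own reverse complement; an aligned column counts as
# a base pair when the two template positions it represents can pair
# (Watson-Crick, plus G.U wobble in RNA mode).

## Column predicate on (a from x, b from revComp(y)): the structural
## partner of a is the complement of b, so Watson-Crick pairing reduces
## to identity; wobble G.U appears as columns (G, A) and (T, C).
.pairedMatrix <- function(a, b, wobble) {
  p <- outer(a, b, "==")
  if (wobble)
    p <- p | (outer(a == "G", b == "A", "&")) |
      (outer(a == "T", b == "C", "&"))
  p
}

## Global Needleman-Wunsch with linear gap penalty; rows vectorised via a
## running-maximum recurrence for the leftward gap term.
.nwPairAlign <- function(x, y, wobble = TRUE, match = 1, mismatch = -1,
                         gap = -2) {
  a <- strsplit(x, "", fixed = TRUE)[[1L]]
  b <- strsplit(revComp(y), "", fixed = TRUE)[[1L]]
  n1 <- length(a); n2 <- length(b)
  paired <- .pairedMatrix(a, b, wobble)
  S <- ifelse(paired, match, mismatch)
  H <- matrix(0, n1 + 1L, n2 + 1L)
  H[1L, ] <- gap * (0:n2)
  j <- 0:n2
  for (i in 2:(n1 + 1L)) {
    V <- pmax(H[i - 1L, 1:n2] + S[i - 1L, ], H[i - 1L, 2:(n2 + 1L)] + gap)
    W <- c(H[i - 1L, 1L] + gap, V)
    H[i, ] <- cummax(W - gap * j) + gap * j
  }
  ## traceback (prefer diagonal, then up, then left)
  i <- n1 + 1L; jj <- n2 + 1L
  cols <- 0L; pairedCols <- 0L; run <- 0L; best <- 0L
  pairedRun <- logical(0L)
  while (i > 1L || jj > 1L) {
    if (i > 1L && jj > 1L &&
        H[i, jj] == H[i - 1L, jj - 1L] + S[i - 1L, jj - 1L]) {
      cols <- cols + 1L
      pairedRun <- c(pairedRun, paired[i - 1L, jj - 1L])
      i <- i - 1L; jj <- jj - 1L
    } else if (i > 1L && H[i, jj] == H[i - 1L, jj] + gap) {
      cols <- cols + 1L; pairedRun <- c(pairedRun, FALSE)
      i <- i - 1L
    } else {
      cols <- cols + 1L; pairedRun <- c(pairedRun, FALSE)
      jj <- jj - 1L
    }
  }
  pairedCols <- sum(pairedRun)
  r <- rle(pairedRun)
  best <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  list(score = H[n1 + 1L, n2 + 1L], columns = cols,
       pairedColumns = pairedCols, bestStem = as.integer(best))
}

#' Pairing score of two sequences
#'
#' How well sequence \code{x} can base-pair with sequence \code{y}:
#' \code{x} is globally aligned against \code{revComp(y)} (match +1 for a
#' pairable column, mismatch -1, gap -2) and the pairing fraction is the
#' number of paired columns over all alignment columns.  With
#' \code{y = x} this is the palindromic stem score.
#'
#' @param x,y Nucleotide strings (length >= 4).
#' @param wobble Count G.U as a pair (RNA transcripts). Default
#'   \code{TRUE}; set \code{FALSE} for strict Watson-Crick pairing.
#' @param match,mismatch,gap Alignment scores. Defaults +1 / -1 / -2.
#' @return Named list: \code{pairingFraction} in [0, 1],
#'   \code{bestStemLen} (longest contiguous paired run, nt),
#'   \code{score}, \code{columns}.
#' @export
pairingScore <- function(x, y = x, wobble = TRUE, match = 1, mismatch = -1,
                         gap = -2) {
  x <- .normalizeSeq(x); y <- .normalizeSeq(y)
  if (nchar(x) < 4L || nchar(y) < 4L)
    stop("sequences of at least 4 nt are required")
  r <- .nwPairAlign(x, y, wobble = wobble, match = match,
                    mismatch = mismatch, gap = gap)
  list(pairingFraction = r$pairedColumns / r$columns,
       bestStemLen = r$bestStem, score = r$score, columns = r$columns)
}

#' Palindromic stem score of a sequence
#'
#' Scores the self-complementarity of a sequence by aligning it against
#' its own reverse complement; a reverse-complement palindrome attains a
#' pairing fraction of exactly 1.
#'
#' @inheritParams pairingScore
#' @param seq Nucleotide string (length >= 4).
#' @return As [pairingScore()].
#' @examples
#' palindromicStemScore("GGGCCC")$pairingFraction   # 1
#' palindromicStemScore("AAAAAA")$pairingFraction   # 0
#' @export
palindromicStemScore <- function(seq, wobble = TRUE, match = 1,
                                 mismatch = -1, gap = -2) {
  pairingScore(seq, seq, wobble = wobble, match = match,
               mismatch = mismatch, gap = gap)
}

#' Hairpin report for an annotated element
#'
#' Palindromic stem score of each LTR plus the cross-LTR pairing score
#' (how well the 5' LTR can pair with the 3' LTR), the quantitative
#' summary of the super-hairpin arrangement in which the two LTRs of a
#' transcript pair with each other.  For an element without a located 3'
#' LTR a partial report is returned with the missing scores set to
#' \code{NA} and \code{soloLtr = TRUE}.
#'
#' @param element A [CassandraElement-class].
#' @param seq The source sequence (plus strand).
#' @param wobble Count G.U pairs. Default \code{TRUE}.
#' @return List with \code{ltr5}, \code{ltr3}, \code{crossLtr} (each as
#'   [pairingScore()] output or \code{NA}) and \code{soloLtr}.
#' @export
elementHairpinReport <- function(element, seq, wobble = TRUE) {
  stopifnot(is(element, "CassandraElement"))
  seq <- .normalizeSeq(seq)
  sub <- function(ir) substr(seq, IRanges::start(ir), IRanges::end(ir))
  ltr5seq <- sub(element@ltr5)
  if (element@strand == "-") ltr5seq <- revComp(ltr5seq)
  out <- list(ltr5 = pairingScore(ltr5seq, wobble = wobble),
              ltr3 = NA, crossLtr = NA, soloLtr = TRUE)
  if (length(element@ltr3) == 1L) {
    ltr3seq <- sub(element@ltr3)
    if (element@strand == "-") ltr3seq <- revComp(ltr3seq)
    out$ltr3 <- pairingScore(ltr3seq, wobble = wobble)
    out$crossLtr <- pairingScore(ltr5seq, ltr3seq, wobble = wobble)
    out$soloLtr <- FALSE
  }
  out
}
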