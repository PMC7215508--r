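# Independent re-implementations used as test oracles.  Everything here
# is deliberately naive (per-position loops, expand.grid enumeration over
# all site tuples) and shares no code with the package engine.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracleRandSeq <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

## concrete-base reverse complement, written independently of revComp()
oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

## one fixed concretisation of a degenerate motif (first base of each set)
oracleConcretize <- function(motif)
  chartr("RYSWKMBDHVN", "ACCAGACAAAA", motif)

## naive per-position plus-strand scan of a concrete A/C/G/T subject
oracleScanPlus <- function(seq, motif, maxMismatch = 0L) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- strsplit(motif, "", fixed = TRUE)[[1L]]
  n <- length(s); k <- length(m)
  starts <- integer(0L); mms <- integer(0L)
  if (n >= k) {
    for (i in seq_len(n - k + 1L)) {
      mm <- 0L
      for (j in seq_len(k)) {
        if (!(s[i + j - 1L] %in% ORACLE_IUPAC[[m[j]]])) mm <- mm + 1L
        if (mm > maxMismatch) break
      }
      if (mm <= maxMismatch) {
        starts <- c(starts, i); mms <- c(mms, mm)
      }
    }
  }
  data.frame(start = starts, end = starts + k - 1L, mm = mms)
}

## exact plus-strand scan via Biostrings (degenerate pattern, concrete
## subject), an oracle entirely outside this package
oracleScanBio <- function(seq, motif, maxMismatch = 0L) {
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(motif), Biostrings::DNAString(seq),
    max.mismatch = maxMismatch,
    fixed = c(pattern = FALSE, subject = TRUE))
  st <- BiocGenerics::start(hits)
  mm <- vapply(seq_along(hits), function(i)
    Biostrings::neditStartingAt(Biostrings::DNAString(motif),
                                Biostrings::DNAString(seq), starting.at = st[i],
                                fixed = c(pattern = FALSE, subject = TRUE)),
    integer(1L))
  if (length(st) == 0L) mm <- integer(0L)
  data.frame(start = st, end = st + nchar(motif) - 1L, mm = mm)
}

## exhaustive chain enumeration (expand.grid over all site tuples) with an
## independently written collapse; returns a data.frame sorted by
## (start, strand) with columns start, end, mm, strand
oracleChains <- function(seq, motifs, gapMin, gapMax, maxMismatch = 0L,
                         strand = "both",
                         siteFun = oracleScanBio) {
  K <- length(motifs)
  onePass <- function(s) {
    sites <- lapply(motifs, function(m) siteFun(s, m, maxMismatch))
    none <- data.frame(start = integer(0L), end = integer(0L),
                       mm = integer(0L), key = character(0L),
                       stringsAsFactors = FALSE)
    if (any(vapply(sites, nrow, integer(1L)) == 0L)) return(none)
    idx <- do.call(expand.grid, lapply(sites, function(d) seq_len(nrow(d))))
    keep <- rep(TRUE, nrow(idx))
    for (k in seq_len(K - 1L)) {
      gap <- sites[[k + 1L]]$start[idx[[k + 1L]]] -
        sites[[k]]$end[idx[[k]]] - 1L
      keep <- keep & gap >= gapMin[k] & gap <= gapMax[k]
    }
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) == 0L) return(none)
    key <- vapply(seq_len(nrow(idx)), function(r)
      paste(paste0(seq_len(K), "@",
                   vapply(seq_len(K), function(k)
                     sites[[k]]$start[idx[r, k]], integer(1L))),
            collapse = ";"), character(1L))
    data.frame(
      start = sites[[1L]]$start[idx[[1L]]],
      end = sites[[K]]$end[idx[[K]]],
      mm = Reduce(`+`, lapply(seq_len(K), function(k)
        sites[[k]]$mm[idx[[k]]])),
      key = key, stringsAsFactors = FALSE)
  }
  collapse <- function(df) {
    if (nrow(df) == 0L) return(df)
    o <- order(df$mm, df$start, df$end - df$start)
    used <- character(0L)
    keep <- logical(nrow(df))
    for (i in o) {
      sk <- strsplit(df$key[i], ";", fixed = TRUE)[[1L]]
      if (!any(sk %in% used)) {
        keep[i] <- TRUE
        used <- c(used, sk)
      }
    }
    df[keep, , drop = FALSE]
  }
  plus <- collapse(onePass(seq))
  plus$strand <- rep("+", nrow(plus))
  out <- plus
  if (strand == "both") {
    L <- nchar(seq)
    mn <- collapse(onePass(oracleRevComp(seq)))
    mn$strand <- rep("-", nrow(mn))
    if (nrow(mn)) {
      st <- L - mn$end + 1L
      en <- L - mn$start + 1L
      mn$start <- st; mn$end <- en
    }
    out <- rbind(plus, mn)
  }
  out <- out[order(out$start, out$strand),
             c("start", "end", "mm", "strand"), drop = FALSE]
  rownames(out) <- NULL
  out
}

## engine chains as a comparable data.frame
chainsAsDf <- function(gr) {
  df <- data.frame(
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    mm = as.integer(S4Vectors::mcols(gr)$totalMismatches),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## one concrete Cassandra-like element body (boxA .. PBS) with the given
## intervening gaps, using independently concretised boxes
oracleElementBody <- function(g1, g2) {
  paste0(oracleConcretize("RGTTAAGYRHGY"), oracleRandSeq(g1),
         oracleConcretize("RRRATRGGTRACY"), oracleRandSeq(g2),
         "TGGTATCAGAGC")
}

## random sequence with planted concrete elements (possibly on the minus
## strand); uses the caller's RNG state
oracleTestSeq <- function(nElements = 2L, spacer = 400L, flank = 300L) {
  pieces <- character(0L)
  for (i in seq_len(nElements)) {
    body <- oracleElementBody(sample(15:25, 1L), sample(5:200, 1L))
    if (stats::runif(1L) < 0.5) body <- oracleRevComp(body)
    pieces <- c(pieces, oracleRandSeq(spacer + sample(0:200, 1L)), body)
  }
  paste0(paste(pieces, collapse = ""), oracleRandSeq(flank))
}

## all-pairs amplicon lengths, written independently: one product per
## (plus site, minus site) pair with the minus footprint strictly
## downstream of the plus footprint; 5'-to-5' inclusive length
oracleAmpliconLengths <- function(fwdStart, fwdLen, revStart, revLen,
                                  maxLen = Inf) {
  out <- integer(0L)
  for (f in fwdStart) for (r in revStart) {
    if (r > f + fwdLen - 1L) {
      len <- (r + revLen - 1L) - f + 1L
      if (len <= maxLen) out <- c(out, len)
    }
  }
  sort(out)
}
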