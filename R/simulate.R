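# Seeded generator of Cassandra-like units, tandem arrays and background
# genomes with truth annotations.  All randomness is local to an explicit
# seed (Mersenne-Twister), so outputs are byte-identical across runs.

.CASSANDRA_BOXA <- "RGTTAAGYRHGY"
.CASSANDRA_BOXC <- "RRRATRGGTRACY"
.CASSANDRA_PBS <- "TGGTATCAGAGC"

#' Cassandra consensus motifs
#'
#' The conserved RNA polymerase III promoter boxes of the 5S domain
#' carried in every Cassandra LTR (boxA, boxC, separated by about 18 nt)
#' and the primer binding site internal to the 5' LTR.
#'
#' @return Named character vector with elements \code{boxA}, \code{boxC},
#'   \code{PBS}.
#' @export
cassandraMotifs <- function() {
  c(boxA = .CASSANDRA_BOXA, boxC = .CASSANDRA_BOXC, PBS = .CASSANDRA_PBS)
}

#' The Cassandra linked query
#'
#' boxA, then boxC after 15--25 intervening nucleotides, then the PBS
#' after 5--200 nucleotides (spanning fern-like short spacers through the
#' long Brassica-like ones).
#'
#' @return A [LinkedQuery-class].
#' @export
cassandraQuery <- function() {
  linkedQuery(c(.CASSANDRA_BOXA, .CASSANDRA_BOXC, .CASSANDRA_PBS),
              gapMin = c(15L, 5L), gapMax = c(25L, 200L),
              name = "Cassandra")
}

#' The Cassandra tandem query
#'
#' The Cassandra unit query repeated with 200--1000 intervening
#' nucleotides between the PBS of one unit and the boxA of the next.
#'
#' @param minRepeats Minimum units per reported array. Default 2.
#' @return A [TandemQuery-class].
#' @export
cassandraTandemQuery <- function(minRepeats = 2L) {
  tandemQuery(cassandraQuery(), unitGap = c(200L, 1000L),
              minRepeats = minRepeats)
}

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  expr
}

.randomBases <- function(n) {
  if (n <= 0L) return(character(0L))
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

## One concrete expansion of a degenerate motif (uniform over each code's
## base set; deterministic under the caller's RNG state).
.expandMotif <- function(motif) {
  codes <- .seqCodes(motif)
  vapply(codes, function(cd) {
    bases <- c("A", "C", "G", "T")[bitwAnd(cd, c(1L, 2L, 4L, 8L)) != 0L]
    if (length(bases) == 1L) bases else sample(bases, 1L)
  }, character(1L))
}

#' Specification of a synthetic Cassandra unit
#'
#' Geometry of one tandem-repeat unit (one LTR plus one internal domain).
#' Defaults reproduce the oat-style geometry: a 229 nt LTR and a 252 nt
#' internal domain (481 nt unit), boxA 30 nt into the LTR, boxC 18 nt
#' after boxA, and the PBS at the start of the internal domain.  Motif
#' placements are checked against the Cassandra query gap windows
#' (15--25 nt boxA to boxC, 5--200 nt boxC to PBS).
#'
#' @param ltrLen LTR length (nt). Default 229.
#' @param internalLen Internal-domain length (nt). Default 252.
#' @param boxAOffset 0-based offset of boxA within the LTR. Default 30.
#' @param boxGap Intervening nucleotides between boxA and boxC.
#'   Default 18.
#' @param pbsOffset Intervening nucleotides between the internal-domain
#'   start and the PBS. Default 0 (PBS at the internal-domain start).
#' @param seed Integer seed for background bases and motif expansion.
#' @return A list of class \code{"unitSpec"}.
#' @export
unitSpec <- function(ltrLen = 229L, internalLen = 252L, boxAOffset = 30L,
                     boxGap = 18L, pbsOffset = 0L, seed = 1L) {
  spec <- list(ltrLen = as.integer(ltrLen),
               internalLen = as.integer(internalLen),
               boxAOffset = as.integer(boxAOffset),
               boxGap = as.integer(boxGap),
               pbsOffset = as.integer(pbsOffset),
               seed = as.integer(seed))
  nA <- nchar(.CASSANDRA_BOXA); nC <- nchar(.CASSANDRA_BOXC)
  nP <- nchar(.CASSANDRA_PBS)
  if (spec$boxGap < 15L || spec$boxGap > 25L)
    stop("infeasible placement: boxA-boxC gap outside the [15,25] query window")
  boxCEnd0 <- spec$boxAOffset + nA + spec$boxGap + nC   # 0-based exclusive
  if (boxCEnd0 > spec$ltrLen)
    stop("infeasible placement: boxC extends beyond the LTR")
  pbsGap <- spec$ltrLen - boxCEnd0 + spec$pbsOffset
  if (pbsGap < 5L || pbsGap > 200L)
    stop("infeasible placement: boxC-PBS gap outside the [5,200] query window")
  if (spec$pbsOffset + nP > spec$internalLen)
    stop("infeasible placement: PBS extends beyond the internal domain")
  class(spec) <- "unitSpec"
  spec
}

#' Generate one concrete Cassandra-like unit
#'
#' Builds the unit sequence (LTR then internal domain) from a
#' [unitSpec()]: uniform-random background with one deterministic
#' concrete expansion of each degenerate promoter code, the boxes at
#' their declared LTR offsets and the PBS at its internal-domain offset.
#'
#' @param spec A [unitSpec()].
#' @return List with \code{seq} (character), \code{truth}
#'   (\link[GenomicRanges]{GRanges} of 1-based motif and segment
#'   intervals on the unit) and \code{spec}.
#' @export
makeUnit <- function(spec = unitSpec()) {
  stopifnot(inherits(spec, "unitSpec"))
  .withSeed(spec$seed, {
    total <- spec$ltrLen + spec$internalLen
    bases <- .randomBases(total)
    put <- function(bases, motif, at0) {       # at0 is 0-based
      conc <- .expandMotif(motif)
      bases[at0 + seq_along(conc)] <- conc
      bases
    }
    a0 <- spec$boxAOffset
    c0 <- a0 + nchar(.CASSANDRA_BOXA) + spec$boxGap
    p0 <- spec$ltrLen + spec$pbsOffset
    bases <- put(bases, .CASSANDRA_BOXA, a0)
    bases <- put(bases, .CASSANDRA_BOXC, c0)
    bases <- put(bases, .CASSANDRA_PBS, p0)
    truth <- GenomicRanges::GRanges(
      seqnames = "unit",
      ranges = IRanges::IRanges(
        start = c(1L, spec$ltrLen + 1L, a0 + 1L, c0 + 1L, p0 + 1L),
        end = c(spec$ltrLen, total,
                a0 + nchar(.CASSANDRA_BOXA),
                c0 + nchar(.CASSANDRA_BOXC),
                p0 + nchar(.CASSANDRA_PBS))),
      strand = "+",
      type = c("long_terminal_repeat", "internal_domain",
               "boxA", "boxC", "PBS"))
    list(seq = paste(bases, collapse = ""), truth = truth, spec = spec)
  })
}

#' Concatenate a unit into a head-to-tail tandem array
#'
#' \code{n} copies of the unit immediately adjacent in head-to-tail
#' orientation; with \code{closingLtr} the array is closed by one final
#' LTR so that \code{n} LTR-internal units alternate as
#' LTR-internal-LTR-...-LTR (\code{n + 1} LTRs).
#'
#' @param unitSeq The unit sequence (LTR then internal domain).
#' @param n Number of units (>= 1).
#' @param ltrLen LTR length; required when \code{closingLtr = TRUE}.
#' @param closingLtr Append the closing LTR. Default \code{TRUE}.
#' @return The array sequence.
#' @export
makeArray <- function(unitSeq, n, ltrLen = NULL, closingLtr = TRUE) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  out <- strrep(unitSeq, n)
  if (closingLtr) {
    if (is.null(ltrLen)) stop("ltrLen is required for the closing LTR")
    out <- paste0(out, substr(unitSeq, 1L, ltrLen))
  }
  out
}

#' Plant elements and arrays in a synthetic genome
#'
#' Generates a uniform-random background sequence and inserts
#' \code{nSingletons} isolated complete elements (unit plus closing LTR)
#' and one tandem array per entry of \code{arrayUnits} (that many
#' head-to-tail units plus closing LTR) at non-overlapping seeded
#' positions, separated by at least \code{pad} nt so that neighbouring
#' features cannot chain into spurious arrays.  Substitutions at
#' \code{mutationRate} are applied within planted features only (the
#' background is already random).  Fully reproducible per seed.
#'
#' @param genomeLength Background length (bp). Default 50000.
#' @param nSingletons Number of isolated elements. Default 3.
#' @param arrayUnits Integer vector: units per planted array.
#'   Default \code{c(3)}.
#' @param mutationRate Per-site substitution rate inside features.
#'   Default 0.
#' @param spec Unit geometry ([unitSpec()]).
#' @param seed Integer seed.
#' @param pad Minimum spacing between planted features (nt). Default 1200.
#' @param seqId Genome sequence name. Default \code{"synth"}.
#' @param maxTries Placement attempts before giving up. Default 1000.
#' @return List with \code{seq}, \code{truth}
#'   (\link[GenomicRanges]{GRanges} of planted features; metadata
#'   \code{type}, \code{nUnits}), \code{chains} (truth spans of every
#'   recoverable boxA..PBS chain, metadata \code{feature}) and the
#'   generation parameters.
#' @export
plantGenome <- function(genomeLength = 50000L, nSingletons = 3L,
                        arrayUnits = c(3L), mutationRate = 0,
                        spec = unitSpec(), seed = 1L, pad = 1200L,
                        seqId = "synth", maxTries = 1000L) {
  stopifnot(inherits(spec, "unitSpec"))
  genomeLength <- as.integer(genomeLength)
  unit <- makeUnit(spec)
  unitLen <- spec$ltrLen + spec$internalLen
  featSeq <- c(
    vapply(seq_len(nSingletons), function(i)
      makeArray(unit$seq, 1L, spec$ltrLen, closingLtr = TRUE), character(1L)),
    vapply(arrayUnits, function(n)
      makeArray(unit$seq, n, spec$ltrLen, closingLtr = TRUE), character(1L)))
  featType <- c(rep("singleton", nSingletons),
                rep("tandem_array", length(arrayUnits)))
  featUnits <- c(rep(1L, nSingletons), as.integer(arrayUnits))
  nf <- length(featSeq)
  .withSeed(seed, {
    lens <- nchar(featSeq)
    if (sum(lens + pad) > genomeLength)
      stop("spec error: features do not fit the genome at this padding")
    ## rejection-sample non-overlapping starts
    starts <- integer(0L)
    ends <- integer(0L)
    for (i in seq_len(nf)) {
      placed <- FALSE
      for (t in seq_len(maxTries)) {
        s <- sample.int(genomeLength - lens[i] + 1L, 1L)
        e <- s + lens[i] - 1L
        if (all(s > ends + pad | e < starts - pad)) {
          starts <- c(starts, s); ends <- c(ends, e); placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("spec error: could not place feature ", i,
             " without overlap after ", maxTries, " tries")
    }
    bg <- .randomBases(genomeLength)
    if (mutationRate > 0)
      featSeq <- vapply(featSeq, function(s)
        .mutateChars(s, mutationRate), character(1L), USE.NAMES = FALSE)
    for (i in seq_len(nf)) {
      bg[starts[i]:ends[i]] <- strsplit(featSeq[i], "", fixed = TRUE)[[1L]]
    }
    seq <- paste(bg, collapse = "")
    o <- order(starts)
    truth <- GenomicRanges::GRanges(
      seqnames = seqId,
      ranges = IRanges::IRanges(start = starts[o], end = ends[o]),
      strand = "+", type = featType[o], nUnits = featUnits[o])
    ## truth chain spans: boxA start .. PBS end per unit copy
    a1 <- spec$boxAOffset + 1L
    pEnd <- spec$ltrLen + spec$pbsOffset + nchar(.CASSANDRA_PBS)
    chS <- integer(0L); chE <- integer(0L); chF <- integer(0L)
    for (i in seq_len(nf)) {
      for (k in seq_len(featUnits[i]) - 1L) {
        chS <- c(chS, starts[i] + k * unitLen + a1 - 1L)
        chE <- c(chE, starts[i] + k * unitLen + pEnd - 1L)
        chF <- c(chF, i)
      }
    }
    oc <- order(chS)
    chains <- GenomicRanges::GRanges(
      seqnames = seqId,
      ranges = IRanges::IRanges(start = chS[oc], end = chE[oc]),
      strand = "+", feature = chF[oc])
    list(seq = seq, truth = truth, chains = chains, spec = spec,
         seed = as.integer(seed), mutationRate = mutationRate,
         seqId = seqId)
  })
}

## substitution engine shared by mutateSeq / plantGenome (uses the
## caller's RNG state)
.mutateChars <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- ceiling(stats::runif(length(hit)) * 3)
    ch[hit] <- vapply(seq_along(hit), function(i)
      alt[[ch[hit[i]]]][pick[i]], character(1L))
  }
  paste(ch, collapse = "")
}

#' Random per-site substitution
#'
#' Independently substitutes each position with probability \code{rate}
#' to a uniformly chosen different base; deterministic per seed.
#'
#' @param seq Nucleotide string (A/C/G/T).
#' @param rate Substitution probability per site, in [0, 1).
#' @param seed Integer seed (\code{NULL} uses the current RNG state).
#' @return The mutated sequence.
#' @export
mutateSeq <- function(seq, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  seq <- .normalizeSeq(seq)
  .withSeed(seed, .mutateChars(seq, rate))
}

#' Write a planted genome with its truth annotations
#'
#' Writes the genome FASTA, the truth features as GFF3 and the truth
#' chain spans as BED (0-based half-open, as the format requires).
#'
#' @param genome Result of [plantGenome()].
#' @param dir Output directory (created if needed).
#' @param name File stem. Default \code{"synth"}.
#' @return Invisibly, the paths written.
#' @export
writeGenome <- function(genome, dir, name = "synth") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fasta"))
  gff <- file.path(dir, paste0(name, ".truth.gff3"))
  bed <- file.path(dir, paste0(name, ".chains.bed"))
  dna <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$seqId))
  Biostrings::writeXStringSet(dna, fa)
  tr <- genome$truth
  S4Vectors::mcols(tr)$ID <- paste0("feature", seq_along(tr))
  rtracklayer::export(tr, gff, format = "gff3")
  ch <- genome$chains
  S4Vectors::mcols(ch)$name <- paste0("chain", seq_along(ch))
  rtracklayer::export(ch, bed, format = "bed")
  invisible(c(fasta = fa, gff3 = gff, bed = bed))
}
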