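#' @import methods
#' @importFrom stats lm median coef aov anova t.test runif setNames
#' @importFrom utils read.delim write.table
NULL

#' LinkedQuery: ordered degenerate motifs joined by gap ranges
#'
#' A linked (associated) query is an ordered list of IUPAC motifs where
#' consecutive motifs must occur on the same strand separated by a number
#' of intervening nucleotides inside a per-link gap range.  Gap \code{i}
#' constrains the distance between the end of motif \code{i} and the start
#' of motif \code{i + 1}.
#'
#' @slot name Query identifier.
#' @slot motifs Character vector of IUPAC motifs (length >= 1).
#' @slot gapMin,gapMax Integer vectors of length \code{length(motifs) - 1}
#'   with \code{0 <= gapMin <= gapMax}.
#' @seealso [parseQuery()], [searchLinked()]
#' @export
setClass("LinkedQuery",
  representation(name = "character", motifs = "character",
                 gapMin = "integer", gapMax = "integer"))

setValidity("LinkedQuery", function(object) {
  if (length(object@motifs) < 1L) return("at least one motif is required")
  for (m in object@motifs) {
    ok <- tryCatch({ .normalizeSeq(m, "motif"); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
    if (nchar(m) == 0L) return("empty motif")
  }
  ng <- length(object@motifs) - 1L
  if (length(object@gapMin) != ng || length(object@gapMax) != ng)
    return("need exactly one gap range between consecutive motifs")
  if (ng > 0L) {
    if (any(object@gapMin < 0L)) return("gap minima must be non-negative")
    if (any(object@gapMin > object@gapMax))
      return("gap minimum exceeds gap maximum")
  }
  TRUE
})

#' Construct a LinkedQuery
#'
#' @param motifs Character vector of IUPAC motifs.
#' @param gapMin,gapMax Integer vectors of per-link gap bounds
#'   (intervening nucleotides), one entry per consecutive motif pair.
#' @param name Query identifier.
#' @return A [LinkedQuery-class] object.
#' @examples
#' linkedQuery(c("RGTTAAGYRHGY", "RRRATRGGTRACY", "TGGTATCAGAGC"),
#'             gapMin = c(15, 5), gapMax = c(25, 200), name = "Cassandra")
#' @export
linkedQuery <- function(motifs, gapMin = integer(0L), gapMax = integer(0L),
                        name = "query") {
  motifs <- vapply(motifs, .normalizeSeq, "", what = "motif", USE.NAMES = FALSE)
  new("LinkedQuery", name = as.character(name), motifs = motifs,
      gapMin = as.integer(gapMin), gapMax = as.integer(gapMax))
}

#' TandemQuery: a repeated linked query
#'
#' A tandem query repeats a unit [LinkedQuery-class]; consecutive unit
#' chains must be separated (end of the last motif to the start of the
#' next unit's first motif) by a gap inside \code{unitGapMin..unitGapMax},
#' and a run must contain at least \code{minRepeats} units.
#'
#' @slot unit The unit [LinkedQuery-class].
#' @slot unitGapMin,unitGapMax Integer gap bounds between consecutive units.
#' @slot minRepeats Minimum number of unit chains per reported array.
#' @export
setClass("TandemQuery",
  representation(unit = "LinkedQuery", unitGapMin = "integer",
                 unitGapMax = "integer", minRepeats = "integer"))

setValidity("TandemQuery", function(object) {
  if (object@unitGapMin < 0L) return("unit gap minimum must be non-negative")
  if (object@unitGapMin > object@unitGapMax)
    return("unit gap minimum exceeds maximum")
  if (object@minRepeats < 1L) return("minRepeats must be >= 1")
  TRUE
})

#' Construct a TandemQuery
#'
#' @param unit A [LinkedQuery-class] describing one repeat unit.
#' @param unitGap Length-2 integer vector, inter-unit gap range in
#'   intervening nucleotides. Default \code{c(200, 1000)}.
#' @param minRepeats Minimum run length reported as an array. Default 2.
#' @return A [TandemQuery-class] object.
#' @export
tandemQuery <- function(unit, unitGap = c(200L, 1000L), minRepeats = 2L) {
  new("TandemQuery", unit = unit, unitGapMin = as.integer(unitGap[1L]),
      unitGapMax = as.integer(unitGap[2L]), minRepeats = as.integer(minRepeats))
}

#' Annotated Cassandra element
#'
#' Structural annotation of one linked-search chain interpreted as a
#' Cassandra TRIM element: 5' LTR, internal domain, primer binding site
#' (PBS), and the two RNA polymerase III promoter boxes within the LTR.
#' All intervals are 1-based inclusive on the plus strand of the source
#' sequence.  \code{ltr3} is empty unless located separately (for example
#' with [locateLtr3()] or from generator truth).
#'
#' @slot seqId Source sequence name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot ltr5,internal,ltr3,pbs,boxA,boxC \link[IRanges]{IRanges} intervals
#'   (possibly empty for \code{ltr3}).
#' @slot pbsOffset Intervening nucleotides between the boxC end and the PBS
#'   start (in element orientation).
#' @export
setClass("CassandraElement",
  representation(seqId = "character", strand = "character",
                 ltr5 = "IRanges", internal = "IRanges", ltr3 = "IRanges",
                 pbs = "IRanges", boxA = "IRanges", boxC = "IRanges",
                 pbsOffset = "integer"))

#' Tandem array structural model
#'
#' Alternating LTR / internal-domain segmentation of a tandem array of
#' Cassandra elements, with unit-period statistics.  For a complete array
#' the pattern is LTR-internal-LTR-...-LTR so that
#' \code{nLtrs == nInternal + 1}.
#'
#' @slot seqId,strand Source sequence name and strand.
#' @slot segments \link[GenomicRanges]{GRanges} of alternating segments
#'   with metadata columns \code{type} (\code{"long_terminal_repeat"} or
#'   \code{"internal_domain"}) and \code{truncated}.
#' @slot nLtrs,nInternal Segment counts.
#' @slot unitPeriod Median distance between consecutive LTR starts (nt).
#' @slot periodSpread Max minus min of those distances (nt).
#' @export
setClass("TandemArrayModel",
  representation(seqId = "character", strand = "character",
                 segments = "GRanges", nLtrs = "integer",
                 nInternal = "integer", unitPeriod = "numeric",
                 periodSpread = "numeric"))

#' Predicted amplicon ladder
#'
#' The set of in silico PCR product lengths a primer pair yields on a
#' template, deduplicated by length (a gel cannot separate equal lengths)
#' and sorted.  On an ideal tandem template the lengths form an arithmetic
#' series \code{base + period * (rung - 1)} whose period equals the tandem
#' unit length; \code{formula} renders this as \code{"base + (period)_n"}.
#'
#' @slot lengths Sorted unique product lengths (nt).
#' @slot base Smallest rung (nt); \code{NA} for an empty ladder.
#' @slot period Median consecutive-rung difference (nt); 0 with < 2 rungs.
#' @slot formula Text rendering \code{"base + (period)_n"}.
#' @slot amplicons \link[GenomicRanges]{GRanges} of all products before
#'   length deduplication (metadata: \code{length}, \code{junctions}).
#' @export
setClass("Ladder",
  representation(lengths = "integer", base = "integer", period = "numeric",
                 formula = "character", amplicons = "GRanges"))

#' qPCR standard curve
#'
#' Least-squares fit of cycle threshold (Ct) against log10 of template
#' concentration for a dilution series.  The amplification efficiency per
#' cycle is \code{10^(-1/slope)}; a perfect doubling assay has slope
#' \code{-1/log10(2) = -3.32} and efficiency 2.
#'
#' @slot slope Cycles per log10(concentration).
#' @slot intercept Cycles at concentration 1.
#' @slot r2 Coefficient of determination.
#' @slot efficiency Fold amplification per cycle, \code{10^(-1/slope)}.
#' @slot concRange Calibrated concentration range (same units as input).
#' @slot n Number of dilution points fitted.
#' @export
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 efficiency = "numeric", concRange = "numeric", n = "integer"))

setMethod("show", "LinkedQuery", function(object) {
  cat("LinkedQuery '", object@name, "': ", formatQuery(object), "\n", sep = "")
})

setMethod("show", "TandemQuery", function(object) {
  cat("TandemQuery (minRepeats=", object@minRepeats, "): ",
      formatQuery(object), "\n", sep = "")
})

setMethod("show", "Ladder", function(object) {
  if (length(object@lengths) == 0L) {
    cat("Ladder: empty (no products)\n")
  } else {
    cat("Ladder: ", length(object@lengths), " rung(s), formula ",
        object@formula, "\n  lengths: ",
        paste(object@lengths, collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve: slope %.4f, intercept %.3f, r2 %.4f, efficiency %.3f (n=%d)\n",
    object@slope, object@intercept, object@r2, object@efficiency, object@n))
})

setMethod("show", "CassandraElement", function(object) {
  cat("CassandraElement on ", object@seqId, " (", object@strand, "): ltr5 [",
      IRanges::start(object@ltr5), ",", IRanges::end(object@ltr5),
      "], pbs [", IRanges::start(object@pbs), ",", IRanges::end(object@pbs),
      "], pbsOffset ", object@pbsOffset, "\n", sep = "")
})

setMethod("show", "TandemArrayModel", function(object) {
  cat("TandemArrayModel on ", object@seqId, " (", object@strand, "): ",
      object@nLtrs, " LTR(s), ", object@nInternal,
      " internal domain(s), unit period ", object@unitPeriod,
      " nt (spread ", object@periodSpread, ")\n", sep = "")
})

## Simple accessors -----------------------------------------------------

#' @describeIn LinkedQuery-class Motifs of a query.
#' @param x A query object.
#' @export
queryMotifs <- function(x) {
  if (is(x, "TandemQuery")) x@unit@motifs else x@motifs
}

#' @describeIn LinkedQuery-class Gap ranges as a two-column matrix.
#' @export
queryGaps <- function(x) {
  q <- if (is(x, "TandemQuery")) x@unit else x
  cbind(min = q@gapMin, max = q@gapMax)
}

#' @describeIn Ladder-class Sorted unique product lengths.
#' @param x A \code{Ladder}.
#' @export
ladderLengths <- function(x) x@lengths

#' @describeIn Ladder-class Smallest rung length.
#' @export
ladderBase <- function(x) x@base

#' @describeIn Ladder-class Median consecutive-rung spacing.
#' @export
ladderPeriod <- function(x) x@period

#' @describeIn Ladder-class Formula rendering \code{"base + (period)_n"}.
#' @export
ladderFormula <- function(x) x@formula

#' @describeIn StandardCurve-class Slope (cycles per log10 concentration).
#' @param x A \code{StandardCurve}.
#' @export
curveSlope <- function(x) x@slope

#' @describeIn StandardCurve-class Amplification efficiency per cycle.
#' @export
curveEfficiency <- function(x) x@efficiency

#' @describeIn StandardCurve-class Coefficient of determination.
#' @export
curveR2 <- function(x) x@r2
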