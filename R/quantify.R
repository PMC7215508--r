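# Copy-number arithmetic: qPCR standard curve and relative
# quantification, dot-blot absolute copy number, singleton/tandem
# decomposition, and simple group comparisons.

## Mass of 1 pg double-stranded DNA in base pairs.
.BP_PER_PG <- 978e6

#' Fit a qPCR standard curve
#'
#' Least-squares line of cycle threshold against log10 of template
#' concentration over a dilution series.  A perfect doubling assay (Ct
#' increases by one per 2-fold dilution) has slope \code{-1/log10(2) =
#' -3.32}: a tenfold concentration difference shifts Ct by 3.3 cycles.
#' The amplification efficiency per cycle is \code{10^(-1/slope)}.
#'
#' @param concentration Template amounts per reaction (e.g. ng); all > 0.
#' @param ct Cycle-threshold values, same length.
#' @return A [StandardCurve-class].
#' @examples
#' conc <- 10 / 2^(0:7)
#' fitStandardCurve(conc, 15 - log2(conc))
#' @export
fitStandardCurve <- function(concentration, ct) {
  if (is.data.frame(concentration)) {
    ct <- concentration$ct
    concentration <- concentration$concentration
  }
  if (length(concentration) != length(ct))
    stop("concentration and ct must have the same length")
  if (length(concentration) < 3L)
    stop("at least 3 dilution points are required")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  x <- log10(concentration)
  if (length(unique(concentration)) < 2L || stats::var(x) == 0)
    stop("concentrations must not all be equal")
  fit <- stats::lm(ct ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  ## a noiseless series is an exact fit; the perfect-fit warning from
  ## summary.lm is expected there and not informative
  r2 <- suppressWarnings(summary(fit)$r.squared)
  eff <- if (slope < 0) 10^(-1 / slope) else NA_real_
  new("StandardCurve", slope = slope, intercept = intercept, r2 = r2,
      efficiency = eff, concRange = range(concentration),
      n = length(ct))
}

#' Copies from a sample Ct via a standard curve
#'
#' Inverts the standard curve to infer the sample's template
#' concentration, then scales by a reference of known copy number:
#' \code{copies = refCopies * concentration / refConcentration}.  A Ct
#' lower by |slope| cycles corresponds to tenfold more copies.  Samples
#' outside the calibrated concentration range are flagged with a warning
#' (extrapolation), not an error.
#'
#' @param ct Sample cycle-threshold value(s).
#' @param curve A [StandardCurve-class].
#' @param refCopies Copy number of the reference sample.
#' @param refConcentration Concentration of the reference sample (same
#'   units as the dilution series).
#' @return Estimated copies, same length as \code{ct}.
#' @export
copiesFromCt <- function(ct, curve, refCopies, refConcentration) {
  stopifnot(is(curve, "StandardCurve"))
  conc <- 10^((ct - curve@intercept) / curve@slope)
  out <- which(conc < curve@concRange[1L] | conc > curve@concRange[2L])
  if (length(out))
    warning("sample(s) ", paste(out, collapse = ", "),
            " outside the calibrated range (extrapolated)")
  refCopies * conc / refConcentration
}

#' Absolute copy number from a dot blot
#'
#' Copies per ng of genomic DNA from hybridization signal ratios against
#' a control fragment of known copy number:
#' \code{copies(ng) = genomicCpm/genomicNg * fragmentCopies/fragmentCpm}.
#' Copies per haploid genome multiply by the genome mass in ng
#' (\code{genomeSize} bp at 978 Mbp per pg).
#'
#' @param genomicCpm Hybridization counts of the genomic DNA spot.
#' @param genomicNg Genomic DNA mass spotted (ng).
#' @param fragmentCopies Known copy count of the control fragment spot.
#' @param fragmentCpm Hybridization counts of the control fragment spot.
#' @param genomeSize Haploid genome size (bp).
#' @return Named list: \code{copiesPerNg}, \code{copiesPerGenome}.
#' @export
dotBlotCopies <- function(genomicCpm, genomicNg, fragmentCopies,
                          fragmentCpm, genomeSize) {
  if (any(c(genomicNg, fragmentCopies, genomeSize) <= 0))
    stop("masses, copies and genome size must be positive")
  if (fragmentCpm <= 0) stop("control fragment counts must be positive")
  if (genomicCpm < 0) stop("hybridization counts must be non-negative")
  perNg <- genomicCpm / genomicNg * fragmentCopies / fragmentCpm
  ngPerGenome <- genomeSize / .BP_PER_PG / 1000    # pg -> ng
  list(copiesPerNg = perNg, copiesPerGenome = perNg * ngPerGenome)
}

#' Copies per genome from a genomic mass fraction
#'
#' A probe accounting for a mass fraction \code{f} of a genome of
#' \code{genomeSize} bp is present in \code{floor(f * genomeSize /
#' probeLen)} copies.
#'
#' @param massFraction Fraction of genomic DNA mass, in (0, 1) (0 allowed).
#' @param genomeSize Haploid genome size (bp).
#' @param probeLen Probe length (nt).
#' @return Whole number of copies per haploid genome.
#' @examples
#' copiesPerGenomeFromFraction(0.0005, 4.8e9, 388)   # 6185
#' @export
copiesPerGenomeFromFraction <- function(massFraction, genomeSize, probeLen) {
  if (massFraction < 0 || massFraction >= 1)
    stop("massFraction must lie in [0, 1)")
  if (probeLen <= 0 || genomeSize <= 0)
    stop("genomeSize and probeLen must be positive")
  floor(massFraction * genomeSize / probeLen)
}

#' Singleton copies by subtracting tandem from total
#'
#' @param total Total element copies per genome.
#' @param tandem Copies residing in tandem arrays.
#' @return \code{total - tandem}.
#' @export
singletonCount <- function(total, tandem) {
  if (any(tandem < 0) || any(total < 0)) stop("copy numbers must be >= 0")
  if (any(tandem > total))
    stop("tandem copies exceed total copies (negative singleton count)")
  total - tandem
}

#' Compare copy numbers between groups
#'
#' Two groups: two-sample t test (Welch by default, pooled-variance on
#' request).  Three or more groups: one-way ANOVA.
#'
#' @param ... Two or more numeric vectors of per-accession copy numbers,
#'   or a single list of them.
#' @param varEqual Use the pooled-variance (classic Student) t test for
#'   two groups. Default \code{FALSE} (Welch).
#' @return List with \code{method}, \code{statistic}, \code{p.value} and
#'   \code{means}.
#' @export
compareGroups <- function(..., varEqual = FALSE) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1L]]) &&
      !is.numeric(groups[[1L]]))
    groups <- groups[[1L]]
  if (length(groups) < 2L) stop("at least two groups are required")
  if (any(vapply(groups, length, integer(1L)) < 2L))
    stop("each group needs at least two values")
  means <- vapply(groups, mean, numeric(1L))
  if (length(groups) == 2L) {
    if (stats::var(groups[[1L]]) == 0 && stats::var(groups[[2L]]) == 0) {
      ## degenerate: identical-variance-free groups
      if (means[1L] == means[2L])
        return(list(method = "t", statistic = 0, p.value = 1, means = means))
      return(list(method = "t", statistic = Inf, p.value = 0, means = means,
                  degenerate = TRUE))
    }
    tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = varEqual)
    return(list(method = if (varEqual) "t (pooled)" else "t (Welch)",
                statistic = unname(tt$statistic), p.value = tt$p.value,
                means = means))
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(values ~ fac)
  tab <- stats::anova(fit)
  list(method = "one-way ANOVA", statistic = tab$`F value`[1L],
       p.value = tab$`Pr(>F)`[1L], means = means)
}
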