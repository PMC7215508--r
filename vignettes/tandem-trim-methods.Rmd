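---
title: "TandemTRIM methods: model, conventions and design decisions"
author: "TandemTRIM maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TandemTRIM methods: model, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TandemTRIM)
```

# The biological model

Cassandra elements are TRIMs — terminal-repeat retrotransposons in
miniature. Each element consists of a 5' long terminal repeat (LTR)
carrying a 5S rRNA-derived promoter, a short internal domain beginning
with a primer binding site (PBS), and a 3' LTR. In tandem arrays the
elements sit head to tail, so consecutive units share orientation and
the 3' LTR of one unit is immediately followed (after a short spacer)
by the 5' LTR of the next. TandemTRIM models an element as a **linked
chain of three conserved degenerate motifs**:

| Motif | Sequence | Location |
|---|---|---|
| box A | `RGTTAAGYRHGY` | internal control region of the LTR promoter |
| box C | `RRRATRGGTRACY` | internal control region, downstream of box A |
| PBS | `TGGTATCAGAGC` | start of the internal domain, after the LTR |

with spacer constraints of 15–25 nt between box A and box C and
5–200 nt between box C and the PBS. The query text form is

```
RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]TGGTATCAGAGC
```

and `cassandraQuery()` returns it ready-built. The arithmetic extremes
of this geometry bound every reported chain span: 57 nt
(12 + 15 + 13 + 5 + 12) to 262 nt (12 + 25 + 13 + 200 + 12).

A tandem array is a maximal run of such chains on one strand whose
inter-chain gaps (intervening nucleotides between the end of one chain
and the start of the next) lie in a bounded window, 200–1000 nt by
default: `(RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]TGGTATCAGAGC)[200-1000]n`.

# Matching semantics

Motifs and subjects both use the full IUPAC alphabet. Every code is a
4-bit base-set mask (A=1, C=2, G=4, T=8); a subject letter matches a
pattern code **iff the subject's base set is a subset of the pattern's
base set** (`bitwAnd(pat, sub) == sub`). Consequences:

* `R` in the pattern matches subject `A`, `G` and `R`, but not `N`;
* `N` in the subject is matched only by pattern `N` — an ambiguous
  subject base is never silently accepted by a narrower pattern code;
* a mismatch is a position violating its code, and `maxMismatch`
  bounds the count per motif. The engine is cross-checked in the test
  suite against a naive reference scanner and against
  `Biostrings::matchPattern(fixed = c(pattern = FALSE, subject = TRUE))`.

Degeneracy (`motifDegeneracy`) is the product of per-position code
cardinalities: 48 for box A, 64 for box C.

# Coordinate convention

All results are `GRanges` with **1-based, fully inclusive** coordinates,
the native convention of the Bioconductor container classes used
throughout. BED output (0-based half-open) is produced only through
`rtracklayer::export`, which performs the conversion; no hand-rolled
offset arithmetic crosses the package boundary. Minus-strand matches
are found by scanning the reverse complement of the motif (for single
motifs) or the reverse complement of the sequence (for chains) and
mapping starts back via `start' = L - end + 1`; every search is exactly
strand-symmetric, a property asserted over seeded corpora in the tests.

# The chained search and its collapse rule

`searchLinked` scans each motif independently, then joins hits
left-to-right subject to the gap windows, where the **gap is the count
of intervening nucleotides**: `gap = start2 - end1 - 1`. Because
degenerate motifs can match at nearby offsets, several chains may share
a site. Chains sharing any site are **collapsed to a single
representative**, chosen by (1) fewest total mismatches, (2) leftmost
start, (3) smallest span. This keeps one call per biological element
while preserving every independent element. The tests compare the
engine against an exhaustive `expand.grid` enumeration with an
independently written collapse.

`searchTandem` then partitions same-strand chains into maximal runs
under the inter-unit gap window; `minRepeats` (default 2) controls
whether singletons are reported.

# Annotation

`annotateElement` segments a chain by its geometry: everything from the
start of box A through the base before the PBS is the 5' LTR, and the
PBS onward is internal domain. The PBS offset (nucleotides between the
box C end and the PBS start) is the chain's most variable dimension.
`locateLtr3` finds the 3' LTR as the next downstream LTR-promoter chain
(box A + box C without a reachable PBS, or the next unit's 5' LTR in an
array). `decomposeArray` maps an *n*-chain array to *n* LTR-promoter
units and *n − 1* complete inter-unit intervals, so `unitPeriod`
estimates the tandem period as the median start-to-start distance.
A truncation flag compares the final partial unit against 0.8 × the
median period, and is `NA` unless the physical array extent
(`arrayExtent`) is supplied — without the array's outer boundary,
truncation of the last unit is undecidable.

# In silico PCR

`findBindingSites` applies the biological extension rule: a site is
reported only if its total mismatches are within budget **and its
3'-terminal `anchorLen` bases (default 3) are mismatch-free**, because
polymerase extension requires a matched 3' end. On the minus strand the
primer's 3' end maps to the leftmost footprint position.

`enumerateAmplicons` pairs every plus-strand site with every downstream,
non-overlapping minus-strand site. The **product length is the 5'-to-5'
inclusive distance**: reverse-primer 5' coordinate − forward-primer 5'
coordinate + 1, i.e. both primer footprints are part of the product, as
in a real PCR.

On a tandem template, a divergent (inverted, outward-facing) primer
pair inside one unit yields one product per spanned repeat junction:
with *n* units and `maxLen = Inf` there are exactly *n(n − 1)/2*
forward/reverse pairings, whose distinct lengths form the arithmetic
ladder

```
length_k = base + period × (k - 1),
```

rendered by `ladderFormula` as e.g. `368 + (481)_n`. The period, taken
as the median consecutive-rung difference, equals the tandem unit
length, and therefore must coincide with the period recovered
independently by `decomposeArray` on the same template — an internal
consistency check used both in the tests and in `scripts/acceptance.R`.
`renderGel` draws lanes with bands placed by log(length), largest at
the top, deterministically.

```{r ladder}
u   <- makeUnit(unitSpec())          # 229 nt LTR + 252 nt internal domain
arr <- makeArray(u$seq, 5L, ltrLen = 229L)
fwd <- substr(arr, 383L, 403L)
rev <- revComp(substr(arr, 249L, 269L))
predictLadder(arr, fwd, rev)
```

# Quantification

`fitStandardCurve` regresses Ct on log10(concentration); a perfect
doubling assay has slope −1/log10(2) ≈ −3.32 and efficiency
`10^(-1/slope) = 2`. `copiesFromCt` inverts the curve and warns on
extrapolation beyond the calibrated range. `dotBlotCopies` scales a
hybridization signal by a single-copy reference;
`copiesPerGenomeFromFraction` converts a genome mass fraction *f* into
copies per 1C genome as `round(f × G / L)` for genome size *G* (bp) and
fragment length *L* (bp). The two routes agree by construction when fed
consistent inputs, using 978 × 10^6 bp per pg of DNA. `singletonCount`
is total copies minus tandem-resident copies; `compareGroups` offers
Welch (default) and pooled two-sample t-tests and one-way ANOVA, each
verified against hand-computed statistics in the tests.

```{r quant}
copiesPerGenomeFromFraction(0.0005, 4.8e9, 388)
```

# The hairpin score

LTR self-complementarity is scored without an RNA-folding engine:
`palindromicStemScore(s)` is the fraction of aligned columns that form
a Watson–Crick pair in a Needleman–Wunsch alignment of `s` against
`revComp(s)` — for a perfect revcomp palindrome the score is 1, and for
random sequence it settles near 0.58 (measured mean 0.5846 over 100
seeded 200-mers; the tests assert < 0.6 and strict inferiority to a
palindromic control).

With `wobble = TRUE`, G·U (here G·T) pairs also count. Because a G·T
pair in the alignment of `s` versus `revComp(s)` corresponds to columns
(G, A) or (T, C), the wobble score is **not** exactly strand-symmetric;
exact `score(s) == score(revComp(s))` holds only in Watson–Crick mode,
and the package documents and tests it that way. Mutation degrades the
score monotonically from a palindromic stem (1 → ≈0.68 at a 40%
per-base mutation rate in the test suite).

# The synthetic-data generator

`unitSpec` fixes a unit geometry (LTR length, internal-domain length,
motif offsets, seed) with validity checks that the motifs fit their
compartments and the gaps satisfy the query windows; the defaults give
a 481 nt unit (229 + 252). `makeUnit` draws one unit: degenerate motif
positions are concretised by sampling **one** concrete realisation per
seed — a deliberate realism limit, since real families carry correlated
variants, but sufficient for exact-recovery truth. `makeArray` tandems
the unit with an optional closing LTR; `plantGenome` embeds singletons
and arrays at random non-overlapping positions and strands in random
background and returns the sequence together with exact truth
`GRanges`. `mutateSeq` applies seeded per-base substitution. Everything
is reproducible byte-for-byte from the seed, and the generators
save and restore the caller's RNG state.

At mutation rate 0 the search recovers every planted element with
exact coordinates; recovery is monotone non-increasing in the mutation
rate (aggregated over seeds). Both properties are asserted in the
acceptance tests.

# Problem sizes

The test corpora use genome lengths of 15–30 kb, arrays of 2–13 units,
200-seed oracle sweeps and 60-seed mutation sweeps. These sizes are the
package's own choice: large enough that every combinatorial branch of
the chain search, collapse rule and amplicon pairing is exercised many
times per run, small enough that the whole suite is convenient to run
routinely.

# Decisions on open points

* **Amplicon length convention**: 5'-to-5' inclusive, anchored to the
  arithmetic of published tandem-ladder band series.
* **Array decomposition**: *n* chains → *n* LTR-promoter units and
  *n − 1* internal domains; the 3' LTR of the last unit is only
  attributable with the physical array extent, hence the `NA`
  truncation default.
* **Tandem query text**: the `(…)[a-b]n` form encodes the inter-unit
  gap window but not `minRepeats`, which stays a function argument.
* **CLI**: exported `cli*` functions plus a thin
  `inst/scripts/tandemtrim.R` launcher, so every code path is testable
  in-process.

# Session info

```{r session}
sessionInfo()
```
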