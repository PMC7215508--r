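# TandemTRIM

Detection and quantification of Cassandra TRIM retroelement tandem
arrays in plant genome sequences.

Cassandra elements are terminal-repeat retrotransposons in miniature
(TRIMs): short non-autonomous retroelements whose long terminal repeats
(LTRs) carry a 5S rRNA-derived promoter region. In many plant genomes
they occur not only as dispersed single elements but as long
head-to-tail tandem arrays. Two experimental signatures identify such
arrays: inverted ("divergent") primer pairs that face away from each
other within one unit amplify a ladder of products whose lengths differ
by exactly one tandem-unit length, and hybridization or qPCR assays
report far more element copies than a dispersed-element model would
predict. TandemTRIM implements the computational side of that tool
chain:

* **Degenerate motif scanning** over the full IUPAC nucleotide alphabet
  with a per-motif mismatch budget (`findMotif`, `revComp`,
  `motifDegeneracy`).
* **Linked queries** — chains of motifs separated by bounded spacer
  distances, written as
  `RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]TGGTATCAGAGC` — and a
  distance-constrained chained search on both strands (`parseQuery`,
  `searchLinked`).
* **Tandem-array search**: maximal runs of linked matches with bounded
  inter-unit gaps, `(query)[gapMin-gapMax]n` (`searchTandem`,
  `tandemQuery`).
* **Element annotation**: 5' LTR / internal-domain segmentation from the
  chain geometry, primer-binding-site (PBS) offset, 3' LTR location, and
  tandem-unit period estimation from array decomposition
  (`annotateElement`, `locateLtr3`, `decomposeArray`, `unitPeriod`).
* **In silico PCR**: primer binding with a mismatch-free 3' anchor,
  amplicon enumeration under the 5'-to-5' inclusive length convention,
  ladder fitting to `base + (period)_n`, and a plain-text virtual gel
  (`findBindingSites`, `enumerateAmplicons`, `predictLadder`,
  `renderGel`).
* **Copy-number arithmetic**: qPCR standard curves and
  copies-from-Ct, dot-blot copy estimation, genome-mass-fraction
  conversion, singleton subtraction, and group comparison
  (`fitStandardCurve`, `copiesFromCt`, `dotBlotCopies`,
  `copiesPerGenomeFromFraction`, `singletonCount`, `compareGroups`).
* **Hairpin scoring**: an alignment-based palindromic stem score for LTR
  self-complementarity, with optional G·U wobble pairing
  (`palindromicStemScore`, `pairingScore`, `elementHairpinReport`).
* **Synthetic data**: a seeded generator for Cassandra units, tandem
  arrays and whole test genomes with exact truth annotations
  (`unitSpec`, `makeUnit`, `makeArray`, `plantGenome`, `mutateSeq`,
  `writeGenome`).
* **CLI and I/O**: subcommands `scan`, `tandem`, `ladder`, `quantify`,
  `simulate`, `hairpin` via `inst/scripts/tandemtrim.R`, plus
  GFF3/BED/TSV/FASTA readers and writers.

Interfaces follow Bioconductor conventions: S4 classes with validity
methods, `GRanges`-based results with 1-based inclusive coordinates,
camelCase exports, `show` methods and accessors.

## Worked example

Build the canonical Cassandra query, simulate a genome with planted
elements, and search it:

```r
library(TandemTRIM)

q <- cassandraQuery()
q
#> LinkedQuery 'Cassandra': RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]TGGTATCAGAGC

g <- plantGenome(genomeLength = 30000L, nSingletons = 2L,
                 arrayUnits = c(3L), seed = 42L)
hits <- searchLinked(g$seq, q, seqId = g$seqId)
hits
#> GRanges object with 5 ranges and 3 metadata columns:
#>       seqnames      ranges strand | totalMismatches   queryName
#>          <Rle>   <IRanges>  <Rle> |       <integer> <character>
#>   [1]    synth 18783-18993      + |               0   Cassandra
#>   [2]    synth 21687-21897      + |               0   Cassandra
#>   [3]    synth 22168-22378      + |               0   Cassandra
#>   [4]    synth 22649-22859      + |               0   Cassandra
#>   [5]    synth 27215-27425      + |               0   Cassandra
#>   ...

arrays <- searchTandem(g$seq, cassandraTandemQuery(), seqId = g$seqId)
arrays
#> GRanges object with 1 range and 3 metadata columns:
#>       seqnames      ranges strand |    nUnits interUnitGaps ...
#>   [1]    synth 21687-22859      + |         3       270,270 ...
```

The three middle chains are the planted 3-unit array; `searchTandem`
groups them into one `tandem_array` record with its inter-unit gaps.

Predict the divergent-primer ladder on a 5-unit tandem template
(229 nt LTR + 252 nt internal domain, 481 nt unit):

```r
u   <- makeUnit(unitSpec())
arr <- makeArray(u$seq, 5L, ltrLen = 229L)
fwd <- substr(arr, 383L, 403L)                # internal-domain primer
rev <- revComp(substr(arr, 249L, 269L))       # inverted partner

lad <- predictLadder(arr, fwd, rev)
lad
#> Ladder: 4 rung(s), formula 368 + (481)_n
#>   lengths: 368, 849, 1330, 1811

renderGel(lad, labels = "Avena")              # plain-text virtual gel
```

Quantification:

```r
conc <- 10 / 2^(0:7)                          # perfect doubling series
fitStandardCurve(conc, 15 - log2(conc))
#> StandardCurve: slope -3.3219, intercept 15.000, r2 1.0000, efficiency 2.000 (n=8)

copiesPerGenomeFromFraction(0.0005, 4.8e9, 388)
#> [1] 6185
```

## Command-line use

```sh
Rscript inst/scripts/tandemtrim.R scan --fasta genome.fasta \
    --query query.txt --out hits
Rscript inst/scripts/tandemtrim.R ladder --fasta template.fasta \
    --primers primers.tsv --out ladder
Rscript inst/scripts/tandemtrim.R simulate --out simdir --seed 1
```

Run any subcommand without arguments for its usage line. `scan` and
`tandem` write GFF3 + TSV, `ladder` writes TSV plus a text gel,
`quantify` writes a JSON report, `simulate` writes FASTA plus truth
GFF3/BED, `hairpin` writes a TSV of stem scores.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "TandemTRIM",
                               load_package = "installed")'
```

The suite includes oracle cross-checks of the motif and chain engines
against both a naive reference scanner and Biostrings, plus an
acceptance context (`tests/testthat/test-acceptance.R`) covering ladder
prediction, unit-period recovery, quantification arithmetic, seeded
oracle equivalence, planted-truth recovery under mutation, strand
symmetry, and amplicon-count combinatorics.

## Vignette

A methods vignette describing the model, coordinate and length
conventions, the collapse rule of the chained search, the hairpin
score, and the design of the synthetic-data generator is in
`vignettes/tandem-trim-methods.Rmd`.

## License

MIT (see `LICENSE`).
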