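test_that("makeUnit embeds the motifs at their declared offsets", {
  u <- makeUnit(unitSpec())
  expect_identical(nchar(u$seq), 481L)
  truth <- u$truth
  types <- S4Vectors::mcols(truth)$type
  get <- function(ty) truth[types == ty]
  expect_identical(GenomicRanges::start(get("boxA")), 31L)
  expect_identical(GenomicRanges::start(get("boxC")), 61L)
  expect_identical(GenomicRanges::start(get("PBS")), 230L)
  expect_identical(GenomicRanges::end(get("long_terminal_repeat")), 229L)
  expect_identical(GenomicRanges::end(get("internal_domain")), 481L)
  ## the embedded instances match their degenerate consensus exactly
  m <- cassandraMotifs()
  for (ty in c("boxA", "boxC", "PBS")) {
    r <- get(ty)
    inst <- substr(u$seq, GenomicRanges::start(r), GenomicRanges::end(r))
    expect_length(findMotif(inst, m[[ty]], strand = "+"), 1L)
  }
})

test_that("makeUnit is deterministic per seed and varies across seeds", {
  expect_identical(makeUnit(unitSpec(seed = 3L))$seq,
                   makeUnit(unitSpec(seed = 3L))$seq)
  expect_false(makeUnit(unitSpec(seed = 3L))$seq ==
                 makeUnit(unitSpec(seed = 4L))$seq)
})

test_that("unitSpec validates motif placement against the query windows", {
  expect_error(unitSpec(boxGap = 14L), "\\[15,25\\]")
  expect_error(unitSpec(boxGap = 26L), "\\[15,25\\]")
  expect_error(unitSpec(ltrLen = 70L), "beyond the LTR")
  expect_error(unitSpec(ltrLen = 75L), "\\[5,200\\]")   # boxC-PBS gap only 2
  expect_error(unitSpec(pbsOffset = 60L), "\\[5,200\\]")
  expect_error(unitSpec(internalLen = 10L), "beyond the internal")
  ## alternative published geometries are feasible
  expect_s3_class(unitSpec(ltrLen = 200L, internalLen = 261L), "unitSpec")
  expect_s3_class(unitSpec(ltrLen = 121L, internalLen = 190L), "unitSpec")
})

test_that("makeArray concatenates head-to-tail with a closing LTR", {
  u <- makeUnit(unitSpec())
  expect_identical(nchar(makeArray(u$seq, 4L, 229L)), 4L * 481L + 229L)
  expect_identical(makeArray(u$seq, 1L, closingLtr = FALSE), u$seq)
  expect_error(makeArray(u$seq, 0L), ">= 1")
  expect_error(makeArray(u$seq, 2L), "ltrLen")
  ## an n-unit closed array carries n+1 LTR promoters and n PBS copies
  arr <- makeArray(u$seq, 12L, 229L)
  m <- cassandraMotifs()
  expect_length(findMotif(arr, m["boxA"], strand = "+"), 13L)
  expect_length(findMotif(arr, m["PBS"], strand = "+"), 12L)
})

test_that("plantGenome plants recoverable truth at mutation rate 0", {
  g <- plantGenome(genomeLength = 30000L, nSingletons = 2L,
                   arrayUnits = c(3L), seed = 7L)
  expect_identical(nchar(g$seq), 30000L)
  expect_length(g$truth, 3L)
  expect_identical(sort(S4Vectors::mcols(g$truth)$type),
                   c("singleton", "singleton", "tandem_array"))
  ## every planted chain is recovered at its exact coordinates
  found <- searchLinked(g$seq, cassandraQuery(), seqId = g$seqId)
  expect_identical(GenomicRanges::start(found),
                   GenomicRanges::start(g$chains))
  expect_identical(GenomicRanges::end(found), GenomicRanges::end(g$chains))
  ## the array is recovered as one run with the right unit count
  arrays <- searchTandem(g$seq, cassandraTandemQuery(), seqId = g$seqId)
  expect_length(arrays, 1L)
  expect_identical(S4Vectors::mcols(arrays)$nUnits, 3L)
  truthArr <- g$truth[S4Vectors::mcols(g$truth)$type == "tandem_array"]
  expect_gte(GenomicRanges::start(arrays), GenomicRanges::start(truthArr))
  expect_lte(GenomicRanges::end(arrays), GenomicRanges::end(truthArr))
})

test_that("plantGenome is byte-identical per seed and restores the RNG", {
  g1 <- plantGenome(genomeLength = 10000L, nSingletons = 1L,
                    arrayUnits = integer(0L), seed = 5L)
  g2 <- plantGenome(genomeLength = 10000L, nSingletons = 1L,
                    arrayUnits = integer(0L), seed = 5L)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$truth, g2$truth)
  ## generation does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1L)
  set.seed(99)
  invisible(plantGenome(genomeLength = 10000L, nSingletons = 1L,
                        arrayUnits = integer(0L), seed = 5L))
  x2 <- runif(1L)
  expect_identical(x1, x2)
})

test_that("plantGenome rejects infeasible placements", {
  expect_error(plantGenome(genomeLength = 2000L, nSingletons = 2L,
                           arrayUnits = c(3L)), "do not fit")
})

test_that("mutateSeq substitutes at the requested rate", {
  set.seed(51)
  s <- oracleRandSeq(100000L)
  expect_identical(mutateSeq(s, 0, seed = 1L), s)
  m1 <- mutateSeq(s, 1, seed = 1L)
  a <- strsplit(s, "")[[1L]]; b <- strsplit(m1, "")[[1L]]
  expect_false(any(a == b))                 # every site substituted
  expect_true(all(b %in% c("A", "C", "G", "T")))
  ## binomial check at rate 0.1: observed within 4 sd of expectation
  m <- mutateSeq(s, 0.1, seed = 2L)
  hits <- sum(strsplit(m, "")[[1L]] != a)
  expect_lt(abs(hits - 10000), 4 * sqrt(100000 * 0.1 * 0.9))
  ## deterministic per seed
  expect_identical(mutateSeq(s, 0.1, seed = 2L), m)
  expect_error(mutateSeq(s, 1.5), "rate")
})

test_that("mutation degrades recovery without destroying determinism", {
  g0 <- plantGenome(genomeLength = 20000L, nSingletons = 3L,
                    arrayUnits = integer(0L), seed = 11L)
  gm <- plantGenome(genomeLength = 20000L, nSingletons = 3L,
                    arrayUnits = integer(0L), mutationRate = 0.2,
                    seed = 11L)
  n0 <- length(searchLinked(g0$seq, cassandraQuery()))
  nm <- length(searchLinked(gm$seq, cassandraQuery()))
  expect_identical(n0, 3L)
  expect_lte(nm, n0)
})

test_that("writeGenome writes FASTA plus truth GFF3 and BED that round-trip", {
  dir <- tempfile("genome")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  g <- plantGenome(genomeLength = 15000L, nSingletons = 1L,
                   arrayUnits = c(2L), seed = 13L)
  paths <- writeGenome(g, dir, name = "toy")
  expect_true(all(file.exists(paths)))
  ## FASTA round trip
  back <- readFastaSeqs(paths["fasta"])
  expect_identical(unname(back), g$seq)
  expect_identical(names(back), g$seqId)
  ## GFF3 is 1-based: coordinates come back unchanged
  gff <- rtracklayer::import(paths["gff3"])
  expect_identical(sort(GenomicRanges::start(gff)),
                   sort(GenomicRanges::start(g$truth)))
  expect_identical(sort(GenomicRanges::end(gff)),
                   sort(GenomicRanges::end(g$truth)))
  ## BED is 0-based half-open on disk; rtracklayer restores 1-based
  bed <- rtracklayer::import(paths["bed"])
  expect_identical(GenomicRanges::start(bed),
                   GenomicRanges::start(g$chains))
  expect_identical(GenomicRanges::end(bed), GenomicRanges::end(g$chains))
  ## and the raw BED line is shifted by exactly one at the start
  raw <- read.delim(paths["bed"], header = FALSE)
  expect_identical(sort(as.integer(raw$V2) + 1L),
                   sort(GenomicRanges::start(g$chains)))
})
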