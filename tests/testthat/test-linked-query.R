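test_that("parseQuery parses the Cassandra query text", {
  q <- parseQuery(
    ">Cassandra RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]TGGTATCAGAGC")
  expect_s4_class(q, "LinkedQuery")
  expect_identical(q@name, "Cassandra")
  expect_identical(queryMotifs(q),
                   c("RGTTAAGYRHGY", "RRRATRGGTRACY", "TGGTATCAGAGC"))
  expect_identical(unname(queryGaps(q)[, "min"]), c(15L, 5L))
  expect_identical(unname(queryGaps(q)[, "max"]), c(25L, 200L))
})

test_that("parseQuery accepts round brackets, en dashes and whitespace", {
  q1 <- parseQuery("AAA(3-7)CCC")
  expect_identical(q1@gapMin, 3L)
  expect_identical(q1@gapMax, 7L)
  q2 <- parseQuery("AAA[3–7]CCC")     # en dash
  expect_identical(queryGaps(q2), queryGaps(q1))
  q3 <- parseQuery("  AAA [3-7] CCC ")
  expect_identical(queryMotifs(q3), c("AAA", "CCC"))
})

test_that("parseQuery recognises the tandem wrapper", {
  t1 <- parseQuery("(RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]TGGTATCAGAGC)n")
  expect_s4_class(t1, "TandemQuery")
  expect_identical(t1@unitGapMin, 200L)   # default unit gap
  expect_identical(t1@unitGapMax, 1000L)
  expect_identical(t1@minRepeats, 2L)
  t2 <- parseQuery("(AAA[3-7]CCC)[50-90]n", minRepeats = 3L)
  expect_identical(t2@unitGapMin, 50L)
  expect_identical(t2@unitGapMax, 90L)
  expect_identical(t2@minRepeats, 3L)
  ## a doubled (written-out) query is a plain 6-motif linked query
  q6 <- parseQuery(paste0("RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]",
                          "TGGTATCAGAGC[200-1000]RGTTAAGYRHGY[15-25]",
                          "RRRATRGGTRACY[5-200]TGGTATCAGAGC"))
  expect_s4_class(q6, "LinkedQuery")
  expect_length(queryMotifs(q6), 6L)
  expect_identical(q6@gapMin[3L], 200L)
})

test_that("parseQuery rejects malformed input with useful messages", {
  expect_error(parseQuery("AAA[7-3]CCC"), "inverted")
  expect_error(parseQuery("[3-7]CCC"), "empty motif")
  expect_error(parseQuery("AAA[3-7]"), "end with a motif")
  expect_error(parseQuery("AAA[3-7]CXZ"), "unknown character 'X'")
  expect_error(parseQuery(">name"), "header without")
  expect_error(parseQuery(""), "empty query body")
})

test_that("formatQuery round-trips through parseQuery", {
  qs <- list(
    cassandraQuery(),
    linkedQuery("TGGTATCAGAGC"),
    cassandraTandemQuery(),
    parseQuery("(AAA[3-7]CCC)[50-90]n"))
  for (q in qs) {
    back <- parseQuery(formatQuery(q))
    expect_identical(formatQuery(back), formatQuery(q))
    expect_identical(queryMotifs(back), queryMotifs(q))
  }
  expect_identical(
    formatQuery(cassandraQuery()),
    "RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]TGGTATCAGAGC")
})

test_that("query validity is enforced", {
  expect_error(linkedQuery(character(0L)), "at least one motif")
  expect_error(linkedQuery(c("AAA", "CCC"), gapMin = 5L, gapMax = 3L),
               "exceeds")
  expect_error(linkedQuery(c("AAA", "CCC")), "exactly one gap")
  expect_error(tandemQuery(cassandraQuery(), unitGap = c(10L, 5L)),
               "exceeds")
  expect_error(tandemQuery(cassandraQuery(), minRepeats = 0L), ">= 1")
})

test_that("searchLinked finds a constructed chain and respects gaps", {
  q <- cassandraQuery()
  body <- paste0("AGTTAAGTATGT", strrep("C", 18), "AAAATAGGTAACT",
                 strrep("G", 30), "TGGTATCAGAGC")
  hit <- searchLinked(body, q, strand = "+")
  expect_length(hit, 1L)
  expect_identical(GenomicRanges::start(hit), 1L)
  expect_identical(GenomicRanges::end(hit), nchar(body))
  sites <- S4Vectors::mcols(hit)$sites[[1L]]
  expect_identical(names(sites), queryMotifs(q))
  expect_identical(IRanges::start(sites), c(1L, 31L, 74L))
  ## a boxA-boxC gap outside [15, 25] breaks the chain
  bad <- paste0("AGTTAAGTATGT", strrep("C", 30), "AAAATAGGTAACT",
                strrep("G", 30), "TGGTATCAGAGC")
  expect_length(searchLinked(bad, q, strand = "+"), 0L)
})

test_that("reported gaps always satisfy the query constraints", {
  q <- cassandraQuery()
  set.seed(21)
  for (rep in 1:10) {
    s <- oracleTestSeq(nElements = 3L)
    hits <- searchLinked(s, q)
    for (i in seq_along(hits)) {
      sites <- S4Vectors::mcols(hits)$sites[[i]]
      if (as.character(GenomicRanges::strand(hits))[i] == "-")
        sites <- rev(sites)    # element order on the minus strand
      gaps <- IRanges::start(sites)[-1L] -
        IRanges::end(sites)[-length(sites)] - 1L
      if (as.character(GenomicRanges::strand(hits))[i] == "-")
        gaps <- rev(gaps)
      expect_true(all(gaps >= q@gapMin & gaps <= q@gapMax))
      ## chain span bounds of the Cassandra query
      expect_gte(GenomicRanges::width(hits)[i], 57L)
      expect_lte(GenomicRanges::width(hits)[i], 262L)
    }
  }
})

test_that("engine chains equal exhaustive oracle enumeration", {
  q <- cassandraQuery()
  set.seed(22)
  for (rep in 1:20) {
    s <- oracleTestSeq(nElements = sample(0:3, 1L))
    eng <- chainsAsDf(searchLinked(s, q))
    ora <- oracleChains(s, queryMotifs(q), q@gapMin, q@gapMax)
    expect_identical(eng, ora)
  }
})

test_that("engine chains with a mismatch budget equal the naive oracle", {
  q <- linkedQuery(c("RGTTAAGYRHGY", "TGGTATCAGAGC"),
                   gapMin = 5L, gapMax = 60L)
  set.seed(23)
  for (rep in 1:5) {
    s <- paste0(oracleRandSeq(300L), oracleConcretize("RGTTAAGYRHGY"),
                oracleRandSeq(20L), "TGGTATCAGAGC", oracleRandSeq(300L))
    ## point-mutate one position inside the planted PBS
    substr(s, 334L, 334L) <- "A"
    eng <- chainsAsDf(searchLinked(s, q, maxMismatch = 1L))
    ora <- oracleChains(s, q@motifs, q@gapMin, q@gapMax,
                        maxMismatch = 1L, siteFun = oracleScanPlus)
    expect_identical(eng, ora)
  }
})

test_that("chains sharing a site are collapsed to the best one", {
  ## one boxA-boxC pair followed by two reachable PBS copies: both chains
  ## share boxA and boxC, so collapse keeps one - equal mismatches and
  ## equal start, hence the smaller span (first PBS)
  s <- paste0(oracleConcretize("RGTTAAGYRHGY"), strrep("C", 18),
              oracleConcretize("RRRATRGGTRACY"), strrep("G", 30),
              "TGGTATCAGAGC", strrep("A", 10), "TGGTATCAGAGC")
  q <- cassandraQuery()
  hit <- searchLinked(s, q, strand = "+")
  expect_length(hit, 1L)
  expect_identical(GenomicRanges::end(hit), 85L)
  ## a boxA copy whose gap falls outside [15, 25] never starts a chain
  boxA <- oracleConcretize("RGTTAAGYRHGY")
  s2 <- paste0(boxA, boxA, strrep("C", 16),
               oracleConcretize("RRRATRGGTRACY"), strrep("G", 30),
               "TGGTATCAGAGC")
  hit2 <- searchLinked(s2, q, strand = "+")
  expect_length(hit2, 1L)
  expect_identical(GenomicRanges::start(hit2), 13L)
})

test_that("per-motif mismatch budgets are validated", {
  q <- cassandraQuery()
  expect_error(searchLinked("ACGT", q, maxMismatch = -1L), "non-negative")
  expect_error(searchLinked("ACGT", q, maxMismatch = 12L), "smaller than")
})

test_that("searchTandem chains planted arrays and respects minRepeats", {
  u <- makeUnit(unitSpec())
  arr <- makeArray(u$seq, 5L, ltrLen = 229L)
  tq <- cassandraTandemQuery()
  hits <- searchTandem(arr, tq, strand = "+")
  expect_length(hits, 1L)
  expect_identical(S4Vectors::mcols(hits)$nUnits, 5L)
  expect_identical(as.integer(S4Vectors::mcols(hits)$interUnitGaps[[1L]]),
                   rep(270L, 4L))
  ## units across a too-long gap never join
  twoFar <- paste0(u$seq, strrep("T", 1500L), u$seq)
  expect_length(searchTandem(twoFar, tq, strand = "+"), 0L)
  ## minRepeats = 1 partitions all unit chains into runs
  one <- searchTandem(twoFar, tq, strand = "+", minRepeats = 1L)
  expect_length(one, 2L)
  expect_identical(sum(S4Vectors::mcols(one)$nUnits),
                   length(searchLinked(twoFar, tq@unit, strand = "+")))
  expect_error(searchTandem(arr, tq, minRepeats = 0L), ">= 1")
})

test_that("tandem runs are maximal", {
  u <- makeUnit(unitSpec())
  seqs <- paste0(makeArray(u$seq, 3L, 229L), strrep("A", 2000L),
                 makeArray(u$seq, 2L, 229L))
  tq <- cassandraTandemQuery()
  arrays <- searchTandem(seqs, tq, strand = "+")
  expect_identical(S4Vectors::mcols(arrays)$nUnits, c(3L, 2L))
  chains <- searchLinked(seqs, tq@unit, strand = "+")
  for (i in seq_along(arrays)) {
    run <- S4Vectors::mcols(arrays)$unitChains[[i]]
    ## no further same-strand chain attaches within the unit-gap window
    before <- GenomicRanges::start(run)[1L] -
      GenomicRanges::end(chains) - 1L
    after <- GenomicRanges::start(chains) -
      GenomicRanges::end(run)[length(run)] - 1L
    expect_false(any(before >= tq@unitGapMin & before <= tq@unitGapMax))
    expect_false(any(after >= tq@unitGapMin & after <= tq@unitGapMax))
  }
})

test_that("searchLinked and searchTandem are strand-symmetric", {
  q <- cassandraQuery()
  tq <- cassandraTandemQuery()
  u <- makeUnit(unitSpec())
  set.seed(24)
  base <- paste0(oracleRandSeq(500L), makeArray(u$seq, 3L, 229L),
                 oracleRandSeq(500L))
  for (s in list(base, oracleTestSeq(2L))) {
    L <- nchar(s)
    fwd <- chainsAsDf(searchLinked(s, q))
    rcv <- chainsAsDf(searchLinked(oracleRevComp(s), q))
    mapped <- data.frame(
      start = L - rcv$end + 1L, end = L - rcv$start + 1L, mm = rcv$mm,
      strand = ifelse(rcv$strand == "+", "-", "+"),
      stringsAsFactors = FALSE)
    mapped <- mapped[order(mapped$start, mapped$strand), , drop = FALSE]
    rownames(mapped) <- NULL
    expect_identical(fwd, mapped)
    ## array spans map the same way
    a1 <- searchTandem(s, tq)
    a2 <- searchTandem(oracleRevComp(s), tq)
    expect_identical(sort(GenomicRanges::width(a1)),
                     sort(GenomicRanges::width(a2)))
    expect_identical(sort(S4Vectors::mcols(a1)$nUnits),
                     sort(S4Vectors::mcols(a2)$nUnits))
  }
})
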