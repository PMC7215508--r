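# Standard-format readers and writers: FASTA in (Biostrings), GFF3/BED
# out (rtracklayer), TSV tables in and out.  Internal coordinates are
# 1-based inclusive (GRanges); BED conversion happens only inside
# rtracklayer at the format boundary.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (multi-record, wrapped or single-line).
#' @return Named character vector of upper-cased sequences.
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("FASTA file contains no sequences: ", path)
  out <- toupper(as.character(dna))
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}

#' Read linked/tandem queries
#'
#' One query per record: FASTA-style (\code{">name"} header lines with
#' the query body on the following line(s)) or one bare query per line.
#'
#' @param path Query file.
#' @param ... Passed to [parseQuery()].
#' @return List of [LinkedQuery-class] / [TandemQuery-class] objects.
#' @export
readQueries <- function(path, ...) {
  if (!file.exists(path)) stop("cannot read query file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("query file is empty: ", path)
  queries <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(trimws(lines[i]), ">")) {
      hdr <- trimws(lines[i]); body <- character(0L); i <- i + 1L
      while (i <= length(lines) && !startsWith(trimws(lines[i]), ">")) {
        body <- c(body, trimws(lines[i])); i <- i + 1L
      }
      queries[[length(queries) + 1L]] <-
        parseQuery(paste(hdr, paste(body, collapse = "")), ...)
    } else {
      queries[[length(queries) + 1L]] <- parseQuery(trimws(lines[i]), ...)
      i <- i + 1L
    }
  }
  queries
}

#' Read primers from TSV or FASTA
#'
#' TSV needs columns \code{id} and \code{sequence}; FASTA records use the
#' header as id.
#'
#' @param path Primer file.
#' @return Named character vector of primer sequences (5' to 3').
#' @export
readPrimers <- function(path) {
  if (!file.exists(path)) stop("cannot read primer file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(trimws(first), ">")) return(readFastaSeqs(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(tab)))
    stop("primer table schema error: columns 'id' and 'sequence' required")
  stats::setNames(toupper(tab$sequence), tab$id)
}

#' Read a qPCR dilution series
#'
#' @param path TSV with columns \code{concentration} and \code{ct}.
#' @return Data frame with those columns.
#' @export
readDilutionSeries <- function(path) {
  if (!file.exists(path)) stop("cannot read dilution table: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("concentration", "ct") %in% names(tab)))
    stop("dilution table schema error: columns 'concentration' and 'ct' required")
  tab[, c("concentration", "ct")]
}

## Build a parent/child GRanges for GFF3 export of chain hits.
.chainsForGff <- function(chains, parentType = "linked_match",
                          childType = "match_part") {
  if (length(chains) == 0L) {
    g <- GenomicRanges::GRanges()
    S4Vectors::mcols(g)$type <- character(0L)
    return(g)
  }
  ids <- paste0(parentType, seq_along(chains))
  parents <- GenomicRanges::granges(chains)
  S4Vectors::mcols(parents) <- S4Vectors::DataFrame(
    type = parentType, ID = ids,
    Name = S4Vectors::mcols(chains)$queryName,
    mismatches = S4Vectors::mcols(chains)$totalMismatches)
  kids <- list()
  for (i in seq_along(chains)) {
    s <- S4Vectors::mcols(chains)$sites[[i]]
    k <- GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(chains))[i],
      ranges = s,
      strand = as.character(GenomicRanges::strand(chains))[i])
    S4Vectors::mcols(k) <- S4Vectors::DataFrame(
      type = childType, ID = paste0(ids[i], ".", seq_along(s)),
      Name = names(s), Parent = ids[i], mismatches = NA_integer_)
    kids[[i]] <- k
  }
  c(parents, do.call(c, kids))
}

#' Write chain hits as GFF3 and TSV
#'
#' GFF3 uses feature type \code{linked_match} with \code{match_part}
#' children for the motif sites (1-based inclusive, per the format); the
#' TSV summary has one row per chain.
#'
#' @param chains Result of [searchLinked()].
#' @param gff3,tsv Output paths (either may be \code{NULL} to skip).
#' @return Invisibly, the paths written.
#' @export
writeChains <- function(chains, gff3 = NULL, tsv = NULL) {
  if (!is.null(gff3))
    rtracklayer::export(.chainsForGff(chains), gff3, format = "gff3")
  if (!is.null(tsv)) {
    df <- data.frame(
      seq_id = as.character(GenomicRanges::seqnames(chains)),
      start = GenomicRanges::start(chains),
      end = GenomicRanges::end(chains),
      strand = as.character(GenomicRanges::strand(chains)),
      span = GenomicRanges::width(chains),
      mismatches = S4Vectors::mcols(chains)$totalMismatches,
      query = S4Vectors::mcols(chains)$queryName)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(gff3 = gff3, tsv = tsv))
}

#' Write array hits as GFF3 and TSV
#'
#' GFF3 uses feature type \code{tandem_array} with \code{linked_match}
#' children for the unit chains.
#'
#' @param arrays Result of [searchTandem()].
#' @param gff3,tsv Output paths (either may be \code{NULL} to skip).
#' @return Invisibly, the paths written.
#' @export
writeArrays <- function(arrays, gff3 = NULL, tsv = NULL) {
  if (!is.null(gff3)) {
    if (length(arrays) == 0L) {
      g <- GenomicRanges::GRanges()
      S4Vectors::mcols(g)$type <- character(0L)
      rtracklayer::export(g, gff3, format = "gff3")
    } else {
      ids <- paste0("tandem_array", seq_along(arrays))
      parents <- GenomicRanges::granges(arrays)
      S4Vectors::mcols(parents) <- S4Vectors::DataFrame(
        type = "tandem_array", ID = ids,
        nUnits = S4Vectors::mcols(arrays)$nUnits)
      kids <- list()
      for (i in seq_along(arrays)) {
        ch <- S4Vectors::mcols(arrays)$unitChains[[i]]
        k <- GenomicRanges::granges(ch)
        S4Vectors::mcols(k) <- S4Vectors::DataFrame(
          type = "linked_match", ID = paste0(ids[i], ".", seq_along(ch)),
          nUnits = NA_integer_, Parent = ids[i])
        kids[[i]] <- k
      }
      rtracklayer::export(c(parents, do.call(c, kids)), gff3,
                          format = "gff3")
    }
  }
  if (!is.null(tsv)) {
    df <- data.frame(
      seq_id = as.character(GenomicRanges::seqnames(arrays)),
      start = GenomicRanges::start(arrays),
      end = GenomicRanges::end(arrays),
      strand = as.character(GenomicRanges::strand(arrays)),
      n_units = S4Vectors::mcols(arrays)$nUnits,
      span = GenomicRanges::width(arrays),
      gaps = vapply(S4Vectors::mcols(arrays)$interUnitGaps,
                    function(g) paste(g, collapse = ","), character(1L)))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(gff3 = gff3, tsv = tsv))
}
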