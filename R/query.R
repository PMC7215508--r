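# Linked-query text syntax: motifs joined by gap ranges written [a-b] or
# (a-b) (hyphen or en dash), optionally FASTA-headed (">name ..."), with a
# whole-query "(...)n" wrapper marking a tandem (repeated) query.

.GAP_TOKEN <- paste0("\\[([0-9]+)[-\u2013\u2014]([0-9]+)\\]",
                     "|\\(([0-9]+)[-\u2013\u2014]([0-9]+)\\)")

.parseLinkedBody <- function(body, name) {
  if (!nzchar(body)) stop("query parse error: empty query body")
  hits <- gregexpr(.GAP_TOKEN, body, perl = TRUE)[[1L]]
  starts <- as.integer(hits)
  if (starts[1L] == -1L) starts <- integer(0L)
  lens <- attr(hits, "match.length")
  motifs <- character(0L); gmin <- integer(0L); gmax <- integer(0L)
  pos <- 1L
  nseg <- length(starts)
  for (i in seq_len(nseg)) {
    piece <- substr(body, pos, starts[i] - 1L)
    if (!nzchar(piece))
      stop("query parse error: empty motif before position ", starts[i])
    motifs <- c(motifs, piece)
    tok <- substr(body, starts[i], starts[i] + lens[i] - 1L)
    nums <- regmatches(tok, gregexpr("[0-9]+", tok))[[1L]]
    a <- as.integer(nums[1L]); b <- as.integer(nums[2L])
    if (a > b)
      stop("query parse error: inverted gap range [", a, "-", b,
           "] at position ", starts[i])
    gmin <- c(gmin, a); gmax <- c(gmax, b)
    pos <- starts[i] + lens[i]
  }
  tail <- substr(body, pos, nchar(body))
  if (!nzchar(tail))
    stop("query parse error: query must end with a motif, not a gap")
  motifs <- c(motifs, tail)
  for (m in motifs) {
    ch <- strsplit(toupper(m), "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% c(.IUPAC_LETTERS, "U")))
    if (length(bad))
      stop("query parse error: unknown character '", ch[bad[1L]],
           "' in motif '", m, "' at motif position ", bad[1L])
  }
  linkedQuery(motifs, gmin, gmax, name = name)
}

#' Parse a linked or tandem query string
#'
#' Parses the linked-query text syntax: IUPAC motifs joined by gap ranges
#' in square or round brackets (\code{"[15-25]"}, \code{"(5-200)"}; hyphen
#' and en dash both accepted), optionally preceded by a FASTA-style header
#' (\code{">name"}).  A query whose whole body is wrapped as
#' \code{"(\dots)n"}, optionally with an explicit unit gap
#' (\code{"(\dots)[200-1000]n"}), is a tandem query: the unit is repeated
#' with consecutive unit chains separated by the unit gap.
#'
#' @param text One query record (header plus body, or body only).
#' @param minRepeats Minimum repeat count attached to a tandem query
#'   (default 2; the marker \code{n} itself does not encode a count).
#' @param defaultUnitGap Unit gap assumed when the \code{"(\dots)n"} form
#'   carries no explicit gap. Default \code{c(200, 1000)}.
#' @return A [LinkedQuery-class] or [TandemQuery-class].
#' @examples
#' parseQuery(">Cassandra RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]TGGTATCAGAGC")
#' parseQuery("(RGTTAAGYRHGY[15-25]RRRATRGGTRACY[5-200]TGGTATCAGAGC)n")
#' @export
parseQuery <- function(text, minRepeats = 2L,
                       defaultUnitGap = c(200L, 1000L)) {
  if (length(text) != 1L || !is.character(text))
    stop("query parse error: text must be a single string")
  text <- gsub("[[:space:]]+$", "", gsub("^[[:space:]]+", "", text))
  name <- "query"
  if (startsWith(text, ">")) {
    text <- sub("^>", "", text)
    parts <- strsplit(text, "[[:space:]]+")[[1L]]
    if (length(parts) < 2L)
      stop("query parse error: header without query body")
    name <- parts[1L]
    text <- paste(parts[-1L], collapse = "")
  } else {
    text <- gsub("[[:space:]]+", "", text)
  }
  ## tandem wrapper: body starts with "(" whose matching ")" is followed by
  ## an optional gap token and a terminal "n"
  if (startsWith(text, "(")) {
    ch <- strsplit(text, "", fixed = TRUE)[[1L]]
    depth <- 0L; closeAt <- NA_integer_
    for (i in seq_along(ch)) {
      if (ch[i] == "(") depth <- depth + 1L
      if (ch[i] == ")") {
        depth <- depth - 1L
        if (depth == 0L) { closeAt <- i; break }
      }
    }
    if (!is.na(closeAt)) {
      rest <- substr(text, closeAt + 1L, nchar(text))
      if (grepl("^(\\[[0-9]+[-\u2013\u2014][0-9]+\\])?[nN]$", rest)) {
        unit <- .parseLinkedBody(substr(text, 2L, closeAt - 1L), name)
        gap <- defaultUnitGap
        if (nchar(rest) > 1L) {
          nums <- regmatches(rest, gregexpr("[0-9]+", rest))[[1L]]
          gap <- as.integer(nums)
          if (gap[1L] > gap[2L])
            stop("query parse error: inverted unit gap range")
        }
        return(tandemQuery(unit, unitGap = gap, minRepeats = minRepeats))
      }
    }
  }
  .parseLinkedBody(text, name)
}

#' Render a query in canonical form
#'
#' Canonical form uses square brackets and hyphens for gaps; a tandem
#' query is rendered as \code{"(unit)[min-max]n"}.
#' \code{parseQuery(formatQuery(q))} is structurally identical to \code{q}
#' (for a tandem query, up to the \code{minRepeats} argument, which the
#' text syntax does not encode).
#'
#' @param query A [LinkedQuery-class] or [TandemQuery-class].
#' @return A single string.
#' @export
formatQuery <- function(query) {
  if (is(query, "TandemQuery")) {
    return(sprintf("(%s)[%d-%d]n", formatQuery(query@unit),
                   query@unitGapMin, query@unitGapMax))
  }
  n <- length(query@motifs)
  if (n == 1L) return(query@motifs)
  out <- query@motifs[1L]
  for (i in seq_len(n - 1L)) {
    out <- paste0(out, sprintf("[%d-%d]", query@gapMin[i], query@gapMax[i]),
                  query@motifs[i + 1L])
  }
  out
}
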