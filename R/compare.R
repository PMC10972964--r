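# Cross-annotation comparison: match-maximizing global alignment (free gaps,
# no mismatch penalty -- the optimum equals the longest common subsequence),
# percent identity normalized by the shorter sequence, and best-match reports.

#' Maximum number of identically aligned positions
#'
#' Over all global alignments with free end and internal gaps and no mismatch
#' penalty, the maximum number of identically aligned positions equals the
#' longest-common-subsequence length; computed by exact dynamic programming.
#'
#' @param a,b DNA (or any) strings; must be non-empty.
#' @return integer count of identical aligned positions.
#' @examples
#' maxMatchAlignment("ACGT", "AGT")
#' @export
maxMatchAlignment <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b),
            length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty")
  .lcs_length_cpp(a, b)
}

#' Percent identity normalized by the shorter sequence
#'
#' `identical positions / length of shorter sequence * 100`. Note that with
#' this normalization a sequence aligning completely into a longer one scores
#' 100 even though the longer sequence has unmatched bases.
#'
#' @inheritParams maxMatchAlignment
#' @return numeric percent in `[0, 100]`.
#' @export
percentIdentity <- function(a, b) {
  maxMatchAlignment(a, b) / min(nchar(a), nchar(b)) * 100
}

#' Number of mismatches against the shorter sequence
#'
#' `length of shorter sequence - identical positions`.
#'
#' @inheritParams maxMatchAlignment
#' @return integer mismatch count.
#' @export
mismatches <- function(a, b) {
  min(nchar(a), nchar(b)) - maxMatchAlignment(a, b)
}

#' Best-match report of queries against a reference set
#'
#' References shorter than `minLength` are excluded (full-length V genes
#' only). For each query, every reference achieving the maximum percent
#' identity is reported (ties are kept). Percent identity is reported to one
#' decimal place.
#'
#' @param queries,references named [Biostrings::DNAStringSet] or named
#'   character vectors.
#' @param minLength minimum reference length in nt (default 223, i.e.
#'   > 222 bp).
#' @return data.frame with one row per (query, best-matching reference):
#'   `query`, `reference`, `identical_positions`, `percent_identity`,
#'   `mismatches`.
#' @export
bestMatchReport <- function(queries, references, minLength = 223L) {
  toChar <- function(x) {
    if (methods::is(x, "DNAStringSet")) x <- as.character(x)
    stopifnot(is.character(x), !is.null(names(x)))
    toupper(x)
  }
  queries <- toChar(queries)
  references <- toChar(references)
  references <- references[nchar(references) >= minLength]
  if (length(references) == 0L)
    stop("no references of length >= ", minLength, " remain")
  rows <- list()
  for (qn in names(queries)) {
    q <- queries[[qn]]
    ident <- vapply(references, function(r) maxMatchAlignment(q, r),
                    integer(1L))
    pid <- ident / pmin(nchar(q), nchar(references)) * 100
    best <- which(round(pid, 10) == round(max(pid), 10))
    rows[[qn]] <- data.frame(
      query = qn, reference = names(references)[best],
      identical_positions = unname(ident[best]),
      percent_identity = round(unname(pid[best]), 1L),
      mismatches = pmin(nchar(q), nchar(references)[best]) -
        unname(ident[best]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
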