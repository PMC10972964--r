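# Central S4 containers.

#' Annotated germline gene set
#'
#' Result of the end-to-end annotation pipeline ([runAnnotate()]): scanner
#' candidates, functionality calls, family assignments and gene names, plus
#' per-stage counts.
#'
#' @slot candidates a [GenomicRanges::GRanges] of V/J candidates with scanner
#'   metadata columns.
#' @slot calls [S4Vectors::DataFrame] with `call` (F/ORF/P) and `reasons`,
#'   parallel to `candidates`.
#' @slot geneNames character vector of assigned names, parallel to
#'   `candidates`.
#' @slot families data.frame of V family membership (`gene`, `family`,
#'   `identity`, `waiver`).
#' @slot consensus named character vector of family consensus sequences.
#' @slot chain chain the locus was annotated as.
#' @slot log list of per-stage counts.
#' @export
setClass("GermlineSet",
         representation(candidates = "GRanges", calls = "DataFrame",
                        geneNames = "character", families = "data.frame",
                        consensus = "character", chain = "character",
                        log = "list"))

setValidity("GermlineSet", function(object) {
  n <- length(object@candidates)
  msg <- character(0)
  if (nrow(object@calls) != n)
    msg <- c(msg, "calls must be parallel to candidates")
  if (length(object@geneNames) != n)
    msg <- c(msg, "geneNames must be parallel to candidates")
  if (nrow(object@calls) > 0L &&
      !all(object@calls$call %in% c("F", "ORF", "P")))
    msg <- c(msg, "calls must be F, ORF or P")
  if (length(msg) > 0L) msg else TRUE
})

#' Repertoire summary statistics
#'
#' Container for the post-clonotyping summary of one chain's repertoire:
#' UMI-weighted V/J usage and pairing, CDR3 spectratype, rank-abundance
#' shares, publicity across samples, CDR3 convergence, amino-acid composition
#' and chimera rate.
#'
#' @slot chain chain analysed.
#' @slot vUsage,jUsage named numeric frequency maps (sum to 1).
#' @slot vjPairing data.frame of V-J pairing frequencies.
#' @slot spectratype named numeric, CDR3 aa length -> weighted frequency.
#' @slot rankGroups named numeric of rank-group repertoire shares.
#' @slot publicity list from [publicity()] (or empty for one sample).
#' @slot convergence named integer, CDR3 aa -> distinct nt count.
#' @slot aaComposition named numeric of mean aa counts per CDR3.
#' @slot chimeraRate UMI-weighted fraction of chimeric receptors.
#' @slot nClonotypes clonotypes analysed (after filtering/downsampling).
#' @slot nExcluded clonotypes excluded as non-expressed.
#' @export
setClass("RepertoireSummary",
         representation(chain = "character", vUsage = "numeric",
                        jUsage = "numeric", vjPairing = "data.frame",
                        spectratype = "numeric", rankGroups = "numeric",
                        publicity = "list", convergence = "integer",
                        aaComposition = "numeric", chimeraRate = "numeric",
                        nClonotypes = "integer", nExcluded = "integer"))

setValidity("RepertoireSummary", function(object) {
  msg <- character(0)
  ok1 <- function(x) length(x) == 0L || abs(sum(x) - 1) < 1e-9
  if (!ok1(object@vUsage)) msg <- c(msg, "vUsage must sum to 1")
  if (!ok1(object@jUsage)) msg <- c(msg, "jUsage must sum to 1")
  if (!ok1(object@spectratype)) msg <- c(msg, "spectratype must sum to 1")
  if (!ok1(object@rankGroups)) msg <- c(msg, "rankGroups must sum to 1")
  if (length(object@convergence) > 0L && any(object@convergence < 1L))
    msg <- c(msg, "convergence counts must be >= 1")
  if (length(msg) > 0L) msg else TRUE
})
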