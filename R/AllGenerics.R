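#' CDR3 length spectratype
#'
#' Frequency-weighted distribution of CDR3 amino-acid lengths.
#'
#' @param x a clonotype data.frame or a [RepertoireSummary-class] object.
#' @param ... unused.
#' @return named numeric, length -> summed relative frequency (sums to 1).
#' @export
setGeneric("spectratype", function(x, ...) standardGeneric("spectratype"))

#' Accessors for annotation and repertoire containers
#'
#' @param x a [GermlineSet-class] or [RepertoireSummary-class] object.
#' @return `candidates`: the candidate [GenomicRanges::GRanges];
#'   `functionality`: the F/ORF/P call [S4Vectors::DataFrame]; `geneNames`:
#'   assigned gene names; `familyTable`: family membership data.frame;
#'   `consensusSeqs`: named family consensus sequences; `vUsage`/`jUsage`:
#'   frequency maps.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname accessors
#' @export
setGeneric("functionality", function(x) standardGeneric("functionality"))
#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("familyTable", function(x) standardGeneric("familyTable"))
#' @rdname accessors
#' @export
setGeneric("consensusSeqs", function(x) standardGeneric("consensusSeqs"))
#' @rdname accessors
#' @export
setGeneric("vUsage", function(x) standardGeneric("vUsage"))
#' @rdname accessors
#' @export
setGeneric("jUsage", function(x) standardGeneric("jUsage"))
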