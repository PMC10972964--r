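# show() methods and accessors for the S4 containers.

#' @rdname accessors
#' @export
setMethod("candidates", "GermlineSet", function(x) x@candidates)

#' @rdname accessors
#' @export
setMethod("functionality", "GermlineSet", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("geneNames", "GermlineSet", function(x) x@geneNames)

#' @rdname accessors
#' @export
setMethod("familyTable", "GermlineSet", function(x) x@families)

#' @rdname accessors
#' @export
setMethod("consensusSeqs", "GermlineSet", function(x) x@consensus)

setMethod("show", "GermlineSet", function(object) {
  lg <- object@log
  cat("GermlineSet (", object@chain, ")\n", sep = "")
  cat("  candidates: ", lg$n_v, " V, ", lg$n_j, " J\n", sep = "")
  cat("  functionality: ", lg$n_f, " F / ", lg$n_orf, " ORF / ", lg$n_p,
      " P\n", sep = "")
  cat("  V families: ", lg$n_families, "\n", sep = "")
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("vUsage", "RepertoireSummary", function(x) x@vUsage)

#' @rdname accessors
#' @export
setMethod("jUsage", "RepertoireSummary", function(x) x@jUsage)

#' @rdname spectratype
#' @export
setMethod("spectratype", "RepertoireSummary", function(x, ...) x@spectratype)

setMethod("show", "RepertoireSummary", function(object) {
  cat("RepertoireSummary (", object@chain, ")\n", sep = "")
  cat("  clonotypes: ", object@nClonotypes, " (", object@nExcluded,
      " excluded as non-expressed)\n", sep = "")
  cat("  V genes: ", length(object@vUsage), "; J genes: ",
      length(object@jUsage), "\n", sep = "")
  if (length(object@spectratype) > 0L) {
    mode <- names(object@spectratype)[which.max(object@spectratype)]
    cat("  CDR3 spectratype mode: ", mode, " aa\n", sep = "")
  }
  if (length(object@publicity) > 0L) {
    ms <- object@publicity$mean_share
    cat("  public share (all samples): ",
        sprintf("%.3f", ms[length(ms)]), "\n", sep = "")
  }
  cat("  max CDR3 convergence: ",
      if (length(object@convergence)) max(object@convergence) else 0L,
      "\n", sep = "")
  cat("  chimera rate: ", sprintf("%.3f", object@chimeraRate), "\n",
      sep = "")
  invisible(NULL)
})
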