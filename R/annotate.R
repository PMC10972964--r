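# End-to-end annotation: scan -> classify -> cluster -> name -> export, and
# the repertoire summary constructor.

extractSense <- function(seqs, gr) {
  vapply(seq_along(gr), function(i) {
    s <- seqs[[as.character(GenomicRanges::seqnames(gr)[i])]]
    senseExtract(s, GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
                 as.character(GenomicRanges::strand(gr)[i]))
  }, character(1L))
}

#' Annotate a genomic sequence end to end
#'
#' Runs the V and J scanners on both strands, classifies every candidate,
#' clusters V genes into families, assigns names by genomic order toward the
#' C gene, and returns the bundle as a [GermlineSet-class].
#'
#' @param seq genomic input: a FASTA path, [Biostrings::DNAStringSet] or
#'   named character vector.
#' @param chain chain used for gene naming.
#' @param towardC `"right"` or `"left"`: direction of the C gene in forward
#'   coordinates.
#' @param config a [vdjConfig()] list.
#' @param waivers gene ids (names assigned pre-clustering, `V<i>` in scan
#'   order) exempt from the family identity threshold.
#' @param signalPeptideHook,rssScoreHook optional external predictors (see
#'   [classifyV()]).
#' @return a [GermlineSet-class].
#' @export
runAnnotate <- function(seq, chain = "TRA", towardC = "right",
                        config = vdjConfig(), waivers = character(0),
                        signalPeptideHook = NULL, rssScoreHook = NULL) {
  if (is.character(seq) && length(seq) == 1L && file.exists(seq))
    seq <- readFasta(seq)
  seqs <- asNamedStrings(seq)
  vc <- scanVGenes(seqs, config)
  jc <- scanJGenes(seqs, config)
  all <- sortCandidates(c(vc, jc))
  if (length(all) == 0L) {
    return(methods::new("GermlineSet", candidates = emptyCandidates(),
                        calls = S4Vectors::DataFrame(
                          call = character(0),
                          reasons = IRanges::CharacterList()),
                        geneNames = character(0),
                        families = data.frame(), consensus = character(0),
                        chain = chain,
                        log = list(n_v = 0L, n_j = 0L, n_f = 0L, n_orf = 0L,
                                   n_p = 0L, n_families = 0L)))
  }
  S4Vectors::mcols(all)$gene_seq <- extractSense(seqs, all)
  calls <- classifyCandidates(all, seq = seqs,
                              signalPeptideHook = signalPeptideHook,
                              rssScoreHook = rssScoreHook, config = config)
  isV <- S4Vectors::mcols(all)$gene_type == "V"
  ids <- paste0(ifelse(isV, "V", "J"),
                ave(seq_along(all), isV, FUN = seq_along))
  geneNames <- character(length(all))
  families <- data.frame()
  consensus <- character(0)
  if (any(isV)) {
    vSeqs <- stats::setNames(S4Vectors::mcols(all)$gene_seq[isV], ids[isV])
    fam <- clusterFamilies(vSeqs, threshold = config$familyThreshold,
                           waivers = intersect(waivers, ids[isV]))
    families <- fam$members
    consensus <- fam$consensus
    geneNames[isV] <- nameGenes(
      stats::setNames(GenomicRanges::start(all)[isV], ids[isV]),
      chain = chain, geneType = "V",
      families = fam$members$family[match(ids[isV], fam$members$gene)],
      calls = calls$call[isV], towardC = towardC)
  }
  if (any(!isV)) {
    geneNames[!isV] <- nameGenes(
      stats::setNames(GenomicRanges::start(all)[!isV], ids[!isV]),
      chain = chain, geneType = "J", calls = calls$call[!isV],
      towardC = towardC)
  }
  S4Vectors::mcols(all)$gene_name <- geneNames
  S4Vectors::mcols(all)$call <- calls$call
  methods::new("GermlineSet", candidates = all, calls = calls,
               geneNames = geneNames, families = families,
               consensus = consensus, chain = chain,
               log = list(n_v = sum(isV), n_j = sum(!isV),
                          n_f = sum(calls$call == "F"),
                          n_orf = sum(calls$call == "ORF"),
                          n_p = sum(calls$call == "P"),
                          n_families = length(consensus)))
}

#' MiXCR-style anchor points for exported genes
#'
#' 0-based offsets within each exported gene sequence. For V genes the CDR3
#' anchor is computed from the 2nd-CYS motif (the conserved cysteine codon);
#' the CDR1/CDR2/FR anchors default to typical V-domain offsets and can be
#' replaced via `overrides` (the paper-grade boundaries come from external
#' domain alignment). J genes anchor FR4 at the conserved F of the FG motif.
#' Anchors must be strictly increasing within each gene.
#'
#' @param gs a [GermlineSet-class].
#' @param overrides optional data.frame keyed by `gene_name` whose remaining
#'   columns replace computed anchor values.
#' @return data.frame of anchor offsets, one row per gene.
#' @export
computeAnchors <- function(gs, overrides = NULL) {
  stopifnot(methods::is(gs, "GermlineSet"))
  mc <- S4Vectors::mcols(gs@candidates)
  rows <- list()
  for (i in seq_along(gs@candidates)) {
    width <- GenomicRanges::width(gs@candidates)[i]
    nm <- gs@geneNames[i]
    if (mc$gene_type[i] == "V") {
      cysAa <- mc$second_cys_aa[i]
      if (is.na(cysAa)) stop("no 2nd-CYS anchor for gene ", nm)
      frame <- mc$frame[i] %||% 0L
      cdr3Begin <- frame + (cysAa + 2L - 1L) * 3L
      row <- data.frame(gene_name = nm, gene_type = "V", FR1Begin = 0L,
                        CDR1Begin = 78L, FR2Begin = 114L, CDR2Begin = 165L,
                        FR3Begin = 195L, CDR3Begin = cdr3Begin,
                        VEnd = width, JBegin = NA_integer_,
                        FR4Begin = NA_integer_, FR4End = NA_integer_,
                        DBegin = NA_integer_, DEnd = NA_integer_,
                        stringsAsFactors = FALSE)
    } else if (mc$gene_type[i] == "J") {
      coreNt <- mc$core_pos[i] - GenomicRanges::start(gs@candidates)[i]
      if (as.character(GenomicRanges::strand(gs@candidates)[i]) == "-")
        coreNt <- GenomicRanges::end(gs@candidates)[i] - mc$core_pos[i] - 10L
      row <- data.frame(gene_name = nm, gene_type = "J", FR1Begin = NA,
                        CDR1Begin = NA, FR2Begin = NA, CDR2Begin = NA,
                        FR3Begin = NA, CDR3Begin = NA, VEnd = NA,
                        JBegin = 0L, FR4Begin = as.integer(coreNt),
                        FR4End = width, DBegin = NA_integer_,
                        DEnd = NA_integer_, stringsAsFactors = FALSE)
    } else {
      row <- data.frame(gene_name = nm, gene_type = "D", FR1Begin = NA,
                        CDR1Begin = NA, FR2Begin = NA, CDR2Begin = NA,
                        FR3Begin = NA, CDR3Begin = NA, VEnd = NA,
                        JBegin = NA, FR4Begin = NA, FR4End = NA,
                        DBegin = 0L, DEnd = width, stringsAsFactors = FALSE)
    }
    rows[[i]] <- row
  }
  anchors <- do.call(rbind, rows)
  if (!is.null(overrides)) {
    stopifnot("gene_name" %in% names(overrides))
    for (j in seq_len(nrow(overrides))) {
      k <- match(overrides$gene_name[j], anchors$gene_name)
      if (is.na(k)) next
      cols <- setdiff(names(overrides), "gene_name")
      anchors[k, cols] <- overrides[j, cols]
    }
  }
  for (i in seq_len(nrow(anchors))) {
    vals <- if (anchors$gene_type[i] == "V")
      unlist(anchors[i, c("FR1Begin", "CDR1Begin", "FR2Begin", "CDR2Begin",
                          "FR3Begin", "CDR3Begin", "VEnd")])
    else if (anchors$gene_type[i] == "J")
      unlist(anchors[i, c("JBegin", "FR4Begin", "FR4End")])
    else unlist(anchors[i, c("DBegin", "DEnd")])
    if (any(diff(vals) <= 0))
      stop("non-monotone anchor points for gene ", anchors$gene_name[i])
  }
  anchors
}

#' Export a germline library (FASTA + anchor TSV)
#'
#' Functional and ORF genes only; pseudogenes are excluded. Output ordering
#' is deterministic (by gene name), so reruns are byte-identical.
#'
#' @param gs a [GermlineSet-class].
#' @param dir output directory (created if needed).
#' @param overrides optional anchor overrides (see [computeAnchors()]).
#' @return invisibly, the paths written.
#' @export
exportGermlineLibrary <- function(gs, dir, overrides = NULL) {
  stopifnot(methods::is(gs, "GermlineSet"))
  keep <- gs@calls$call %in% c("F", "ORF")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sub <- gs@candidates[keep]
  nms <- gs@geneNames[keep]
  ord <- order(nms)
  fa <- file.path(dir, paste0(gs@chain, "_germline.fasta"))
  writeFasta(stats::setNames(
    Biostrings::DNAStringSet(S4Vectors::mcols(sub)$gene_seq[ord]),
    nms[ord]), fa)
  gsKeep <- methods::new(
    "GermlineSet", candidates = sub[ord],
    calls = gs@calls[keep, , drop = FALSE][ord, , drop = FALSE],
    geneNames = nms[ord], families = gs@families,
    consensus = gs@consensus, chain = gs@chain, log = gs@log)
  anchors <- computeAnchors(gsKeep, overrides)
  tsv <- file.path(dir, paste0(gs@chain, "_anchors.tsv"))
  utils::write.table(anchors, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, anchors = tsv))
}

#' Summarise a clonotype repertoire
#'
#' Filters out non-expressed clonotypes, optionally downsamples each sample
#' to the smallest sample's UMI total, and computes the full set of summary
#' statistics as a [RepertoireSummary-class].
#'
#' @param df clonotype data.frame (all samples of one chain).
#' @param chain expected chain (defaults to the table's unique chain).
#' @param seed seed for downsampling.
#' @param downsample downsample to the smallest sample before summarising.
#' @param key clonotype identity for publicity: `"aa"` or `"nt"`.
#' @param boundaries rank-group boundaries for [rankAbundance()].
#' @return a [RepertoireSummary-class].
#' @export
repertoireSummary <- function(df, chain = NULL, seed = 1L,
                              downsample = FALSE, key = "aa",
                              boundaries = c(10L, 100L, 1000L)) {
  df <- validateClonotypes(df)
  if (is.null(chain)) {
    chain <- unique(df$chain)
    if (length(chain) != 1L)
      stop("table contains multiple chains; pass `chain` explicitly")
  }
  chim <- flagChimeras(df, chain)
  chimeraRate <- sum(df$umi_count[chim]) / sum(df$umi_count)
  df <- filterProductive(df)
  nExcluded <- attr(df, "n_excluded")
  if (downsample && length(unique(df$sample_id)) > 1L)
    df <- downsampleClonotypes(df, seed)
  up <- usageAndPairing(df)
  pub <- if (length(unique(df$sample_id)) >= 2L) publicity(df, key)
         else list()
  methods::new("RepertoireSummary", chain = chain, vUsage = up$v_usage,
               jUsage = up$j_usage, vjPairing = up$vj,
               spectratype = spectratype(df),
               rankGroups = rankAbundance(df, boundaries), publicity = pub,
               convergence = convergence(df),
               aaComposition = aaComposition(df),
               chimeraRate = chimeraRate, nClonotypes = nrow(df),
               nExcluded = as.integer(nExcluded))
}
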