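# Seeded simulators for ground-truthed synthetic inputs: genomic loci with
# planted V/D/J cassettes (with optional defects) and clonotype tables with
# controlled statistical structure.

# run expr with a local RNG state
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Planting codon table: one codon per amino acid, chosen so that planted
# coding sequence can never contain an AAA or TTT trinucleotide across any
# codon junction (see background sampler below for why that matters).
PLANT_CODONS <- c(
  A = "GCT", C = "TGC", D = "GAT", E = "GAG", F = "TTC", G = "GGA",
  H = "CAT", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTC",
  W = "TGG", Y = "TAT")

# filler alphabet for planted proteins: no C/W/Y/F (reserved for anchors), no
# codon that can seed AAA/TTT at a junction
FILLER_AA <- c("A", "D", "G", "H", "L", "P", "R", "S", "V")

encodeAa <- function(aa) {
  paste(PLANT_CODONS[strsplit(aa, "", fixed = TRUE)[[1L]]], collapse = "")
}

# i.i.d. background with a structural guarantee: no AAA or TTT run. The RSS
# nonamer consensus (ACAAAAACC) and its complement cannot then occur within
# the mismatch budget anywhere outside the planted signals, so the background
# is certifiably free of accidental RSSs (hence of complete cassettes).
sampleBackground <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      b <- sample(names(p), 1L, prob = p)
      if (i >= 3L && b %in% c("A", "T") &&
          out[i - 1L] == b && out[i - 2L] == b) next
      out[i] <- b
      break
    }
  }
  paste(out, collapse = "")
}

SPACER23 <- "TTAGCTTCAGCTTAGCTTCAGCT"
SPACER12 <- "TTAGCTTCAGCT"

plantedVProtein <- function(familyMotif, exonAa, leader = FALSE) {
  # anchors at fixed exon offsets: 1st-CYS at aa 25, TRP at aa 40, 2nd-CYS
  # motif (YYC) at aa 100-102; family motif opens the mature protein
  filler <- function(k) paste(sample(FILLER_AA, k, replace = TRUE),
                              collapse = "")
  if (leader) {
    lead <- paste0("M", filler(16L))
    mature <- paste0(familyMotif, filler(25L - 18L - nchar(familyMotif)))
    head <- paste0(lead, mature)          # aa 1..24, M at 1
  } else {
    head <- paste0(familyMotif, filler(24L - nchar(familyMotif)))
  }
  paste0(head, "C", filler(14L), "W", filler(59L), "YYC",
         filler(exonAa - 102L))
}

buildVCassette <- function(familyMotif, leaderMode, defect = "none") {
  exonAa <- 120L                           # 360 nt, the scanner's window max
  prot <- plantedVProtein(familyMotif, exonAa,
                          leader = leaderMode == "single_exon")
  if (defect == "stop_codon")
    prot <- paste0(substr(prot, 1L, 59L), "*", substr(prot, 61L, exonAa))
  if (defect == "missing_anchor")          # 2nd-CYS motif YYC -> YAC
    prot <- paste0(substr(prot, 1L, 100L), "A", substr(prot, 102L, exonAa))
  if (defect == "missing_first_cys")
    prot <- paste0(substr(prot, 1L, 24L), "S", substr(prot, 26L, exonAa))
  if (defect == "missing_trp")
    prot <- paste0(substr(prot, 1L, 39L), "L", substr(prot, 41L, exonAa))
  exon <- encodeAa(gsub("*", "", prot, fixed = TRUE))
  if (defect == "stop_codon")              # re-insert the stop in frame
    exon <- paste0(substr(exon, 1L, 177L), "TAA",
                   substr(exon, 178L, nchar(exon)))
  lead <- if (leaderMode == "spliced") "AG" else ""
  spacer <- if (defect == "spacer_out_of_tolerance")
    paste0(SPACER23, "TTA") else SPACER23
  cac <- if (defect == "no_cac") "AAC" else "CAC"
  cassette <- paste0(lead, exon, cac, spacer, "ACAAAAACC")
  geneStart <- nchar(lead) + 1L
  geneEnd <- nchar(lead) + nchar(exon)
  list(seq = cassette, gene_start = geneStart, gene_end = geneEnd,
       protein = prot, leader_mode = leaderMode)
}

buildJCassette <- function(defect = "none") {
  cdr3part <- "GCTGATGGA"                  # in frame with the J core
  body <- "TTCGGCACAGGGACCAAGCTCACCGTCCTGG"
  if (defect == "missing_fg")
    body <- paste0("CTC", substr(body, 4L, nchar(body)))
  if (defect == "stop_codon")
    body <- paste0(substr(body, 1L, 15L), "TAA",
                   substr(body, 19L, nchar(body)))
  donor <- if (defect == "missing_donor") "CCAAGA" else "GTAAGA"
  spacer <- if (defect == "spacer_out_of_tolerance")
    paste0(SPACER12, "TTA") else SPACER12
  gtg <- if (defect == "no_cac") "GTT" else "GTG"
  rss <- paste0(revComp("ACAAAAACC"), revComp(spacer), gtg)
  cassette <- paste0(rss, cdr3part, body, donor, "CCTCCT")
  geneStart <- nchar(rss) + 1L
  geneEnd <- nchar(rss) + nchar(cdr3part) + nchar(body)
  list(seq = cassette, gene_start = geneStart, gene_end = geneEnd,
       core_offset = nchar(cdr3part) + 1L,
       protein = translateDNA(paste0(cdr3part, body)))
}

buildDCassette <- function(segment = "GGGACAGGGGGC") {
  rss5 <- paste0(revComp("ACAAAAACC"), revComp(SPACER12), "GTG")
  rss3 <- paste0("CAC", SPACER23, "ACAAAAACC")
  cassette <- paste0(rss5, segment, rss3)
  list(seq = cassette, gene_start = nchar(rss5) + 1L,
       gene_end = nchar(rss5) + nchar(segment))
}

#' Specification of a synthetic genomic locus
#'
#' @param nV,nJ number of planted V and J genes.
#' @param leaderModes per-V leader modes (`"spliced"`/`"single_exon"`),
#'   recycled; default alternates with a spliced majority.
#' @param strands per-gene strands for the `nV + nJ` genes, recycled; default
#'   mixes both strands.
#' @param defects named character vector mapping gene ids (`V1`, `J2`, ...)
#'   to a defect: `stop_codon`, `no_cac`, `missing_anchor`,
#'   `missing_first_cys`, `missing_trp`, `missing_fg`, `missing_donor`,
#'   `spacer_out_of_tolerance`.
#' @param familyMotifs family motifs planted at the mature V start, recycled
#'   over V genes.
#' @param backgroundGc background GC fraction.
#' @param gapLen background gap length range between cassettes.
#' @param seed integer seed; fully determines the locus.
#' @return a `locus_spec` list for [simulateLocus()].
#' @export
locusSpec <- function(nV = 5L, nJ = 4L,
                      leaderModes = c("spliced", "single_exon", "spliced"),
                      strands = c("-", "+", "-", "-", "+"),
                      defects = character(0),
                      familyMotifs = c("QVQQ", "VSQQ"),
                      backgroundGc = 0.5, gapLen = c(250L, 450L),
                      seed = 1L) {
  spec <- list(nV = as.integer(nV), nJ = as.integer(nJ),
               leaderModes = rep(leaderModes, length.out = nV),
               strands = rep(strands, length.out = nV + nJ),
               defects = defects,
               familyMotifs = rep(familyMotifs, length.out = nV),
               backgroundGc = backgroundGc,
               gapLen = as.integer(gapLen), seed = as.integer(seed))
  class(spec) <- c("locus_spec", "list")
  spec
}

# every 9-mer within the mismatch budget of the nonamer consensus, on the
# given strand of `s` (vectorised over positions)
nearNonamerPositions <- function(s, config) {
  n <- nchar(s)
  if (n < 9L) return(integer(0))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  pat <- strsplit(config$nonamer, "", fixed = TRUE)[[1L]]
  mm <- integer(n - 8L)
  for (k in 1:9) {
    allowed <- intersect(IUPAC_SETS[[pat[k]]], c("A", "C", "G", "T"))
    mm <- mm + as.integer(!chars[k:(n - 9L + k)] %in% allowed)
  }
  which(mm <= config$nonamerMaxMismatch)
}

# Regex-based brute-force check: does any complete V cassette end at the CAC
# anchor `c` of string `x`? (Independent of the scanner: plain regex walks.)
bruteVAt <- function(x, c, cfg) {
  e <- c - 1L
  if (e < cfg$vExonLen[1]) return(FALSE)
  for (st in seq.int(max(1L, e - cfg$vExonLen[2] + 1L),
                     e - cfg$vExonLen[1] + 1L)) {
    frames <- integer(0)
    if (substr(x, st, st + 2L) == "ATG") frames <- 0L
    if (st >= 3L && substr(x, st - 2L, st - 1L) == "AG")
      frames <- union(frames, 0:2)
    for (f in frames) {
      p <- translateDNA(substr(x, st, e), f)
      if (grepl("*", p, fixed = TRUE)) next
      w1 <- substr(p, cfg$firstCysWindowAa[1], cfg$firstCysWindowAa[2])
      rel <- regexpr("C", w1, fixed = TRUE)
      if (rel < 0L) next
      cpos <- cfg$firstCysWindowAa[1] + rel - 1L
      w2 <- substr(p, cpos + cfg$trpOffsetAa[1], cpos + cfg$trpOffsetAa[2])
      if (regexpr("W", w2, fixed = TRUE) < 0L) next
      w3 <- substr(p, cfg$secondCysWindowAa[1],
                   cfg$secondCysWindowAa[2] + 2L)
      if (regexpr("(Y[YFLHI]|TF)C", w3) < 0L) next
      return(TRUE)
    }
  }
  FALSE
}

# ... and any complete J cassette starting at gene start `g` of string `x`?
bruteJAt <- function(x, g, cfg) {
  n <- nchar(x)
  region <- substr(x, g, min(n, g + cfg$jLen[2]))
  cores <- gregexpr("TT[CT]GG.{4}GG", region)[[1L]]
  if (cores[1L] < 0L) return(FALSE)
  for (qr in as.integer(cores)) {
    q <- g + qr - 1L
    dRegion <- substr(x, q + 11L, min(n, g + cfg$jLen[2] + 5L))
    donors <- gregexpr("GT[AG][AGT]G[AGT]", dRegion)[[1L]]
    if (donors[1L] < 0L) next
    for (dr in as.integer(donors)) {
      d <- q + 10L + dr
      len <- d - g
      if (len < cfg$jLen[1] || len > cfg$jLen[2]) next
      body <- substr(x, q, d - 1L)
      p <- translateDNA(body)
      if (!grepl("*", p, fixed = TRUE) && startsWith(p, "FG") &&
          grepl("T..[CGT].[AG]T", body)) return(TRUE)
    }
  }
  FALSE
}

# Certify that no complete V or J cassette exists outside the planted genes:
# enumerate every potential RSS anchor on either strand (a CAC with the
# nonamer consensus at a tolerated spacer offset) and brute-force check it
# for a complete cassette, skipping the planted anchors.
certifyLocus <- function(s, truth, config = vdjConfig()) {
  n <- nchar(s)
  strands <- list(`+` = s, `-` = revComp(s))
  vAnchors <- list(`+` = integer(0), `-` = integer(0))
  jStarts <- list(`+` = integer(0), `-` = integer(0))
  for (i in seq_len(nrow(truth))) {
    st <- truth$strand[i]
    if (truth$gene_type[i] == "V") {
      vAnchors[[st]] <- c(vAnchors[[st]],
                          if (st == "+") truth$end[i] + 1L
                          else n - truth$start[i] + 2L)
    } else if (truth$gene_type[i] == "J") {
      jStarts[[st]] <- c(jStarts[[st]],
                         if (st == "+") truth$start[i]
                         else n - truth$end[i] + 1L)
    }
  }
  for (str in c("+", "-")) {
    x <- strands[[str]]
    opp <- if (str == "+") "-" else "+"
    for (p in nearNonamerPositions(x, config)) {
      for (c in (p - 27L):(p - 25L)) {
        if (c < 1L || substr(x, c, c + 2L) != "CAC") next
        if (c %in% vAnchors[[str]]) next
        if (bruteVAt(x, c, config)) return(FALSE)
      }
      for (c12 in (p - 16L):(p - 14L)) {
        if (c12 < 1L || substr(x, c12, c12 + 2L) != "CAC") next
        g <- n - c12 + 2L              # J gene start on the opposite strand
        if (g %in% jStarts[[opp]] || g + 3L > n) next
        if (bruteJAt(strands[[opp]], g, config)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Build a synthetic locus with planted V/J cassettes
#'
#' Each planted V is `[leader][V exon with anchors at recorded offsets]`
#' `[CAC + spacer + nonamer]`; each J is `[nonamer + spacer + CAC (reverse`
#' `complemented)][CDR3 part + J core + confirmatory motif][splice donor]`.
#' Genes are embedded at recorded coordinates/strands in i.i.d. background
#' that is structurally screened (and then certified) to contain no
#' accidental RSS, hence no accidental complete cassette.
#'
#' @param spec a [locusSpec()].
#' @return list with `seq` (named [Biostrings::DNAStringSet] of length 1) and
#'   `truth` (data.frame of planted genes: id, type, start/end/strand in
#'   forward coordinates, leader mode, defect, family motif, core offset).
#' @export
simulateLocus <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  for (attempt in 0:19) {
    out <- withSeed(spec$seed + attempt * 7919L, buildLocusOnce(spec))
    if (certifyLocus(out$sequence, out$truth)) {
      seqName <- paste0("synthetic_locus_seed", spec$seed)
      return(list(
        seq = stats::setNames(
          Biostrings::DNAStringSet(out$sequence), seqName),
        truth = cbind(seq_id = seqName, out$truth)))
    }
  }
  stop("could not build a certified cassette-free locus for this spec")
}

buildLocusOnce <- function(spec) {
  ids <- c(if (spec$nV > 0L) paste0("V", seq_len(spec$nV)),
           if (spec$nJ > 0L) paste0("J", seq_len(spec$nJ)))
  types <- c(rep("V", spec$nV), rep("J", spec$nJ))
  pieces <- character(0)
  pos <- 0L
  truth <- list()
  gap <- function() sampleBackground(
    sample(spec$gapLen[1]:spec$gapLen[2], 1L), spec$backgroundGc)
  for (i in seq_along(ids)) {
    g <- gap()
    pieces <- c(pieces, g)
    pos <- pos + nchar(g)
    defect <- if (ids[i] %in% names(spec$defects))
      spec$defects[[ids[i]]] else "none"
    strand <- spec$strands[i]
    if (types[i] == "V") {
      cas <- buildVCassette(spec$familyMotifs[i],
                            spec$leaderModes[sum(types[seq_len(i)] == "V")],
                            defect)
      fam <- spec$familyMotifs[i]
      core <- NA_integer_
    } else {
      cas <- buildJCassette(defect)
      fam <- NA_character_
      core <- cas$core_offset
    }
    len <- nchar(cas$seq)
    inserted <- if (strand == "-") revComp(cas$seq) else cas$seq
    mapPos <- function(p) if (strand == "-") pos + len - p + 1L else pos + p
    gs <- sort(c(mapPos(cas$gene_start), mapPos(cas$gene_end)))
    truth[[i]] <- data.frame(
      gene_id = ids[i], gene_type = types[i], start = gs[1L], end = gs[2L],
      strand = strand,
      leader_mode = if (types[i] == "V")
        spec$leaderModes[sum(types[seq_len(i)] == "V")] else "none",
      defect = defect, family_motif = fam, core_offset = core,
      protein = cas$protein, stringsAsFactors = FALSE)
    pieces <- c(pieces, inserted)
    pos <- pos + len
  }
  tail <- gap()
  pieces <- c(pieces, tail)
  list(sequence = paste(pieces, collapse = ""),
       truth = do.call(rbind, truth))
}

#' Specification of a synthetic repertoire
#'
#' Defaults emulate an unbiased splenic repertoire: mostly singleton-UMI
#' clonotypes, a Gaussian-like CDR3 length distribution centred at 14-15
#' amino acids, about 10 percent public share across three birds, a low
#' background convergence rate with one strongly convergent CDR3 (12 distinct
#' nucleotide variants), and no chimeras unless requested.
#'
#' @param nSamples number of samples (birds).
#' @param nClonotypes clonotypes per sample.
#' @param vNames,jNames germline gene names to draw calls from (defaults
#'   derived from `chain`).
#' @param cdr3LenMean,cdr3LenSd CDR3 amino-acid length distribution.
#' @param publicFraction fraction of clonotypes shared by all samples.
#' @param convergenceRate fraction of clonotypes that re-encode an existing
#'   CDR3 amino-acid sequence with a different nucleotide sequence.
#' @param convergenceMax size of the planted maximal convergence group.
#' @param chimeraRate fraction of clonotypes carrying a V call from another
#'   chain's locus.
#' @param chain chain of the simulated tables.
#' @param umiGeomP geometric parameter for UMI counts (`1 + rgeom(umiGeomP)`,
#'   so most clonotypes are singletons).
#' @param seed integer seed.
#' @return a `repertoire_spec` list for [simulateRepertoire()].
#' @export
repertoireSpec <- function(nSamples = 3L, nClonotypes = 8000L,
                           vNames = NULL, jNames = NULL,
                           cdr3LenMean = 14.5, cdr3LenSd = 1.5,
                           publicFraction = 0.10, convergenceRate = 0.05,
                           convergenceMax = 12L, chimeraRate = 0,
                           chain = "TRA", umiGeomP = 0.8, seed = 1L) {
  if (is.null(vNames)) vNames <- paste0(chain, "V1-", 1:12)
  if (is.null(jNames)) jNames <- paste0(chain, "J", 1:6)
  spec <- list(nSamples = as.integer(nSamples),
               nClonotypes = as.integer(nClonotypes), vNames = vNames,
               jNames = jNames, cdr3LenMean = cdr3LenMean,
               cdr3LenSd = cdr3LenSd, publicFraction = publicFraction,
               convergenceRate = convergenceRate,
               convergenceMax = as.integer(convergenceMax),
               chimeraRate = chimeraRate, chain = chain,
               umiGeomP = umiGeomP, seed = as.integer(seed))
  class(spec) <- c("repertoire_spec", "list")
  spec
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

GENCODE_BY_AA <- local({
  codons <- as.character(Biostrings::GENETIC_CODE)
  nts <- names(Biostrings::GENETIC_CODE)
  split(nts, codons)
})

randomEncode <- function(aa) {
  paste(vapply(strsplit(aa, "", fixed = TRUE)[[1L]], function(a) {
    opts <- GENCODE_BY_AA[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1L)), collapse = "")
}

#' Simulate per-sample clonotype tables with known truth
#'
#' @param spec a [repertoireSpec()].
#' @return list with `tables` (one data.frame with columns `sample_id`,
#'   `chain`, `v_call`, `j_call`, `cdr3`, `cdr3_aa`, `umi_count`, all samples
#'   stacked) and `truth` (planted usage weights and rates).
#' @export
simulateRepertoire <- function(spec) {
  stopifnot(inherits(spec, "repertoire_spec"))
  withSeed(spec$seed, {
    vW <- rgamma(length(spec$vNames), shape = 2)
    vW <- vW / sum(vW)
    jW <- rgamma(length(spec$jNames), shape = 2)
    jW <- jW / sum(jW)
    makeClones <- function(n) {
      L <- pmax(6L, round(stats::rnorm(n, spec$cdr3LenMean, spec$cdr3LenSd)))
      aa <- vapply(L, function(l)
        paste(sample(AA20, l, replace = TRUE), collapse = ""), character(1L))
      data.frame(
        v_call = sample(spec$vNames, n, replace = TRUE, prob = vW),
        j_call = sample(spec$jNames, n, replace = TRUE, prob = jW),
        cdr3_aa = aa,
        cdr3 = vapply(aa, randomEncode, character(1L), USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    }
    nPub <- round(spec$publicFraction * spec$nClonotypes)
    publicPool <- makeClones(nPub)
    tabs <- list()
    otherV <- if (spec$chain == "TRD") c("TRAV1-3", "TRAV2-5", "TRAV3-1")
              else c("TRDV1-2", "TRDV2-1")
    for (si in seq_len(spec$nSamples)) {
      priv <- makeClones(spec$nClonotypes - nPub)
      # background convergence: re-encode an existing CDR3 with new codons
      nConv <- round(spec$convergenceRate * nrow(priv))
      if (nConv > 0L) {
        src <- sample.int(nrow(priv) - nConv, nConv, replace = TRUE)
        tgt <- nrow(priv) - nConv + seq_len(nConv)
        priv$cdr3_aa[tgt] <- priv$cdr3_aa[src]
        priv$v_call[tgt] <- priv$v_call[src]
        priv$j_call[tgt] <- priv$j_call[src]
        priv$cdr3[tgt] <- vapply(priv$cdr3_aa[tgt], randomEncode,
                                 character(1L), USE.NAMES = FALSE)
      }
      df <- rbind(publicPool, priv)
      # planted maximal convergence group in the first sample
      if (si == 1L && spec$convergenceMax > 1L) {
        aaStar <- paste(sample(AA20, round(spec$cdr3LenMean),
                               replace = TRUE), collapse = "")
        nts <- character(0)
        while (length(nts) < spec$convergenceMax)
          nts <- unique(c(nts, randomEncode(aaStar)))
        idx <- nrow(df) - spec$convergenceMax + seq_len(spec$convergenceMax)
        df$cdr3_aa[idx] <- aaStar
        df$cdr3[idx] <- nts[seq_len(spec$convergenceMax)]
        df$v_call[idx] <- df$v_call[idx[1L]]
        df$j_call[idx] <- df$j_call[idx[1L]]
      }
      if (spec$chimeraRate > 0) {
        chim <- stats::runif(nrow(df)) < spec$chimeraRate
        df$v_call[chim] <- sample(otherV, sum(chim), replace = TRUE)
      }
      df$sample_id <- paste0("S", si)
      df$chain <- spec$chain
      df$umi_count <- 1L + stats::rgeom(nrow(df), spec$umiGeomP)
      tabs[[si]] <- df
    }
    tables <- do.call(rbind, tabs)
    tables <- tables[, c("sample_id", "chain", "v_call", "j_call", "cdr3",
                         "cdr3_aa", "umi_count")]
    rownames(tables) <- NULL
    list(tables = tables,
         truth = list(vUsage = stats::setNames(vW, spec$vNames),
                      jUsage = stats::setNames(jW, spec$jNames),
                      publicFraction = spec$publicFraction,
                      convergenceMax = spec$convergenceMax,
                      chimeraRate = spec$chimeraRate))
  })
}
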