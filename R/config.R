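#' Scanner configuration
#'
#' Bundles every tunable window used by the motif engine and the V/J/D
#' scanners. Values are the package defaults unless overridden; all lengths
#' are in nucleotides unless the name says `Aa`.
#'
#' @param vExonLen length window (nt) for a V candidate, start codon or
#'   splice acceptor through to the base before the RSS `CAC`.
#' @param jLen length window (nt) for a J candidate, RSS end to splice donor.
#' @param dLen length window (nt) for a D segment between its two RSSs.
#' @param leaderWindow how far upstream of the V exon (nt) to search for the
#'   `AG` splice acceptor or the `ATG` of a single-exon leader.
#' @param firstCysWindowAa 1st-CYS searched within these amino-acid positions
#'   of the V exon.
#' @param trpOffsetAa CONSERVED-TRP searched this many residues after the
#'   1st-CYS.
#' @param secondCysWindowAa 2nd-CYS motif searched within these amino-acid
#'   positions from the V exon start.
#' @param familyK family motifs must begin within the first `familyK` residues
#'   of the mature V protein.
#' @param leaderAa assumed leader length (aa) used to extend the family-motif
#'   search window for single-exon candidates, whose protein still carries the
#'   leader.
#' @param nonamer RSS nonamer consensus used to pin the spacer length.
#' @param nonamerMaxMismatch mismatches tolerated against the nonamer
#'   consensus.
#' @param relaxJSecondary if `TRUE` the confirmatory `TNNBNRT` motif between
#'   the J core and the splice donor is demoted from a requirement to a note.
#' @param familyThreshold percent nucleotide identity for family membership.
#' @param rssScoreThreshold threshold applied to `rssScoreHook` output during
#'   classification (ignored when no hook is supplied).
#' @return a named list of class `vdj_config`.
#' @export
vdjConfig <- function(vExonLen = c(240L, 360L),
                      jLen = c(40L, 75L),
                      dLen = c(8L, 25L),
                      leaderWindow = 400L,
                      firstCysWindowAa = c(15L, 40L),
                      trpOffsetAa = c(10L, 20L),
                      secondCysWindowAa = c(80L, 115L),
                      familyK = 15L,
                      leaderAa = 20L,
                      nonamer = "ACAAAAACC",
                      nonamerMaxMismatch = 2L,
                      relaxJSecondary = FALSE,
                      familyThreshold = 75,
                      rssScoreThreshold = NULL) {
  cfg <- list(vExonLen = as.integer(vExonLen), jLen = as.integer(jLen),
              dLen = as.integer(dLen), leaderWindow = as.integer(leaderWindow),
              firstCysWindowAa = as.integer(firstCysWindowAa),
              trpOffsetAa = as.integer(trpOffsetAa),
              secondCysWindowAa = as.integer(secondCysWindowAa),
              familyK = as.integer(familyK), leaderAa = as.integer(leaderAa),
              nonamer = toupper(nonamer),
              nonamerMaxMismatch = as.integer(nonamerMaxMismatch),
              relaxJSecondary = isTRUE(relaxJSecondary),
              familyThreshold = familyThreshold,
              rssScoreThreshold = rssScoreThreshold)
  stopifnot(length(cfg$vExonLen) == 2L, cfg$vExonLen[1] <= cfg$vExonLen[2],
            length(cfg$jLen) == 2L, cfg$jLen[1] <= cfg$jLen[2],
            length(cfg$dLen) == 2L, nchar(cfg$nonamer) == 9L)
  class(cfg) <- c("vdj_config", "list")
  cfg
}

#' Read a key=value configuration file
#'
#' Plain-text `key = value` lines (comments start with `#`). Vector values are
#' comma-separated. Unknown keys are an error; missing keys take the
#' [vdjConfig()] defaults.
#'
#' @param path configuration file.
#' @return a `vdj_config` list.
#' @export
readConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(vdjConfig())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: '", lines[which(bad)[1L]], "'")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  defaults <- formals(vdjConfig)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key: ", unknown[1L])
  args <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1L]]
    v <- trimws(v)
    parsed <- suppressWarnings(as.numeric(v))
    args[[keys[i]]] <- if (anyNA(parsed)) {
      if (all(v %in% c("TRUE", "FALSE"))) as.logical(v) else v
    } else parsed
  }
  do.call(vdjConfig, args)
}
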