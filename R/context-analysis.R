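# Positional composition and enrichment of the flanking regions around
# homorepeats: positions -flank..-1 before region start, +1..+flank after
# region end.

#' Positional composition of repeat flanks
#'
#' For every region, position -j is the residue j places before the region
#' start and +j the residue j places after the region end. Positions
#' falling outside the protein are skipped (they reduce that position's
#' denominator), as are ambiguity letters. Flank residues belonging to
#' other detected regions are deliberately not masked: alanine-rich
#' neighbourhoods are part of the signal.
#'
#' @param regions A \linkS4class{RepeatRegions}.
#' @param proteome The proteome the regions were detected on.
#' @param flank Number of positions on each side (default 10).
#' @param subset Label recorded on the profile; defaults to "pure",
#'   "impure" or "all" according to the purity mix of \code{regions}.
#' @return A \linkS4class{CompositionProfile}.
#' @export
positionalComposition <- function(regions, proteome, flank = 10L,
                                  subset = NULL) {
  stopifnot(methods::is(regions, "RepeatRegions"))
  seqs <- .as_seqvec(proteome)
  pid <- proteinId(regions)
  missing <- setdiff(pid, names(seqs))
  if (length(missing) > 0L)
    stop("region refers to unknown protein: ", missing[1])
  lens <- nchar(seqs)[pid]
  if (any(end(regions) > lens) || any(start(regions) < 1L))
    stop("region out of protein bounds")
  if (is.null(subset)) {
    pu <- unique(purity(regions))
    subset <- if (length(pu) == 1L) pu else "all"
  }
  labels <- .flank_labels(flank)
  counts <- matrix(0L, nrow = 20L, ncol = 2L * flank,
                   dimnames = list(.AA20, labels))
  if (length(regions) > 0L) {
    offs <- c(seq(-flank, -1L), seq_len(flank))
    n <- length(regions)
    # absolute position matrix: regions x positions
    anchor <- cbind(matrix(rep(start(regions), flank), ncol = flank),
                    matrix(rep(end(regions), flank), ncol = flank))
    pos <- sweep(anchor, 2L, -offs, FUN = "-")  # anchor + offset
    inb <- pos >= 1L & pos <= matrix(rep(lens, 2L * flank), ncol = 2L * flank)
    pidm <- matrix(rep(pid, 2L * flank), ncol = 2L * flank)
    labm <- matrix(rep(labels, each = n), ncol = 2L * flank)
    letter <- substring(seqs[pidm[inb]], pos[inb], pos[inb])
    keep <- letter %in% .AA20
    tab <- table(factor(letter[keep], levels = .AA20),
                 factor(labm[inb][keep], levels = labels))
    counts <- counts + unclass(tab)
  }
  denom <- as.integer(colSums(counts))
  freq <- sweep(counts, 2L, pmax(denom, 1L), FUN = "/")
  methods::new("CompositionProfile", freq = freq, denom = denom,
               subset = subset)
}

#' Positional enrichment versus background
#'
#' Divides every cell of a composition profile by the letter's proteome
#' background frequency, the enrichment convention used for flank
#' heat-maps.
#'
#' @param profile A \linkS4class{CompositionProfile}.
#' @param background A \linkS4class{BackgroundComposition}.
#' @return An \linkS4class{EnrichmentProfile}.
#' @export
positionalEnrichment <- function(profile, background) {
  stopifnot(methods::is(profile, "CompositionProfile"),
            methods::is(background, "BackgroundComposition"))
  freq <- positionFreq(profile)
  bg <- bgFreq(background)[rownames(freq)]
  zero <- bg == 0 & rowSums(freq) > 0
  if (any(zero))
    stop("background frequency is zero for letter with nonzero ",
         "flank frequency: ", rownames(freq)[zero][1])
  ratio <- sweep(freq, 1L, bg, FUN = "/")
  ratio[bg == 0, ] <- NA_real_
  methods::new("EnrichmentProfile", ratio = ratio,
               denom = positionCounts(profile), subset = profile@subset,
               background = background)
}

#' Marker enrichment summary
#'
#' Extracts the flank markers tracked across species: single-cell ratios
#' G+1, M-1, S-1, S+1, V-1 and V+1, plus "P" and "G", the mean ratio of
#' that letter over all flank positions (-10..-1, +1..+10).
#'
#' @param enrichment An \linkS4class{EnrichmentProfile} computed with
#'   \code{flank >= 10}.
#' @return A named numeric vector with elements "G+1", "M-1", "S-1",
#'   "S+1", "V-1", "V+1", "P", "G".
#' @export
markerSummary <- function(enrichment) {
  stopifnot(methods::is(enrichment, "EnrichmentProfile"))
  ratio <- positionRatio(enrichment)
  if (!all(c("-1", "+1") %in% colnames(ratio)))
    stop("enrichment profile lacks the -1/+1 positions")
  cell <- function(letter, pos) unname(ratio[letter, pos])
  c("G+1" = cell("G", "+1"), "M-1" = cell("M", "-1"),
    "S-1" = cell("S", "-1"), "S+1" = cell("S", "+1"),
    "V-1" = cell("V", "-1"), "V+1" = cell("V", "+1"),
    "P" = mean(ratio["P", ]), "G" = mean(ratio["G", ]))
}

#' Long-format view of a composition/enrichment pair
#'
#' Convenience export for TSV output: one row per (position, letter) with
#' frequency, denominator and enrichment ratio.
#'
#' @param profile A \linkS4class{CompositionProfile}.
#' @param enrichment Matching \linkS4class{EnrichmentProfile} (optional).
#' @return A data.frame with columns position, letter, frequency,
#'   denominator and (if enrichment given) ratio.
#' @export
contextLong <- function(profile, enrichment = NULL) {
  freq <- positionFreq(profile)
  out <- data.frame(
    position = rep(colnames(freq), each = nrow(freq)),
    letter = rep(rownames(freq), ncol(freq)),
    frequency = as.vector(freq),
    denominator = rep(positionCounts(profile), each = nrow(freq)),
    stringsAsFactors = FALSE)
  if (!is.null(enrichment))
    out$ratio <- as.vector(positionRatio(enrichment))
  out
}
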