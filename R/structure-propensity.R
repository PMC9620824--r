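# Tripeptide-based local secondary-structure propensity.
#
# A sequence is split into overlapping tripeptides (two shared residues);
# each tripeptide carries a probability vector over 27 local-structure
# classes, the ordered triples over the alpha (a), beta (b) and gamma (g)
# Ramachandran regions. The prediction at residue i integrates the
# tripeptides centred at i-2..i+2 through a renormalised weighted average
# and is reduced to three classes: all-helical "aaa", all-extended "bbb"
# and "others" (the remaining 25).

#' 27 structure-class labels
#'
#' The ordered triples over \{a, b, g\} in lexicographic order:
#' "aaa", "aab", ..., "ggg".
#'
#' @return Character vector of length 27.
#' @export
structureClasses <- function() .CLASS27

#' Load a tripeptide propensity table from TSV
#'
#' Expects a header with a \code{tripeptide} column followed by the 27
#' class-probability columns named as in [structureClasses()]. Each row
#' must sum to 1 within 1e-6 (rows are renormalised exactly after the
#' check). Tripeptides absent from the table fall back to the uniform
#' 1/27 vector at lookup time, with a warning counting the misses.
#'
#' @param path Path to the TSV resource.
#' @param provenance Free-text origin recorded on the object.
#' @return A \linkS4class{PropensityTable}.
#' @export
loadPropensityTable <- function(path, provenance = path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!identical(names(df), c("tripeptide", .CLASS27)))
    stop("propensity table must have columns: tripeptide, ",
         paste(.CLASS27, collapse = ", "))
  probs <- as.matrix(df[, .CLASS27])
  rownames(probs) <- toupper(df$tripeptide)
  if (anyDuplicated(rownames(probs)))
    stop("duplicate tripeptide in propensity table: ",
         rownames(probs)[duplicated(rownames(probs))][1])
  sums <- rowSums(probs)
  bad <- which(abs(sums - 1) > 1e-6)
  if (length(bad) > 0L)
    stop("propensity row does not sum to 1: ", rownames(probs)[bad[1]])
  probs <- probs / sums
  methods::new("PropensityTable", probs = probs, provenance = provenance)
}

#' Write a propensity table to TSV
#'
#' @param table A \linkS4class{PropensityTable}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writePropensityTable <- function(table, path) {
  stopifnot(methods::is(table, "PropensityTable"))
  df <- data.frame(tripeptide = rownames(table@probs), table@probs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-residue secondary-structure propensity
#'
#' Predicts reduced structure fractions for every interior residue of a
#' sequence. The tripeptide centred at residue i is seq[i-1..i+1]; the
#' 27-class vector at i is the weighted average of the vectors of the
#' tripeptides centred at i-2..i+2 (weights \code{contextWeights},
#' centre-heavy by default; out-of-range neighbours are dropped and the
#' remaining weights renormalised), then reduced to (aaa, bbb, others).
#' Terminal residues (i = 1 and i = L) carry no prediction.
#'
#' @param sequence A single protein sequence (character or AAString),
#'   length >= 3.
#' @param table A \linkS4class{PropensityTable}.
#' @param contextWeights Positive weights for the five context
#'   tripeptides, default \code{c(1, 2, 4, 2, 1)};
#'   \code{c(0, 0, 1, 0, 0)} reproduces the raw per-tripeptide lookup.
#' @return A numeric matrix with one row per interior residue (rownames =
#'   residue positions 2..L-1) and columns aaa, bbb, others; rows sum
#'   to 1.
#' @export
predictProfile <- function(sequence, table,
                           contextWeights = c(1, 2, 4, 2, 1)) {
  stopifnot(methods::is(table, "PropensityTable"))
  s <- toupper(as.character(sequence))
  if (length(s) != 1L) stop("'sequence' must be a single sequence")
  L <- nchar(s)
  if (L < 3L) stop("sequence must have length >= 3")
  if (length(contextWeights) != 5L || any(contextWeights < 0) ||
      sum(contextWeights) <= 0)
    stop("'contextWeights' must be 5 non-negative weights, not all zero")
  centres <- 2:(L - 1L)
  tris <- substring(s, centres - 1L, centres + 1L)
  V <- propensityLookup(table, tris)          # (L-2) x 27
  nMissing <- attr(V, "nMissing")
  if (nMissing > 0L)
    warning(nMissing, " tripeptide lookup(s) fell back to the uniform ",
            "vector")
  nC <- length(centres)
  num <- matrix(0, nC, 27L)
  den <- numeric(nC)
  for (d in -2:2) {
    wgt <- contextWeights[d + 3L]
    if (wgt == 0) next
    src <- seq_len(nC) + d                     # neighbour row index
    ok <- src >= 1L & src <= nC
    num[ok, ] <- num[ok, ] + wgt * V[src[ok], , drop = FALSE]
    den[ok] <- den[ok] + wgt
  }
  avg <- num / den
  out <- cbind(aaa = avg[, match("aaa", .CLASS27)],
               bbb = avg[, match("bbb", .CLASS27)],
               others = 1 - avg[, match("aaa", .CLASS27)] -
                 avg[, match("bbb", .CLASS27)])
  rownames(out) <- centres
  out
}

#' Aggregate propensity profiles over repeat regions
#'
#' For each region, predicts over the subsequence spanning the region plus
#' \code{flankComputed} residues on each side (clipped to protein bounds),
#' then maps every predicted residue to a relative position: negative
#' offsets before the region start, positive offsets after the region end,
#' and 0 for residues inside the region. Fractions are averaged per
#' relative position over all contributing residues of all regions; the
#' outermost computed positions (beyond \code{flankReported}) absorb the
#' window-terminus artefacts and are not reported.
#'
#' @param regions A \linkS4class{RepeatRegions}.
#' @param proteome The hosting proteome.
#' @param table A \linkS4class{PropensityTable}.
#' @param flankComputed Residues predicted on each side (default 12).
#' @param flankReported Flank positions reported (default 10); must be
#'   <= \code{flankComputed}.
#' @param contextWeights Passed to [predictProfile()].
#' @return A \linkS4class{PropensityProfile} over positions
#'   -flankReported..-1, 0, +1..+flankReported.
#' @export
aggregateRegionProfiles <- function(regions, proteome, table,
                                    flankComputed = 12L,
                                    flankReported = 10L,
                                    contextWeights = c(1, 2, 4, 2, 1)) {
  stopifnot(methods::is(regions, "RepeatRegions"),
            flankReported <= flankComputed)
  seqs <- .as_seqvec(proteome)
  pid <- proteinId(regions)
  missing <- setdiff(pid, names(seqs))
  if (length(missing) > 0L)
    stop("region refers to unknown protein: ", missing[1])
  labels <- c(sprintf("%d", seq(-flankReported, -1L)), "0",
              sprintf("+%d", seq_len(flankReported)))
  sums <- matrix(0, nrow = length(labels), ncol = 3L,
                 dimnames = list(labels, c("aaa", "bbb", "others")))
  n <- stats::setNames(integer(length(labels)), labels)
  for (k in seq_along(regions)) {
    sq <- seqs[[pid[k]]]
    L <- nchar(sq)
    a <- start(regions)[k]; b <- end(regions)[k]
    if (b > L) stop("region out of protein bounds")
    ws <- max(1L, a - flankComputed); we <- min(L, b + flankComputed)
    if (we - ws + 1L < 3L) next
    prof <- suppressWarnings(
      predictProfile(substring(sq, ws, we), table, contextWeights))
    pos <- as.integer(rownames(prof)) + ws - 1L   # protein coordinates
    rel <- ifelse(pos < a, pos - a, ifelse(pos > b, pos - b, 0L))
    kidx <- which(abs(rel) <= flankReported)
    lab <- ifelse(rel[kidx] > 0L, sprintf("+%d", rel[kidx]),
                  sprintf("%d", rel[kidx]))
    for (q in seq_along(kidx)) {
      sums[lab[q], ] <- sums[lab[q], ] + prof[kidx[q], ]
      n[lab[q]] <- n[lab[q]] + 1L
    }
  }
  frac <- sums / pmax(n, 1L)
  frac[n == 0L, ] <- 0
  methods::new("PropensityProfile", fractions = frac, n = as.integer(n))
}
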