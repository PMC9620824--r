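# Position of repeats within proteins, location stratification with
# Mann-Whitney U tests, and the transit-peptide / signal-peptide
# enrichment table keyed by the most N-terminal repeat's start class.

#' Relative position of regions within proteins
#'
#' Rescales each region's position to [0, 1]. In \code{"midpoint"} mode the
#' sample is ((start + end) / 2) / protein length, so a long N-terminal
#' repeat is not scored as artificially terminal; \code{"start"} mode uses
#' start / protein length and matches the start-based classes of
#' [tpEnrichmentTable()].
#'
#' @param regions A \linkS4class{RepeatRegions}.
#' @param proteome The proteome the regions refer to.
#' @param mode "midpoint" (default) or "start".
#' @return A data.frame with columns protein_id, start, end, relpos, mode.
#' @export
relativePositions <- function(regions, proteome,
                              mode = c("midpoint", "start")) {
  mode <- match.arg(mode)
  stopifnot(methods::is(regions, "RepeatRegions"))
  seqs <- .as_seqvec(proteome)
  pid <- proteinId(regions)
  missing <- setdiff(pid, names(seqs))
  if (length(missing) > 0L)
    stop("region refers to unknown protein: ", missing[1])
  lens <- nchar(seqs)[pid]
  if (length(regions) > 0L && any(end(regions) > lens))
    stop("region out of protein bounds")
  relpos <- if (mode == "midpoint") {
    ((start(regions) + end(regions)) / 2) / lens
  } else {
    start(regions) / lens
  }
  data.frame(protein_id = pid, start = start(regions), end = end(regions),
             relpos = as.numeric(relpos), mode = mode,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Exact two-sided Mann-Whitney p-value for untied samples via the exact
# null distribution of U (pwilcox).
.mw_exact_p <- function(u, na, nb) {
  centre <- na * nb / 2
  if (u <= centre) {
    p <- 2 * stats::pwilcox(u, na, nb)
  } else {
    p <- 2 * (1 - stats::pwilcox(u - 1, na, nb))
  }
  min(1, p)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with U computed from the rank sum of the first sample
#' (average ranks for ties). For small untied samples
#' (\code{min(n_a, n_b) <= 8}, no ties) the two-sided p-value comes from
#' the exact null distribution of U; otherwise from the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b Numeric samples, both non-empty.
#' @return A list with elements \code{statistic} (U of sample a),
#'   \code{p.value}, and \code{exact} (logical).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannWhitneyU <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (!has_ties && min(na, nb) <= 8L) {
    return(list(statistic = u, p.value = .mw_exact_p(u, na, nb),
                exact = TRUE))
  }
  mu <- na * nb / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- (na * nb / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = u, p.value = 1, exact = FALSE))
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity corr.
  list(statistic = u, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       exact = FALSE)
}

#' Stratify relative positions by subcellular location
#'
#' Groups position samples by the hosting protein's location label
#' (proteins without a label fall into "Other/Mixed"), summarises each
#' group and runs pairwise two-sided Mann-Whitney U tests between all
#' non-empty groups. Empty groups are omitted and listed.
#'
#' @param samples Output of [relativePositions()].
#' @param annotations An \linkS4class{AnnotationTable}.
#' @param adjust Apply Holm correction to the pairwise p-values
#'   (default FALSE, matching the uncorrected presentation of the source
#'   statistics).
#' @return A list with elements \code{summary} (data.frame: group, n,
#'   q1, median, q3), \code{p.values} (symmetric matrix, NA diagonal) and
#'   \code{omitted} (character vector of empty groups).
#' @export
stratifyByLocation <- function(samples, annotations, adjust = FALSE) {
  stopifnot(methods::is(annotations, "AnnotationTable"),
            all(c("protein_id", "relpos") %in% names(samples)))
  loc <- annotations@location[match(samples$protein_id, annotations@id)]
  loc[is.na(loc)] <- "Other/Mixed"
  groups <- .LOCATION_LEVELS[.LOCATION_LEVELS %in% loc]
  omitted <- setdiff(.LOCATION_LEVELS, groups)
  vals <- split(samples$relpos, factor(loc, levels = groups))
  summary <- data.frame(
    group = groups,
    n = vapply(vals, length, integer(1)),
    q1 = vapply(vals, function(v) unname(stats::quantile(v, 0.25)),
                numeric(1)),
    median = vapply(vals, stats::median, numeric(1)),
    q3 = vapply(vals, function(v) unname(stats::quantile(v, 0.75)),
                numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        p[i, j] <- p[j, i] <- mannWhitneyU(vals[[i]], vals[[j]])$p.value
      }
    }
    if (adjust) {
      up <- upper.tri(p)
      p[up] <- stats::p.adjust(p[up], method = "holm")
      p[lower.tri(p)] <- t(p)[lower.tri(p)]
    }
  }
  list(summary = summary, p.values = p, omitted = omitted)
}

# Start class of a region start coordinate. Position 1 (no initial
# methionine before the repeat) is kept apart from class "2".
.start_class <- function(start) {
  ifelse(start == 1L, "1",
         ifelse(start == 2L, "2",
                ifelse(start <= 20L, "3-20", ">20")))
}

#' Transit-peptide / signal-peptide enrichment table
#'
#' Classes every protein by the start coordinate of its most N-terminal
#' repeat region (pooled pure + impure): class "2" (right after the
#' initial methionine), "3-20", ">20", and the rare class "1" for repeats
#' with no residue before them. Counts proteins, mitochondrial
#' transit-peptide (mTP) and signal-peptide (SP) predictions, and the
#' corresponding percentages per class, plus the "no polyA" and "any"
#' (all repeat-containing proteins) rows. Proteins without a peptide
#' annotation count as "other".
#'
#' @param proteome The proteome (defines the full protein universe).
#' @param regions Pooled \linkS4class{RepeatRegions}.
#' @param annotations An \linkS4class{AnnotationTable} carrying peptide
#'   calls.
#' @return A data.frame with columns class, proteins, mTP, SP, pct_mTP,
#'   pct_SP; rows "no polyA", "any", "1", "2", "3-20", ">20".
#' @export
tpEnrichmentTable <- function(proteome, regions, annotations) {
  stopifnot(methods::is(regions, "RepeatRegions"),
            methods::is(annotations, "AnnotationTable"))
  seqs <- .as_seqvec(proteome)
  nt <- mostNTerminalRegion(regions)
  missing <- setdiff(proteinId(nt), names(seqs))
  if (length(missing) > 0L)
    stop("region refers to unknown protein: ", missing[1])
  cls <- stats::setNames(rep("no polyA", length(seqs)), names(seqs))
  cls[proteinId(nt)] <- .start_class(start(nt))
  pep <- annotations@peptide[match(names(seqs), annotations@id)]
  pep[is.na(pep)] <- "other"
  row_for <- function(sel, label) {
    n <- sum(sel)
    m <- sum(pep[sel] == "mTP"); s <- sum(pep[sel] == "SP")
    data.frame(class = label, proteins = n, mTP = m, SP = s,
               pct_mTP = if (n > 0) 100 * m / n else 0,
               pct_SP = if (n > 0) 100 * s / n else 0,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row_for(cls == "no polyA", "no polyA"),
    row_for(cls != "no polyA", "any"),
    row_for(cls == "1", "1"),
    row_for(cls == "2", "2"),
    row_for(cls == "3-20", "3-20"),
    row_for(cls == ">20", ">20"))
  rownames(out) <- NULL
  out
}
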