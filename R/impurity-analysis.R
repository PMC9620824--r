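# Composition and position statistics of impurities inside impure
# homorepeat regions, stratified by region length class (5, 6, >6) and
# pooled ("All").

# Long data.frame of impurity occurrences: protein_id, letter, offset,
# region length, length class.
.impurity_long <- function(regions) {
  stopifnot(methods::is(regions, "RepeatRegions"))
  sel <- which(purity(regions) == "impure")
  if (length(sel) == 0L)
    stop("no impure regions: impurity statistics undefined")
  imp <- impurities(regions)[sel]
  ns <- vapply(imp, NROW, integer(1))
  data.frame(
    protein_id = rep(proteinId(regions)[sel], ns),
    letter = unlist(lapply(imp, `[[`, "residue"), use.names = FALSE),
    offset = unlist(lapply(imp, `[[`, "offset"), use.names = FALSE),
    length = rep(width(regions)[sel], ns),
    class = .impure_length_class(rep(width(regions)[sel], ns)),
    stringsAsFactors = FALSE)
}

#' Impurity composition versus proteome background
#'
#' Frequency of each amino acid among impurity occurrences, per region
#' length class (5, 6, >6) and pooled over all impure regions ("All"),
#' with the ratio of each class frequency to the letter's proteome
#' background frequency (the pooled "All"/Bg ratio is the headline
#' statistic). Letters never observed as impurities are reported with
#' frequency 0 and ratio 0; letters absent from the background (ambiguity
#' letters) get ratio NA.
#'
#' @param regions A \linkS4class{RepeatRegions} containing impure regions.
#' @param background A \linkS4class{BackgroundComposition}.
#' @return A data.frame with columns letter, class, n, frequency, ratio.
#' @export
impurityFrequencies <- function(regions, background) {
  stopifnot(methods::is(background, "BackgroundComposition"))
  long <- .impurity_long(regions)
  letters_out <- sort(unique(c(setdiff(.AA20, targetResidue(regions)),
                               long$letter)))
  bg <- bgFreq(background)
  out <- lapply(c("5", "6", ">6", "All"), function(cl) {
    sub <- if (cl == "All") long else long[long$class == cl, , drop = FALSE]
    n_tot <- nrow(sub)
    cnt <- table(factor(sub$letter, levels = letters_out))
    freq <- if (n_tot > 0) as.numeric(cnt) / n_tot else rep(0, length(cnt))
    ratio <- ifelse(letters_out %in% names(bg) & bg[letters_out] > 0,
                    freq / bg[letters_out], NA_real_)
    ratio[freq == 0 & !is.na(ratio)] <- 0
    data.frame(letter = letters_out, class = cl, n = as.integer(cnt),
               frequency = freq, ratio = ratio,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Relative positions of impurities within their regions
#'
#' Each impurity at 1-based offset k in a region of length L contributes
#' relative position (k - 0.5) / L, so the exact centre of a region is 0.5
#' and "second half" means > 0.5. Values lie strictly inside (0, 1).
#'
#' @param regions A \linkS4class{RepeatRegions} containing impure regions.
#' @return A data.frame of samples with columns protein_id, letter, class,
#'   offset, length, relpos.
#' @seealso [impurityPositionSummary()]
#' @export
impurityRelativePositions <- function(regions) {
  long <- .impurity_long(regions)
  long$relpos <- (long$offset - 0.5) / long$length
  long
}

#' Median and quartiles of impurity relative positions
#'
#' Summarises the samples from [impurityRelativePositions()] per letter and
#' length class (plus the pooled "All" class).
#'
#' @param samples Output of [impurityRelativePositions()].
#' @return A data.frame with columns letter, class, n, q1, median, q3.
#' @export
impurityPositionSummary <- function(samples) {
  stopifnot(all(c("letter", "class", "relpos") %in% names(samples)))
  pooled <- samples
  pooled$class <- "All"
  all_s <- rbind(samples, pooled)
  grp <- split(all_s$relpos, list(all_s$letter, all_s$class), drop = TRUE)
  key <- strsplit(names(grp), ".", fixed = TRUE)
  out <- data.frame(
    letter = vapply(key, `[`, "", 1L),
    class = vapply(key, `[`, "", 2L),
    n = vapply(grp, length, integer(1)),
    q1 = vapply(grp, function(v) unname(stats::quantile(v, 0.25)),
                numeric(1)),
    median = vapply(grp, stats::median, numeric(1)),
    q3 = vapply(grp, function(v) unname(stats::quantile(v, 0.75)),
                numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$letter, out$class), , drop = FALSE]
}
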