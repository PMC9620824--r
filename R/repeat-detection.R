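# Detection of pure and impure homorepeat (polyA) regions.
#
# Pure regions are maximal uninterrupted runs of the target residue of
# length >= minLen. Impure regions come from a sliding-window search:
# every window holding at least windowMinCount target residues qualifies,
# qualifying windows are unioned and merged, merged spans are trimmed to
# begin and end on the target residue, and short or target-poor spans are
# dropped.

#' Detect pure homorepeat regions
#'
#' Finds the maximal runs of the target residue with run length at least
#' \code{minLen} (default: four consecutive alanines). Regions never
#' overlap and are returned in coordinate order.
#'
#' @param proteome A named \code{AAStringSet} or character vector of
#'   protein sequences.
#' @param target The repeated residue (default "A").
#' @param minLen Minimum run length, >= 1.
#' @return A \linkS4class{RepeatRegions} with purity "pure".
#' @examples
#' detectPure(c(p1 = "MAAAAG"))   # one region, 2-5
#' detectPure(c(p1 = "MAAAG"))    # run of 3: none
#' @export
detectPure <- function(proteome, target = "A", minLen = 4L) {
  .stopifnot_scalar_letter(target)
  if (minLen < 1L) stop("'minLen' must be >= 1")
  seqs <- .as_seqvec(proteome)
  chars <- .seq_chars(seqs)
  pid <- character(0); st <- integer(0); en <- integer(0)
  for (k in seq_along(chars)) {
    r <- rle(chars[[k]] == target)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minLen
    if (any(keep)) {
      pid <- c(pid, rep(names(seqs)[k], sum(keep)))
      st <- c(st, starts[keep]); en <- c(en, ends[keep])
    }
  }
  RepeatRegions(pid, st, en, rep("pure", length(st)), target = target)
}

# Qualifying-window union spans for the impure search on one sequence.
# Returns an IRanges of merged spans (before trimming).
.impure_spans <- function(is_target, window, window_min_count) {
  L <- length(is_target)
  cs <- c(0L, cumsum(is_target))
  starts <- integer(0); widths <- integer(0)
  if (L >= window) {
    i <- seq_len(L - window + 1L)
    cnt <- cs[i + window] - cs[i]
    hit <- i[cnt >= window_min_count]
    starts <- c(starts, hit)
    widths <- c(widths, rep(window, length(hit)))
  }
  # Terminal windows shorter than `window` qualify on the same count rule.
  for (len in seq_len(min(L, window - 1L))) {
    if (len < window_min_count) next
    if (cs[len + 1L] >= window_min_count) {            # prefix [1, len]
      starts <- c(starts, 1L); widths <- c(widths, len)
    }
    if (cs[L + 1L] - cs[L - len + 1L] >= window_min_count) {  # suffix
      starts <- c(starts, L - len + 1L); widths <- c(widths, len)
    }
  }
  if (length(starts) == 0L) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = starts, width = widths))
}

#' Detect impure homorepeat regions
#'
#' Sliding-window search for regions mostly composed of the target residue:
#' a window of \code{window} residues qualifies when it holds at least
#' \code{windowMinCount} target residues (windows shorter than
#' \code{window} at sequence ends qualify on the same count). Qualifying
#' windows are unioned, merged spans trimmed to begin and end on the
#' target, and spans shorter than 5 residues or with fewer than
#' \code{windowMinCount} target residues dropped. By default spans without
#' any impurity are dropped too, since those are the pure regions reported
#' by [detectPure()]; set \code{requireImpurity = FALSE} for the inclusive
#' variant.
#'
#' @inheritParams detectPure
#' @param window Window length (default 6).
#' @param windowMinCount Minimum target residues per qualifying window
#'   (default 4); must be <= \code{window}.
#' @param requireImpurity Drop all-target spans (default TRUE).
#' @return A \linkS4class{RepeatRegions} with purity "impure" (or mixed
#'   purity when \code{requireImpurity = FALSE}).
#' @examples
#' detectImpure(c(p1 = "MAAAGAAM"))  # region 2-7, impurity G at offset 4
#' @export
detectImpure <- function(proteome, target = "A", window = 6L,
                         windowMinCount = 4L, requireImpurity = TRUE) {
  .stopifnot_scalar_letter(target)
  if (windowMinCount > window)
    stop("'windowMinCount' must be <= 'window'")
  if (windowMinCount < 1L) stop("'windowMinCount' must be >= 1")
  seqs <- .as_seqvec(proteome)
  chars <- .seq_chars(seqs)
  pid <- character(0); st <- integer(0); en <- integer(0)
  imp <- list(); pur <- character(0)
  for (k in seq_along(chars)) {
    ch <- chars[[k]]
    t <- ch == target
    spans <- .impure_spans(t, as.integer(window),
                           as.integer(windowMinCount))
    for (j in seq_along(spans)) {
      a <- BiocGenerics::start(spans)[j]
      b <- BiocGenerics::end(spans)[j]
      idx <- which(t[a:b])                   # trim to target termini
      if (length(idx) == 0L) next
      a2 <- a + idx[1] - 1L
      b2 <- a + idx[length(idx)] - 1L
      len <- b2 - a2 + 1L
      ntg <- sum(t[a2:b2])
      if (len < 5L || ntg < windowMinCount) next
      offs <- which(!t[a2:b2])
      if (requireImpurity && length(offs) == 0L) next
      pid <- c(pid, names(seqs)[k]); st <- c(st, a2); en <- c(en, b2)
      pur <- c(pur, if (length(offs) == 0L) "pure" else "impure")
      imp <- c(imp, list(data.frame(offset = offs,
                                    residue = ch[a2 + offs - 1L],
                                    stringsAsFactors = FALSE)))
    }
  }
  RepeatRegions(pid, st, en, pur, target = target, impurities = imp)
}

#' Tabulate repeat regions by length class
#'
#' Counts regions and distinct hosting proteins per length class,
#' separately for pure (classes 4 and >4) and impure (classes 5, 6, >6)
#' regions, with per-purity totals.
#'
#' @param regions A \linkS4class{RepeatRegions} (pure, impure or combined).
#' @param proteome Optional proteome; only used to validate that the
#'   regions refer to known proteins.
#' @return A data.frame with columns purity, class, regions, proteins.
#' @export
summarizeCounts <- function(regions, proteome = NULL) {
  stopifnot(methods::is(regions, "RepeatRegions"))
  if (!is.null(proteome)) {
    seqs <- .as_seqvec(proteome)
    missing <- setdiff(proteinId(regions), names(seqs))
    if (length(missing) > 0L)
      stop("region refers to unknown protein: ", missing[1])
  }
  one <- function(sel, classes, cls_of) {
    pids <- proteinId(regions)[sel]
    cls <- cls_of(width(regions)[sel])
    rows <- lapply(classes, function(cl) {
      in_cl <- cls == cl
      data.frame(class = cl, regions = sum(in_cl),
                 proteins = length(unique(pids[in_cl])))
    })
    rows <- do.call(rbind, rows)
    rbind(rows, data.frame(class = "Total", regions = length(pids),
                           proteins = length(unique(pids))))
  }
  pure <- one(purity(regions) == "pure", c("4", ">4"),
              function(w) ifelse(w <= 4L, "4", ">4"))
  impure <- one(purity(regions) == "impure", c("5", "6", ">6"),
                .impure_length_class)
  out <- rbind(cbind(purity = "pure", pure),
               cbind(purity = "impure", impure))
  rownames(out) <- NULL
  out
}

#' Most N-terminal region per protein
#'
#' Pools the given regions (typically pure and impure together) and keeps,
#' per protein, the region with the smallest start coordinate. Ties at the
#' same start (a pure run at the head of an impure region) are broken by
#' preferring the longer region.
#'
#' @param regions A \linkS4class{RepeatRegions}.
#' @return A \linkS4class{RepeatRegions} with at most one region per
#'   protein; proteins without regions are absent.
#' @export
mostNTerminalRegion <- function(regions) {
  stopifnot(methods::is(regions, "RepeatRegions"))
  if (length(regions) == 0L) return(regions)
  ord <- order(proteinId(regions), start(regions), -width(regions))
  first <- !duplicated(proteinId(regions)[ord])
  regions[ord[first]]
}

#' Write repeat regions to TSV
#'
#' Columns: protein_id, start, end, length, purity, n_target, impurities
#' (semicolon-joined "offset:residue").
#'
#' @param regions A \linkS4class{RepeatRegions}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeRegions <- function(regions, path) {
  stopifnot(methods::is(regions, "RepeatRegions"))
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read repeat regions from TSV
#'
#' Inverse of [writeRegions()].
#'
#' @param path Path to a regions TSV.
#' @param target Target residue recorded on the returned object.
#' @return A \linkS4class{RepeatRegions}.
#' @export
readRegions <- function(path, target = "A") {
  df <- utils::read.delim(path, colClasses = c(
    protein_id = "character", start = "integer", end = "integer",
    length = "integer", purity = "character", n_target = "integer",
    impurities = "character"), na.strings = character(0))
  imp <- lapply(df$impurities, function(s) {
    if (is.na(s) || s == "")
      return(data.frame(offset = integer(), residue = character()))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(offset = as.integer(vapply(parts, `[`, "", 1L)),
               residue = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  })
  RepeatRegions(df$protein_id, df$start, df$end, df$purity,
                target = target, impurities = imp)
}
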