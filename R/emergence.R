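# Classification of repeat emergence from an ortholog alignment: a repeat
# aligned to gaps in a distant ortholog points to an insertion origin, a
# repeat aligned to non-target residues to successive substitutions.

.msa_seqs <- function(msa) {
  if (methods::is(msa, "XStringSet")) {
    out <- as.character(msa)
  } else if (is.character(msa)) {
    out <- msa
  } else {
    stop("'msa' must be an aligned AAStringSet or named character vector")
  }
  if (is.null(names(out)) || any(names(out) == ""))
    stop("alignment rows must be named")
  if (length(unique(nchar(out))) != 1L)
    stop("alignment rows must all have the same width")
  toupper(out)
}

#' Map region coordinates to alignment columns
#'
#' Translates a region given in ungapped reference coordinates into the
#' alignment columns whose reference residue belongs to the region, by
#' counting non-gap reference positions.
#'
#' @param msa Aligned sequences (equal-width \code{AAStringSet} or named
#'   character vector; gaps as "-").
#' @param refId Name of the reference row.
#' @param start,end 1-based inclusive region coordinates in the ungapped
#'   reference sequence.
#' @return Integer vector of alignment column indices.
#' @examples
#' mapRegionToColumns(c(h = "M-AAAA", o = "MG--AA"), "h", 2, 5)  # 3:6
#' @export
mapRegionToColumns <- function(msa, refId, start, end) {
  seqs <- .msa_seqs(msa)
  if (!refId %in% names(seqs)) stop("reference id not in alignment: ", refId)
  ref <- .seq_chars(seqs[refId])[[1]]
  nongap <- which(ref != "-")
  if (end > length(nongap))
    stop("region extends past ungapped reference length (",
         length(nongap), ")")
  if (start < 1L || start > end) stop("invalid region coordinates")
  nongap[start:end]
}

#' Classify repeat emergence (insertion vs substitution)
#'
#' Looks at the alignment columns of a repeat region in a reference
#' protein and measures, in one named ortholog, the fraction of those
#' columns that are gapped. A gap fraction at or above \code{tIns} calls
#' an insertion origin (the repeat is new sequence absent from the
#' ortholog); at or below \code{tSub} a substitution origin (the ortholog
#' aligns residues, mostly non-target, at those positions); anything in
#' between is a mixed call. Thresholds are reported with every call.
#'
#' @inheritParams mapRegionToColumns
#' @param orthologId Name of the ortholog row to compare against.
#' @param target Repeat residue (default "A").
#' @param tIns,tSub Gap-fraction thresholds, \code{0 <= tSub < tIns <= 1}
#'   (defaults 0.8 / 0.2).
#' @return A one-row data.frame: ref_id, ortholog_id, start, end,
#'   n_columns, gap_fraction, target_fraction, nontarget_fraction, call,
#'   t_ins, t_sub.
#' @export
classifyEmergence <- function(msa, refId, start, end, orthologId,
                              target = "A", tIns = 0.8, tSub = 0.2) {
  if (!(tSub >= 0 && tSub < tIns && tIns <= 1))
    stop("thresholds must satisfy 0 <= tSub < tIns <= 1")
  seqs <- .msa_seqs(msa)
  if (!orthologId %in% names(seqs))
    stop("ortholog id not in alignment: ", orthologId)
  cols <- mapRegionToColumns(seqs, refId, start, end)
  if (length(cols) == 0L) stop("empty region column set")
  orth <- .seq_chars(seqs[orthologId])[[1]][cols]
  gap_frac <- mean(orth == "-")
  target_frac <- mean(orth == target)
  call <- if (gap_frac >= tIns) "insertion"
          else if (gap_frac <= tSub) "substitution"
          else "mixed"
  data.frame(ref_id = refId, ortholog_id = orthologId,
             start = start, end = end, n_columns = length(cols),
             gap_fraction = gap_frac, target_fraction = target_frac,
             nontarget_fraction = 1 - gap_frac - target_frac,
             call = call, t_ins = tIns, t_sub = tSub,
             stringsAsFactors = FALSE)
}
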