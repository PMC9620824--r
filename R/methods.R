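# Accessors, subsetting, combination and show methods for the S4 containers.

#' Construct a RepeatRegions object
#'
#' Low-level constructor; the detectors [detectPure()] and [detectImpure()]
#' are the usual entry points.
#'
#' @param proteinId Character vector of hosting protein ids.
#' @param start,end Integer vectors of 1-based inclusive coordinates.
#' @param purity Character vector, "pure" or "impure" per region.
#' @param target Single repeated residue letter.
#' @param impurities List of data.frames (columns offset, residue), one per
#'   region; pure regions take an empty data.frame.
#' @return A \linkS4class{RepeatRegions} object.
#' @examples
#' RepeatRegions("p1", 2, 5, "pure")
#' @export
RepeatRegions <- function(proteinId = character(), start = integer(),
                          end = integer(), purity = character(),
                          target = "A", impurities = NULL) {
  n <- length(start)
  if (is.null(impurities)) {
    impurities <- rep(list(data.frame(offset = integer(),
                                      residue = character())), n)
  }
  methods::new("RepeatRegions",
    proteinId = as.character(proteinId),
    ranges = IRanges::IRanges(start = as.integer(start),
                              end = as.integer(end)),
    purity = as.character(purity), target = target,
    impurities = impurities)
}

#' @rdname RepeatRegions-class
#' @export
setMethod("proteinId", "RepeatRegions", function(object) object@proteinId)

#' @rdname RepeatRegions-class
#' @export
setMethod("purity", "RepeatRegions", function(object) object@purity)

#' @rdname RepeatRegions-class
#' @export
setMethod("impurities", "RepeatRegions", function(object) object@impurities)

#' @rdname RepeatRegions-class
#' @export
setMethod("targetResidue", "RepeatRegions", function(object) object@target)

#' @rdname RepeatRegions-class
#' @export
setMethod("nTarget", "RepeatRegions", function(object) {
  BiocGenerics::width(object@ranges) -
    vapply(object@impurities, NROW, integer(1))
})

#' @rdname RepeatRegions-class
#' @export
setMethod("start", "RepeatRegions",
          function(x) BiocGenerics::start(x@ranges))

#' @rdname RepeatRegions-class
#' @export
setMethod("end", "RepeatRegions", function(x) BiocGenerics::end(x@ranges))

#' @rdname RepeatRegions-class
#' @export
setMethod("width", "RepeatRegions", function(x) BiocGenerics::width(x@ranges))

#' @rdname RepeatRegions-class
#' @export
setMethod("length", "RepeatRegions", function(x) length(x@ranges))

#' @rdname RepeatRegions-class
#' @param i Index vector for subsetting.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "RepeatRegions", function(x, i, j, ..., drop = TRUE) {
  methods::initialize(x,
    proteinId = x@proteinId[i], ranges = x@ranges[i],
    purity = x@purity[i], impurities = x@impurities[i])
})

#' Combine RepeatRegions objects
#'
#' @param x,... RepeatRegions objects sharing the same target residue.
#' @return A single combined \linkS4class{RepeatRegions}.
#' @export
setMethod("c", "RepeatRegions", function(x, ...) {
  args <- c(list(x), list(...))
  tg <- unique(vapply(args, targetResidue, character(1)))
  if (length(tg) != 1L)
    stop("cannot combine RepeatRegions with different target residues")
  methods::new("RepeatRegions",
    proteinId = unlist(lapply(args, proteinId), use.names = FALSE),
    ranges = do.call(c, lapply(args, function(a) a@ranges)),
    purity = unlist(lapply(args, purity), use.names = FALSE),
    target = tg,
    impurities = do.call(c, lapply(args, impurities)))
})

#' Flatten RepeatRegions to a data.frame
#'
#' One row per region with columns protein_id, start, end, length, purity,
#' n_target and a semicolon-joined "offset:residue" impurity string — the
#' same layout [writeRegions()] persists.
#'
#' @param x A \linkS4class{RepeatRegions} object.
#' @param ... Ignored.
#' @return A data.frame.
#' @export
setMethod("as.data.frame", "RepeatRegions", function(x, ...) {
  imp <- vapply(x@impurities, function(d) {
    if (NROW(d) == 0L) return("")
    paste(sprintf("%d:%s", d$offset, d$residue), collapse = ";")
  }, character(1))
  data.frame(protein_id = x@proteinId,
             start = start(x), end = end(x), length = width(x),
             purity = x@purity, n_target = nTarget(x),
             impurities = imp, stringsAsFactors = FALSE)
})

setMethod("show", "RepeatRegions", function(object) {
  n <- length(object)
  cat("RepeatRegions with", n, "region(s), target residue",
      object@target, "\n")
  if (n > 0) {
    tab <- table(object@purity)
    cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", "), "\n")
    head_n <- min(n, 5L)
    print(utils::head(as.data.frame(object), head_n))
    if (n > head_n) cat("  ...", n - head_n, "more\n")
  }
})

#' @rdname BackgroundComposition-class
#' @export
setMethod("bgFreq", "BackgroundComposition", function(object) object@freq)

#' @rdname BackgroundComposition-class
#' @export
setMethod("totalResidues", "BackgroundComposition",
          function(object) object@totalResidues)

setMethod("show", "BackgroundComposition", function(object) {
  cat("BackgroundComposition over", format(object@totalResidues,
      big.mark = ","), "standard residues\n")
  print(round(object@freq, 4))
})

#' @rdname AnnotationTable-class
#' @param x An \linkS4class{AnnotationTable}.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "AnnotationTable", function(x, ...) {
  data.frame(id = x@id, location = x@location, peptide = x@peptide,
             stringsAsFactors = FALSE)
})

#' @rdname AnnotationTable-class
#' @export
setMethod("length", "AnnotationTable", function(x) length(x@id))

setMethod("show", "AnnotationTable", function(object) {
  cat("AnnotationTable with", length(object@id), "protein(s)\n")
  cat("  location labels:",
      sum(!is.na(object@location)), "| peptide calls:",
      sum(!is.na(object@peptide)), "\n")
})

#' @rdname CompositionProfile-class
#' @export
setMethod("positionFreq", "CompositionProfile", function(object) object@freq)

#' @rdname CompositionProfile-class
#' @export
setMethod("positionCounts", "CompositionProfile",
          function(object) object@denom)

setMethod("show", "CompositionProfile", function(object) {
  cat("CompositionProfile (", object@subset, " regions), ",
      ncol(object@freq), " flank positions\n", sep = "")
  cat("  per-position denominators:",
      paste(range(object@denom), collapse = "-"), "\n")
})

#' @rdname EnrichmentProfile-class
#' @export
setMethod("positionRatio", "EnrichmentProfile", function(object) object@ratio)

#' @rdname EnrichmentProfile-class
#' @export
setMethod("positionCounts", "EnrichmentProfile",
          function(object) object@denom)

setMethod("show", "EnrichmentProfile", function(object) {
  cat("EnrichmentProfile (", object@subset, " regions), ",
      ncol(object@ratio), " flank positions\n", sep = "")
})

#' @rdname PropensityTable-class
#' @export
setMethod("propensityLookup", "PropensityTable",
  function(object, tripeptides) {
    tri <- toupper(tripeptides)
    hit <- match(tri, rownames(object@probs))
    out <- matrix(1 / 27, nrow = length(tri), ncol = 27,
                  dimnames = list(tri, .CLASS27))
    found <- !is.na(hit)
    if (any(found)) out[found, ] <- object@probs[hit[found], , drop = FALSE]
    attr(out, "nMissing") <- sum(!found)
    out
  })

#' @rdname PropensityTable-class
#' @param x A \linkS4class{PropensityTable}.
#' @export
setMethod("length", "PropensityTable", function(x) nrow(x@probs))

setMethod("show", "PropensityTable", function(object) {
  cat("PropensityTable with", nrow(object@probs),
      "tripeptide(s) x 27 structure classes\n")
  cat("  provenance:", object@provenance, "\n")
})

#' @rdname PropensityProfile-class
#' @param x,... A \linkS4class{PropensityProfile}; further args ignored.
#' @export
setMethod("as.data.frame", "PropensityProfile", function(x, ...) {
  data.frame(position = rownames(x@fractions),
             aaa = x@fractions[, "aaa"], bbb = x@fractions[, "bbb"],
             others = x@fractions[, "others"], n = x@n,
             row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "PropensityProfile", function(object) {
  cat("PropensityProfile over", nrow(object@fractions),
      "relative positions\n")
  print(utils::head(as.data.frame(object), 3))
  cat("  ...\n")
})

#' @rdname SyntheticTruth-class
#' @export
setMethod("truthRegions", "SyntheticTruth", function(object) object@regions)

#' @rdname SyntheticTruth-class
#' @export
setMethod("truthProteins", "SyntheticTruth", function(object) object@proteins)

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@proteins), "protein(s),",
      length(object@regions), "planted region(s)\n")
})
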