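#' @import methods
#' @importFrom S4Vectors isSorted
NULL

#' Proteome-wide amino-acid background composition
#'
#' Frequencies of the 20 standard amino acids over a proteome. Ambiguity
#' letters (X, B, Z, U, O) are excluded from both numerator and denominator,
#' so the 20 frequencies sum to one.
#'
#' @slot freq Named numeric vector of length 20 (one entry per standard
#'   letter) summing to 1.
#' @slot totalResidues Integer count of standard residues used.
#'
#' @seealso [backgroundComposition()]
#' @exportClass BackgroundComposition
setClass("BackgroundComposition",
  representation(freq = "numeric", totalResidues = "numeric"))

setValidity("BackgroundComposition", function(object) {
  msg <- NULL
  if (length(object@freq) != 20L || !identical(sort(names(object@freq)),
                                               sort(.AA20)))
    msg <- c(msg, "freq must be named with exactly the 20 standard letters")
  else if (abs(sum(object@freq) - 1) > 1e-9)
    msg <- c(msg, "frequencies must sum to 1")
  if (any(object@freq < 0)) msg <- c(msg, "frequencies must be non-negative")
  if (object@totalResidues < 1) msg <- c(msg, "totalResidues must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Detected homorepeat regions
#'
#' A set of pure or impure homorepeat regions (polyA by default) detected
#' over a proteome. Coordinates are 1-based and inclusive on both ends.
#' Pure regions are uninterrupted runs of the target residue; impure regions
#' begin and end with the target residue and contain at least one
#' non-target impurity.
#'
#' @slot proteinId Character vector, hosting protein of each region.
#' @slot ranges [IRanges::IRanges] of start/end coordinates within proteins.
#' @slot purity Character vector, \code{"pure"} or \code{"impure"}.
#' @slot target Single letter, the repeated residue (default "A").
#' @slot impurities List parallel to the regions; each element a
#'   \code{data.frame} with columns \code{offset} (1-based position within
#'   the region) and \code{residue}, empty for pure regions.
#'
#' @seealso [detectPure()], [detectImpure()], [RepeatRegions()]
#' @exportClass RepeatRegions
setClass("RepeatRegions",
  representation(proteinId = "character", ranges = "IRanges",
                 purity = "character", target = "character",
                 impurities = "list"))

setValidity("RepeatRegions", function(object) {
  n <- length(object@ranges)
  msg <- NULL
  if (length(object@proteinId) != n || length(object@purity) != n ||
      length(object@impurities) != n)
    msg <- c(msg, "slot lengths differ")
  if (length(object@target) != 1L || !object@target %in% .AA20)
    msg <- c(msg, "target must be one standard letter")
  if (n > 0) {
    if (any(BiocGenerics::start(object@ranges) < 1L))
      msg <- c(msg, "start coordinates must be >= 1")
    if (!all(object@purity %in% c("pure", "impure")))
      msg <- c(msg, "purity must be 'pure' or 'impure'")
    w <- BiocGenerics::width(object@ranges)
    nimp <- vapply(object@impurities, NROW, integer(1))
    if (any(object@purity == "pure" & nimp > 0L))
      msg <- c(msg, "pure regions must carry no impurities")
    if (any(object@purity == "impure" & nimp == 0L))
      msg <- c(msg, "impure regions must carry at least one impurity")
    if (any(object@purity == "impure" & w < 5L))
      msg <- c(msg, "impure regions must have length >= 5")
    ok <- mapply(function(imp, wi) {
      NROW(imp) == 0L || (all(imp$offset >= 2L) && all(imp$offset <= wi - 1L))
    }, object@impurities, w)
    if (!all(ok))
      msg <- c(msg, "regions must begin and end with the target residue")
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-protein annotation table
#'
#' Subcellular-location labels and N-terminal peptide predictions
#' (mitochondrial transit peptide, signal peptide) keyed by protein id.
#' Both annotations use closed vocabularies; either may be absent (NA).
#'
#' @slot id Character vector of unique protein ids.
#' @slot location Character vector over \{Nucleus, Cytoplasm, Mitochondrion,
#'   Secreted, Other/Mixed\} or NA.
#' @slot peptide Character vector over \{mTP, SP, other\} or NA.
#'
#' @seealso [readAnnotations()]
#' @exportClass AnnotationTable
setClass("AnnotationTable",
  representation(id = "character", location = "character",
                 peptide = "character"))

.LOCATION_LEVELS <- c("Nucleus", "Cytoplasm", "Mitochondrion", "Secreted",
                      "Other/Mixed")
.PEPTIDE_LEVELS <- c("mTP", "SP", "other")

setValidity("AnnotationTable", function(object) {
  msg <- NULL
  n <- length(object@id)
  if (length(object@location) != n || length(object@peptide) != n)
    msg <- c(msg, "slot lengths differ")
  if (anyDuplicated(object@id))
    msg <- c(msg, "duplicate protein id")
  if (!all(object@location %in% c(.LOCATION_LEVELS, NA)))
    msg <- c(msg, "unknown location label")
  if (!all(object@peptide %in% c(.PEPTIDE_LEVELS, NA)))
    msg <- c(msg, "unknown peptide label")
  if (is.null(msg)) TRUE else msg
})

#' Positional composition of repeat flanking regions
#'
#' Per-position amino-acid frequencies over the flanking positions
#' -flank..-1 (before region start) and +1..+flank (after region end).
#' Positions falling outside the hosting protein, and ambiguity letters,
#' are excluded from the per-position denominator.
#'
#' @slot freq Numeric matrix, 20 letters (rows) by flank positions (columns,
#'   labelled "-10".."-1", "+1".."+10"); each column with denominator > 0
#'   sums to 1.
#' @slot denom Integer vector of per-position residue counts.
#' @slot subset Label of the region subset profiled ("pure", "impure",
#'   "all").
#'
#' @seealso [positionalComposition()]
#' @exportClass CompositionProfile
setClass("CompositionProfile",
  representation(freq = "matrix", denom = "integer", subset = "character"))

setValidity("CompositionProfile", function(object) {
  msg <- NULL
  if (!identical(rownames(object@freq), .AA20))
    msg <- c(msg, "freq rows must be the 20 standard letters")
  if (length(object@denom) != ncol(object@freq))
    msg <- c(msg, "denom length must match number of positions")
  cs <- colSums(object@freq)
  bad <- object@denom > 0L & abs(cs - 1) > 1e-9
  if (any(bad))
    msg <- c(msg, "per-position frequencies must sum to 1 where denom > 0")
  if (is.null(msg)) TRUE else msg
})

#' Positional enrichment of repeat flanking regions
#'
#' Same shape as [CompositionProfile-class] with each cell divided by the
#' letter's proteome background frequency.
#'
#' @slot ratio Numeric matrix of frequency / background ratios.
#' @slot denom Integer vector of per-position residue counts.
#' @slot subset Region subset label.
#' @slot background The [BackgroundComposition-class] used as denominator.
#'
#' @seealso [positionalEnrichment()], [markerSummary()]
#' @exportClass EnrichmentProfile
setClass("EnrichmentProfile",
  representation(ratio = "matrix", denom = "integer", subset = "character",
                 background = "BackgroundComposition"))

#' Tripeptide structural propensity table
#'
#' Maps tripeptides (three standard letters) to probability vectors over the
#' 27 local-structure classes, the ordered triples over the alpha (a),
#' beta (b) and gamma (g) regions of the Ramachandran space: "aaa", "aab",
#' ..., "ggg". Lookups are case-insensitive; tripeptides absent from the
#' table fall back to the uniform 1/27 vector.
#'
#' @slot probs Numeric matrix, tripeptides (rows) by 27 class columns; rows
#'   sum to 1.
#' @slot provenance Free-text origin of the table.
#'
#' @seealso [loadPropensityTable()], [generatePropensityFixture()]
#' @exportClass PropensityTable
setClass("PropensityTable",
  representation(probs = "matrix", provenance = "character"))

.abg <- c("a", "b", "g")
.CLASS27 <- as.vector(t(outer(.abg, as.vector(t(outer(.abg, .abg, paste0))),
                              paste0)))

setValidity("PropensityTable", function(object) {
  msg <- NULL
  if (!identical(colnames(object@probs), .CLASS27))
    msg <- c(msg, "columns must be the 27 ordered structure-class labels")
  if (nrow(object@probs) > 0) {
    if (is.null(rownames(object@probs)) ||
        !all(nchar(rownames(object@probs)) == 3L))
      msg <- c(msg, "rows must be named by tripeptides")
    if (any(object@probs < -1e-12))
      msg <- c(msg, "probabilities must be non-negative")
    if (any(abs(rowSums(object@probs) - 1) > 1e-9))
      msg <- c(msg, "each tripeptide row must sum to 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Aggregated secondary-structure propensity profile
#'
#' Mean fractions of the reduced structure classes (all-helical "aaa",
#' all-extended "bbb", and "others") per relative position around
#' homorepeat regions: flank positions -10..-1 and +1..+10, with position 0
#' holding the mean over all residues inside the regions themselves.
#'
#' @slot fractions Numeric matrix, positions (rows, "-10".."-1", "0",
#'   "+1".."+10") by 3 class columns; rows with n > 0 sum to 1.
#' @slot n Integer vector of contributing residue counts per position.
#'
#' @seealso [aggregateRegionProfiles()]
#' @exportClass PropensityProfile
setClass("PropensityProfile",
  representation(fractions = "matrix", n = "integer"))

setValidity("PropensityProfile", function(object) {
  msg <- NULL
  if (!identical(colnames(object@fractions), c("aaa", "bbb", "others")))
    msg <- c(msg, "columns must be aaa, bbb, others")
  if (length(object@n) != nrow(object@fractions))
    msg <- c(msg, "n must have one entry per position")
  rs <- rowSums(object@fractions)
  if (any(object@n > 0L & abs(rs - 1) > 1e-9))
    msg <- c(msg, "fractions must sum to 1 at positions with n > 0")
  if (is.null(msg)) TRUE else msg
})

#' Ground truth for a synthetic proteome
#'
#' Ledger emitted by [generateProteome()] describing every planted repeat
#' region and per-protein metadata, for validating the detection and
#' downstream statistics against known parameters.
#'
#' @slot regions Planted regions as a [RepeatRegions-class] object.
#' @slot proteins data.frame with one row per protein: id, length, and the
#'   start class of its most N-terminal planted region ("none", "1", "2",
#'   "3-20", ">20").
#' @slot params List of the realised generator parameters (seed included).
#'
#' @seealso [generateProteome()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(regions = "RepeatRegions", proteins = "data.frame",
                 params = "list"))
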