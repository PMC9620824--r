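#' @rdname RepeatRegions-class
#' @param object,x A \linkS4class{RepeatRegions} object (accessors).
#' @export
setGeneric("proteinId", function(object) standardGeneric("proteinId"))

#' @rdname RepeatRegions-class
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))

#' @rdname RepeatRegions-class
#' @export
setGeneric("impurities", function(object) standardGeneric("impurities"))

#' @rdname RepeatRegions-class
#' @export
setGeneric("nTarget", function(object) standardGeneric("nTarget"))

#' @rdname RepeatRegions-class
#' @export
setGeneric("targetResidue", function(object) standardGeneric("targetResidue"))

#' @rdname BackgroundComposition-class
#' @param object A \linkS4class{BackgroundComposition} object.
#' @export
setGeneric("bgFreq", function(object) standardGeneric("bgFreq"))

#' @rdname BackgroundComposition-class
#' @export
setGeneric("totalResidues", function(object) standardGeneric("totalResidues"))

#' @rdname CompositionProfile-class
#' @param object A profile object.
#' @export
setGeneric("positionFreq", function(object) standardGeneric("positionFreq"))

#' @rdname EnrichmentProfile-class
#' @param object A profile object.
#' @export
setGeneric("positionRatio", function(object) standardGeneric("positionRatio"))

#' @rdname CompositionProfile-class
#' @export
setGeneric("positionCounts", function(object) standardGeneric("positionCounts"))

#' @rdname PropensityTable-class
#' @param object A \linkS4class{PropensityTable} object.
#' @param tripeptides Character vector of tripeptides to look up.
#' @export
setGeneric("propensityLookup",
  function(object, tripeptides) standardGeneric("propensityLookup"))

#' @rdname SyntheticTruth-class
#' @param object A \linkS4class{SyntheticTruth} object.
#' @export
setGeneric("truthRegions", function(object) standardGeneric("truthRegions"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthProteins", function(object) standardGeneric("truthProteins"))
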