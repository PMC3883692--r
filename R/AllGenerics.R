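#' @rdname DiallelDesign-class
#' @param object,x a \linkS4class{DiallelDesign} (or other object).
#' @export
setGeneric("parents", function(object) standardGeneric("parents"))

#' @rdname DiallelDesign-class
#' @export
setGeneric("hybrids", function(object) standardGeneric("hybrids"))

#' @rdname DiallelDesign-class
#' @export
setGeneric("nReplicates", function(object) standardGeneric("nReplicates"))

#' @rdname DiallelDesign-class
#' @export
setGeneric("nBatches", function(object) standardGeneric("nBatches"))

#' @rdname CRLMatrix-class
#' @param object a \linkS4class{CRLMatrix}.
#' @export
setGeneric("crlLabels", function(object) standardGeneric("crlLabels"))

#' @rdname CRLMatrix-class
#' @export
setGeneric("crlWeights", function(object) standardGeneric("crlWeights"))

#' @rdname CRLMatrix-class
#' @export
setGeneric("genotypeDrops", function(object) standardGeneric("genotypeDrops"))

#' @rdname CRLMatrix-class
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))

#' @rdname ParentalPairMatrix-class
#' @param object a \linkS4class{ParentalPairMatrix}.
#' @export
setGeneric("xppValues", function(object) standardGeneric("xppValues"))

#' @rdname ParentalPairMatrix-class
#' @export
setGeneric("rowHybrid", function(object) standardGeneric("rowHybrid"))

#' @rdname ParentalPairMatrix-class
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname ParentalPairMatrix-class
#' @export
setGeneric("featureTags", function(object) standardGeneric("featureTags"))

#' @rdname FeatureRanking-class
#' @param object a \linkS4class{FeatureRanking}.
#' @export
setGeneric("rankMatrix", function(object) standardGeneric("rankMatrix"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("rankSummary", function(object) standardGeneric("rankSummary"))

#' @rdname GroundTruth-class
#' @param object a \linkS4class{GroundTruth}.
#' @export
setGeneric("driverFeatures", function(object) standardGeneric("driverFeatures"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueLabels", function(object) standardGeneric("trueLabels"))

#' @rdname GroundTruth-class
#' @export
setGeneric("drivenMetabolites",
    function(object) standardGeneric("drivenMetabolites"))
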