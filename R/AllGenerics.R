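#' @rdname ScoreModel-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname ScoreModel-accessors
#' @export
setGeneric("backgroundFreqs",
           function(x) standardGeneric("backgroundFreqs"))

#' @rdname FamilyAlignment-accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))

#' @rdname FamilyAlignment-accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname FamilyAlignment-accessors
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname FamilyAlignment-accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname HomogeneityProfile-accessors
#' @export
setGeneric("homogeneityValues",
           function(x, scoredOnly = TRUE)
             standardGeneric("homogeneityValues"))

#' @rdname HomogeneityProfile-accessors
#' @export
setGeneric("columnMask", function(x) standardGeneric("columnMask"))

#' @rdname HomogeneityProfile-accessors
#' @export
setGeneric("meanHomogeneity", function(x) standardGeneric("meanHomogeneity"))

#' @rdname CsCOGPartition-accessors
#' @export
setGeneric("cscogGroups", function(x) standardGeneric("cscogGroups"))

#' @rdname CsCOGPartition-accessors
#' @export
setGeneric("cscogStats", function(x) standardGeneric("cscogStats"))

#' @rdname MsrAnnotation-accessors
#' @export
setGeneric("msrIntervals", function(x) standardGeneric("msrIntervals"))

#' @rdname MsrAnnotation-accessors
#' @export
setGeneric("msrFraction", function(x) standardGeneric("msrFraction"))
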