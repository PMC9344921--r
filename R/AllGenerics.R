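#' @rdname accessors
#' @export
setGeneric("spotPositions", function(x, ...) standardGeneric("spotPositions"))

#' @rdname accessors
#' @export
setGeneric("sectionImage", function(x) standardGeneric("sectionImage"))

#' @rdname accessors
#' @export
setGeneric("sectionImage<-", function(x, value) standardGeneric("sectionImage<-"))

#' @rdname accessors
#' @export
setGeneric("mappedReads", function(x) standardGeneric("mappedReads"))

#' @rdname accessors
#' @export
setGeneric("mappedReads<-", function(x, value) standardGeneric("mappedReads<-"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("sampleCondition", function(x) standardGeneric("sampleCondition"))

#' @rdname accessors
#' @export
setGeneric("timePoint", function(x) standardGeneric("timePoint"))

#' @rdname accessors
#' @export
setGeneric("micronsPerPixel", function(x) standardGeneric("micronsPerPixel"))

#' @rdname accessors
#' @export
setGeneric("spotCounts", function(x) standardGeneric("spotCounts"))

#' @rdname filterSpots
#' @export
setGeneric("filterSpots", function(x, ...) standardGeneric("filterSpots"))

#' @rdname filterSpots
#' @export
setGeneric("includedSpots", function(x, ...) standardGeneric("includedSpots"))

#' @rdname profileToTable
#' @export
setGeneric("profileToTable", function(x, ...) standardGeneric("profileToTable"))
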