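#' Accessor generics
#'
#' Accessors for the package's S4 classes. \code{recordingPeriods} returns
#' the list of channels x samples matrices; \code{eventTags} the event
#' table; \code{processingHistory} the append-only provenance list;
#' \code{segmentData} the 3-D segment array; \code{keepFlags} the logical
#' keep/reject vector; \code{meanPower} the across-segment mean spectrum;
#' \code{itpcValues} the complex ITPC array.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recordingPeriods", function(x) standardGeneric("recordingPeriods"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("eventTags", function(x) standardGeneric("eventTags"))
#' @rdname accessors
#' @export
setGeneric("dataType", function(x) standardGeneric("dataType"))
#' @rdname accessors
#' @export
setGeneric("processingHistory", function(x) standardGeneric("processingHistory"))
#' @rdname accessors
#' @export
setGeneric("badChannels", function(x) standardGeneric("badChannels"))
#' @rdname accessors
#' @export
setGeneric("lineNoiseHz", function(x) standardGeneric("lineNoiseHz"))
#' @rdname accessors
#' @export
setGeneric("layoutName", function(x) standardGeneric("layoutName"))
#' @rdname accessors
#' @export
setGeneric("originalSamplingRate", function(x) standardGeneric("originalSamplingRate"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nPeriods", function(x) standardGeneric("nPeriods"))
#' @rdname accessors
#' @export
setGeneric("segmentData", function(x) standardGeneric("segmentData"))
#' @rdname accessors
#' @export
setGeneric("keepFlags", function(x) standardGeneric("keepFlags"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("relTimeMs", function(x) standardGeneric("relTimeMs"))
#' @rdname accessors
#' @export
setGeneric("maskIntervals", function(x) standardGeneric("maskIntervals"))
#' @rdname accessors
#' @export
setGeneric("psdFreqs", function(x) standardGeneric("psdFreqs"))
#' @rdname accessors
#' @export
setGeneric("meanPower", function(x) standardGeneric("meanPower"))
#' @rdname accessors
#' @export
setGeneric("itpcValues", function(x) standardGeneric("itpcValues"))
#' @rdname accessors
#' @export
setGeneric("windowCentersMs", function(x) standardGeneric("windowCentersMs"))
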