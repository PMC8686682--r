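#' @name polarmin-generics
#' @title Accessor generics
#' @description Accessors for the S4 classes in polarmin. All positions are
#'   1-based.
#' @param x,object an object.
#' @param ... further arguments for methods.
NULL

#' @rdname polarmin-generics
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))

#' @rdname polarmin-generics
#' @export
setGeneric("slackness", function(x) standardGeneric("slackness"))

#' @rdname polarmin-generics
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname polarmin-generics
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname polarmin-generics
#' @export
setGeneric("spacingThreshold", function(x) standardGeneric("spacingThreshold"))

#' @rdname polarmin-generics
#' @export
setGeneric("selectedPositions", function(x) standardGeneric("selectedPositions"))

#' @rdname polarmin-generics
#' @export
setGeneric("specificDensity", function(x) standardGeneric("specificDensity"))

#' @rdname polarmin-generics
#' @export
setGeneric("densityFactor", function(x) standardGeneric("densityFactor"))

#' @rdname polarmin-generics
#' @export
setGeneric("nCharged", function(x) standardGeneric("nCharged"))

#' @rdname polarmin-generics
#' @export
setGeneric("nContexts", function(x) standardGeneric("nContexts"))

#' @rdname polarmin-generics
#' @export
setGeneric("nKmers", function(x) standardGeneric("nKmers"))

#' @rdname polarmin-generics
#' @export
setGeneric("initialEnergy", function(x) standardGeneric("initialEnergy"))

#' @rdname polarmin-generics
#' @export
setGeneric("energyDeficit", function(x) standardGeneric("energyDeficit"))

#' @rdname polarmin-generics
#' @export
setGeneric("energySurplus", function(x) standardGeneric("energySurplus"))

#' @rdname polarmin-generics
#' @export
setGeneric("totalLinkEnergy", function(x) standardGeneric("totalLinkEnergy"))

#' @rdname polarmin-generics
#' @export
setGeneric("linkTable", function(x) standardGeneric("linkTable"))

#' @rdname polarmin-generics
#' @export
setGeneric("uncoveredElements", function(x) standardGeneric("uncoveredElements"))

#' Occurrence query on a suffix index
#'
#' @param x a \linkS4class{SuffixIndex}.
#' @param t 1-based position of a break-free k-mer start.
#' @return Sorted 1-based positions of all occurrences of the k-mer
#'   starting at \code{t}.
#' @export
setGeneric("occurrences", function(x, t) standardGeneric("occurrences"))

#' Frequency threshold covering a fraction of positions
#'
#' Smallest occurrence count f such that positions whose k-mer occurs at
#' most f times make up at least \code{percentile} of all k-mer positions.
#' Used to filter frequent k-mers out of polar set construction.
#'
#' @param x a \linkS4class{SuffixIndex}.
#' @param percentile fraction of positions to include, in (0, 1].
#' @return Integer threshold.
#' @export
setGeneric("frequencyThreshold",
           function(x, percentile) standardGeneric("frequencyThreshold"))

#' @rdname LinkedBlocks-class
#' @param x a \linkS4class{LinkedBlocks}.
#' @param pos 1-based location.
#' @export
setGeneric("addLocation", function(x, pos) standardGeneric("addLocation"))

#' @rdname LinkedBlocks-class
#' @export
setGeneric("removeLocation", function(x, pos) standardGeneric("removeLocation"))

#' @rdname LinkedBlocks-class
#' @export
setGeneric("peekLeft", function(x, pos) standardGeneric("peekLeft"))

#' @rdname LinkedBlocks-class
#' @export
setGeneric("peekRight", function(x, pos) standardGeneric("peekRight"))

#' @rdname LinkedBlocks-class
#' @export
setGeneric("blockStats", function(x) standardGeneric("blockStats"))

#' @rdname LinkedBlocks-class
#' @export
setGeneric("selectedLocations", function(x) standardGeneric("selectedLocations"))
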