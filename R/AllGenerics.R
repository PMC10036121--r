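#' @rdname GenomeModel-class
#' @param x a [GenomeModel] or [FragmentTrack].
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeModel-class
#' @export
setGeneric("gatcSites", function(x) standardGeneric("gatcSites"))

#' @rdname GenomeModel-class
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname GenomeModel-class
#' @export
setGeneric("nFragments", function(x) standardGeneric("nFragments"))

#' @rdname GenomeModel-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname FragmentTrack-class
#' @param x a [FragmentTrack].
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname FragmentTrack-class
#' @export
setGeneric("trackKind", function(x) standardGeneric("trackKind"))

#' @rdname FragmentTrack-class
#' @export
setGeneric("trackGenome", function(x) standardGeneric("trackGenome"))
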