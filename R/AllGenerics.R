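#' @rdname GeneTable
#' @export
setGeneric("speciesKey", function(x) standardGeneric("speciesKey"))

#' @rdname GeneTable
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneTable
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname GeneTable
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname HomologySource
#' @export
setGeneric("sourceName", function(x) standardGeneric("sourceName"))

#' @rdname orthologsOf
#' @export
setGeneric("orthologsOf", function(x, gene, speciesFrom, speciesTo)
  standardGeneric("orthologsOf"))

#' @rdname orthologsOf
#' @export
setGeneric("paralogsOf", function(x, gene, species)
  standardGeneric("paralogsOf"))

#' @rdname ScreenResult
#' @export
setGeneric("screenHits", function(x) standardGeneric("screenHits"))

#' @rdname ScreenResult
#' @export
setGeneric("presenceCalls", function(x) standardGeneric("presenceCalls"))
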