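#' @rdname CommunityCatalog-class
#' @param x,object A `CommunityCatalog`.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname CommunityCatalog-class
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname CommunityCatalog-class
#' @export
setGeneric("targetGenomes", function(x) standardGeneric("targetGenomes"))

#' @rdname CommunityCatalog-class
#' @export
setGeneric("nontargetGenomes", function(x) standardGeneric("nontargetGenomes"))

#' @rdname CommunityCatalog-class
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))

#' @rdname CommunityCatalog-class
#' @export
setGeneric("geneData", function(x) standardGeneric("geneData"))

#' @rdname CommunityCatalog-class
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
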