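#' @rdname MetabolitePanel-class
#' @export
setGeneric("accessionIds", function(x) standardGeneric("accessionIds"))

#' @rdname MetabolitePanel-class
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname MetabolitePanel-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname MetabolitePanel-class
#' @export
setGeneric("panelValues", function(x) standardGeneric("panelValues"))

#' @rdname MetabolitePanel-class
#' @export
setGeneric("valueScale", function(x) standardGeneric("valueScale"))

#' @rdname GenotypeSet-class
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname GenotypeSet-class
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))

#' @rdname GenotypeSet-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname GenotypeSet-class
#' @export
setGeneric("snpMaf", function(x) standardGeneric("snpMaf"))
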