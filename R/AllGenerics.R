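#' @import methods
#' @importFrom BiocGenerics strand start end width
NULL

#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("exonsByTx", function(x, ...) standardGeneric("exonsByTx"))

#' @export
setGeneric("intronsByTx", function(x, ...) standardGeneric("intronsByTx"))

#' @export
setGeneric("smrtSupported", function(x) standardGeneric("smrtSupported"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("classLabels<-", function(x, value) standardGeneric("classLabels<-"))

#' @export
setGeneric("eventIds", function(x) standardGeneric("eventIds"))

#' @export
setGeneric("eventTypes", function(x) standardGeneric("eventTypes"))

#' @export
setGeneric("psiValues", function(x) standardGeneric("psiValues"))

#' @export
setGeneric("totalTpm", function(x) standardGeneric("totalTpm"))
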