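#' @rdname SignatureSet-class
#' @param object a package object.
#' @export
setGeneric("signatures", function(object) standardGeneric("signatures"))

#' @rdname SignatureSet-class
#' @export
setGeneric("markerTable", function(object) standardGeneric("markerTable"))

#' @rdname CooccurrenceNetwork-class
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname CooccurrenceNetwork-class
#' @export
setGeneric("zScores", function(object) standardGeneric("zScores"))

#' @rdname CooccurrenceNetwork-class
#' @export
setGeneric("candidateGenes", function(object) standardGeneric("candidateGenes"))

#' Rank cell types by network connectivity
#'
#' Orders cell types by undirected degree (ties broken by weighted degree,
#' then lexical id), identifying the hub types of the co-occurrence network.
#'
#' @param object a [CooccurrenceNetwork-class].
#' @return a `DataFrame` with columns `type`, `degree`, `weightedDegree`,
#'   ordered from most to least connected.
#' @export
setGeneric("hubRanking", function(object) standardGeneric("hubRanking"))

#' @rdname LRResult-class
#' @export
setGeneric("lrTable", function(object) standardGeneric("lrTable"))
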