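# Accessors and show methods for the package's S4 classes.

#' @rdname SignatureSet-class
#' @aliases signatures,SignatureSet-method
#' @export
setMethod("signatures", "SignatureSet", function(object) object@signatures)

#' @rdname SignatureSet-class
#' @aliases markerTable,SignatureSet-method
#' @export
setMethod("markerTable", "SignatureSet", function(object) object@markers)

setMethod("show", "SignatureSet", function(object) {
    cat("SignatureSet with", length(object@signatures), "cell types\n")
    ns <- lengths(object@signatures)
    cat("  genes per type:", paste(sprintf("%s=%d", names(ns), ns),
                                   collapse = ", "), "\n")
    th <- object@thresholds
    cat(sprintf("  thresholds: pct_in > %g, log2FC > %g%s\n",
                th$minPct, th$minLog2fc,
                if (is.finite(th$maxGenes)) sprintf(", max %d genes",
                                                    th$maxGenes) else ""))
})

#' @rdname CooccurrenceNetwork-class
#' @aliases edges,CooccurrenceNetwork-method
#' @export
setMethod("edges", "CooccurrenceNetwork", function(object) object@edges)

#' @rdname CooccurrenceNetwork-class
#' @aliases zScores,CooccurrenceNetwork-method
#' @export
setMethod("zScores", "CooccurrenceNetwork", function(object) object@z)

#' @rdname CooccurrenceNetwork-class
#' @aliases candidateGenes,CooccurrenceNetwork-method
#' @export
setMethod("candidateGenes", "CooccurrenceNetwork",
          function(object) object@candidates)

setMethod("show", "CooccurrenceNetwork", function(object) {
    cat("CooccurrenceNetwork over", nrow(object@z), "cell types\n")
    cat(sprintf("  directed hits at z > %g; %d undirected edge(s)\n",
                object@threshold, nrow(object@edges)))
    if (nrow(object@edges)) {
        ed <- object@edges
        for (i in seq_len(min(nrow(ed), 10)))
            cat(sprintf("  %s -- %s (weight %.3f)\n",
                        ed$typeA[i], ed$typeB[i], ed$weight[i]))
        if (nrow(ed) > 10) cat("  ...\n")
    }
})

#' @rdname hubRanking
#' @aliases hubRanking,CooccurrenceNetwork-method
#' @export
setMethod("hubRanking", "CooccurrenceNetwork", function(object) {
    types <- rownames(object@z)
    deg <- stats::setNames(numeric(length(types)), types)
    wdeg <- deg
    ed <- object@edges
    if (nrow(ed)) {
        for (i in seq_len(nrow(ed))) {
            a <- ed$typeA[i]; b <- ed$typeB[i]; w <- ed$weight[i]
            deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
            wdeg[a] <- wdeg[a] + w; wdeg[b] <- wdeg[b] + w
        }
    }
    ord <- order(-deg, -wdeg, types)
    S4Vectors::DataFrame(type = types[ord], degree = as.integer(deg[ord]),
                         weightedDegree = wdeg[ord])
})

#' @rdname LRResult-class
#' @aliases lrTable,LRResult-method
#' @export
setMethod("lrTable", "LRResult", function(object) object@table)

setMethod("show", "LRResult", function(object) {
    tb <- object@table
    cat(sprintf("LRResult: %d scored (cluster pair, L-R pair) rows over %d clusters\n",
                nrow(tb), length(object@clusters)))
    cat(sprintf("  null: %s%d label %s\n",
                if (object@exhaustive) "exhaustive, " else "",
                object@nPerm,
                if (object@exhaustive) "assignments" else "permutations"))
    if (!is.null(tb$significant))
        cat("  significant rows:", sum(tb$significant), "\n")
})

setMethod("show", "KMCurve", function(object) {
    cat(sprintf("KMCurve '%s': %d time points, %d events, final S = %.4f\n",
                object@group, length(object@time), sum(object@nEvent),
                if (length(object@surv)) object@surv[length(object@surv)]
                else 1))
})

setMethod("show", "SimParams", function(object) {
    cat("SimParams:\n")
    cat(sprintf("  %d genes, %d cell types x %d cells, %d markers/type (fold %g, NB dispersion %g)\n",
                object@nGenes, object@nCellTypes, object@cellsPerType,
                object@markersPerType, object@markerFold, object@nbDispersion))
    cat(sprintf("  %d bulk samples (logit sd %g, noise CV %g); %d L-R pairs (%d planted)\n",
                object@nBulkSamples, object@propLogitSd, object@bulkNoiseCv,
                object@lrPairs, length(object@plantedLR)))
    cat(sprintf("  survival log-HR %g on %d effect gene(s); seed %d\n",
                object@survivalLogHR, length(object@survivalEffectGenes),
                object@seed))
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:\n")
    if (length(object@trueLabels))
        cat(sprintf("  %d cells over %d types\n", length(object@trueLabels),
                    length(unique(object@trueLabels))))
    if (ncol(object@trueProportions))
        cat(sprintf("  proportions for %d bulk samples; %d planted edge(s)\n",
                    ncol(object@trueProportions), nrow(object@plantedEdges)))
    if (nrow(object@plantedLRPairs))
        cat(sprintf("  %d planted L-R pair(s)\n", nrow(object@plantedLRPairs)))
    if (length(object@survivalGroups))
        cat("  survival hazard groups recorded\n")
})
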