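#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Simulation parameters for paired single-cell / bulk experiments
#'
#' Container holding every knob of the synthetic-data generator: the
#' single-cell negative-binomial model (genes, cell types, markers, fold
#' change, dispersion), the bulk mixture model (number of samples, target
#' correlation of mixing proportions, multiplicative noise), the planted
#' ligand-receptor structure and the planted survival effect.
#'
#' @slot nGenes number of genes simulated.
#' @slot nCellTypes number of annotated cell types.
#' @slot cellsPerType cells drawn per type.
#' @slot markersPerType marker genes planted per type.
#' @slot markerFold mean multiplier applied to a type's markers in that type.
#' @slot nbDispersion shared negative-binomial dispersion (var = mu + phi mu^2).
#' @slot nBulkSamples number of bulk samples mixed from the cell-type profiles.
#' @slot proportionCorr target correlation matrix of the latent Gaussian
#'   driving mixing proportions (symmetric, unit diagonal).
#' @slot propLogitSd standard deviation of the latent Gaussian on the logit
#'   scale; controls how variable proportions are across samples.
#' @slot bulkNoiseCv coefficient of variation of multiplicative lognormal
#'   noise on bulk expression.
#' @slot lrPairs number of ligand-receptor pairs in the simulated database.
#' @slot plantedLR list of length-2 integer vectors (ligand cluster,
#'   receptor cluster) receiving a cluster-specific pair each.
#' @slot secretedFrac fraction of database pairs flagged secreted.
#' @slot survivalEffectGenes genes whose mean bulk expression drives hazard.
#' @slot survivalLogHR log hazard ratio per SD of the effect-gene score.
#' @slot seed integer seed; all stages derive their streams from it.
#' @exportClass SimParams
setClass("SimParams", representation(
    nGenes = "integer", nCellTypes = "integer", cellsPerType = "integer",
    markersPerType = "integer", markerFold = "numeric",
    nbDispersion = "numeric", nBulkSamples = "integer",
    proportionCorr = "matrix", propLogitSd = "numeric",
    bulkNoiseCv = "numeric", lrPairs = "integer", plantedLR = "list",
    secretedFrac = "numeric", survivalEffectGenes = "character",
    survivalLogHR = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- character()
    chkPos <- function(x, nm) if (length(x) != 1L || is.na(x) || x < 1L)
        sprintf("'%s' must be a single positive count", nm) else character()
    msg <- c(msg, chkPos(object@nGenes, "nGenes"),
             chkPos(object@nCellTypes, "nCellTypes"),
             chkPos(object@cellsPerType, "cellsPerType"),
             chkPos(object@markersPerType, "markersPerType"),
             chkPos(object@nBulkSamples, "nBulkSamples"))
    if (object@markerFold <= 0) msg <- c(msg, "'markerFold' must be positive")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "'nbDispersion' must be positive")
    if (object@bulkNoiseCv < 0)
        msg <- c(msg, "'bulkNoiseCv' must be nonnegative")
    if (object@propLogitSd <= 0)
        msg <- c(msg, "'propLogitSd' must be positive")
    if (object@secretedFrac < 0 || object@secretedFrac > 1)
        msg <- c(msg, "'secretedFrac' must lie in [0, 1]")
    if (object@lrPairs < 0L) msg <- c(msg, "'lrPairs' must be nonnegative")
    pc <- object@proportionCorr
    if (nrow(pc) != object@nCellTypes || ncol(pc) != object@nCellTypes)
        msg <- c(msg, "'proportionCorr' must be nCellTypes x nCellTypes")
    else {
        if (max(abs(pc - t(pc))) > 1e-8)
            msg <- c(msg, "'proportionCorr' must be symmetric")
        if (max(abs(diag(pc) - 1)) > 1e-8)
            msg <- c(msg, "'proportionCorr' must have unit diagonal")
        if (any(abs(pc) > 1 + 1e-8))
            msg <- c(msg, "'proportionCorr' entries must lie in [-1, 1]")
    }
    if (object@markersPerType * object@nCellTypes > object@nGenes)
        msg <- c(msg, "markersPerType * nCellTypes must not exceed nGenes")
    for (pl in object@plantedLR) {
        if (length(pl) != 2L || any(pl < 1L) || any(pl > object@nCellTypes))
            msg <- c(msg,
                "each 'plantedLR' entry must name two existing cell types")
    }
    if (is.na(object@seed) || abs(object@seed) >= 2^31 - 100)
        msg <- c(msg, "'seed' must be an integer below 2^31 - 100")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated experiment
#'
#' Accumulates the planted truth as the generator stages run: per-cell type
#' labels and marker lists after [simulateCells()], true mixing proportions
#' and planted co-occurrence edges after [simulateBulk()], planted
#' ligand-receptor pairs after [simulateLRDatabase()], and latent hazard
#' groups after [simulateSurvival()].
#'
#' @slot trueLabels per-cell type assignment.
#' @slot trueMarkers named list, per-type planted marker genes.
#' @slot trueProportions cell type x bulk sample mixing proportions
#'   (columns sum to 1).
#' @slot plantedEdges DataFrame of unordered type pairs whose latent
#'   proportion correlation magnitude exceeds `edgeThreshold`.
#' @slot edgeThreshold declared |correlation| threshold defining planted edges.
#' @slot plantedLRPairs DataFrame (pair, ligand cluster, receptor cluster).
#' @slot survivalGroups latent High/Low hazard labels per bulk sample.
#' @exportClass SimTruth
setClass("SimTruth", representation(
    trueLabels = "character", trueMarkers = "list",
    trueProportions = "matrix", plantedEdges = "DataFrame",
    edgeThreshold = "numeric", plantedLRPairs = "DataFrame",
    survivalGroups = "character"),
    prototype(trueProportions = matrix(numeric(), 0, 0),
              plantedEdges = S4Vectors::DataFrame(),
              edgeThreshold = NA_real_,
              plantedLRPairs = S4Vectors::DataFrame()))

setValidity("SimTruth", function(object) {
    msg <- character()
    tp <- object@trueProportions
    if (length(tp) && ncol(tp) > 0) {
        if (any(abs(colSums(tp) - 1) > 1e-12))
            msg <- c(msg, "trueProportions columns must sum to 1")
        if (nrow(object@plantedEdges)) {
            types <- rownames(tp)
            bad <- !(object@plantedEdges$typeA %in% types &
                     object@plantedEdges$typeB %in% types)
            if (any(bad))
                msg <- c(msg, "planted edges reference unknown cell types")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Cell-type signature sets
#'
#' Per-cell-type marker-gene lists together with the marker statistics that
#' admitted each gene and the thresholds used. Built by [buildSignatures()]
#' from the output of [findMarkers()].
#'
#' @slot signatures named list of character vectors, ordered by decreasing
#'   log2 fold change within each type.
#' @slot markers DataFrame of the admitted marker records.
#' @slot thresholds list(minPct, minLog2fc, maxGenes) used for admission.
#' @exportClass SignatureSet
setClass("SignatureSet", representation(
    signatures = "list", markers = "DataFrame", thresholds = "list"))

setValidity("SignatureSet", function(object) {
    msg <- character()
    if (is.null(names(object@signatures)) ||
        anyDuplicated(names(object@signatures)))
        msg <- c(msg, "signatures must be a uniquely named list")
    dup <- vapply(object@signatures, anyDuplicated, 0L) > 0L
    if (any(dup))
        msg <- c(msg, paste0("duplicate genes within signature(s): ",
                             paste(names(object@signatures)[dup],
                                   collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Cell-type co-occurrence network
#'
#' Directed enrichment z-scores between cell types (row i = focal type whose
#' top correlated non-self genes were scored across all types) plus the
#' derived undirected weighted edge set, candidate gene lists and self-gene
#' exclusions. Built by [buildNetwork()] / [runCooccurrence()].
#'
#' @slot z directed cell type x cell type z-score matrix; `z[i, j]` is the
#'   enrichment of type j on type i's candidate gene set.
#' @slot threshold z-score cutoff (strictly exceeded) for a directed hit.
#' @slot edges DataFrame (typeA, typeB, weight, zAB, zBA) of undirected edges.
#' @slot candidates named list of per-focal-type candidate gene vectors.
#' @slot selfExcluded named list of genes removed as self-expressed.
#' @slot degenerate named logical; TRUE where a focal type's enrichment
#'   profile was constant (z row forced to 0).
#' @exportClass CooccurrenceNetwork
setClass("CooccurrenceNetwork", representation(
    z = "matrix", threshold = "numeric", edges = "DataFrame",
    candidates = "list", selfExcluded = "list", degenerate = "logical"))

setValidity("CooccurrenceNetwork", function(object) {
    msg <- character()
    z <- object@z
    if (nrow(z) != ncol(z) || is.null(rownames(z)) ||
        !identical(rownames(z), colnames(z)))
        msg <- c(msg, "z must be square with matching dimnames")
    deg <- object@degenerate
    for (i in seq_len(nrow(z))) {
        if (length(deg) >= i && isTRUE(deg[i])) next
        if (abs(mean(z[i, ])) > 1e-10 || abs(stats::sd(z[i, ]) - 1) > 1e-10)
            msg <- c(msg, sprintf(
                "z row '%s' is not standardized (mean 0, sd 1)",
                rownames(z)[i]))
    }
    ed <- object@edges
    if (nrow(ed)) {
        if (any(ed$typeA == ed$typeB)) msg <- c(msg, "self-edges not allowed")
        if (any(ed$weight <= object@threshold))
            msg <- c(msg, "every edge weight must exceed the threshold")
    }
    if (length(msg)) msg else TRUE
})

#' Ligand-receptor permutation test results
#'
#' One row per (donor cluster, acceptor cluster, ligand-receptor pair) that
#' survived expression masking: the observed mean statistic, the display
#' statistic sqrt(mean(ligand x receptor + 1)), the permutation p-value, the
#' secreted flag and (after [filterSignificant()]) the significance flag.
#'
#' @slot table DataFrame of results.
#' @slot clusters all cluster labels tested (needed to shape the
#'   interaction-strength matrix even when some pairs have no rows).
#' @slot nPerm number of label permutations (or distinct assignments when
#'   exhaustive).
#' @slot exhaustive TRUE when the null enumerated all distinct assignments.
#' @slot seed seed used for the permutation stream and display-stat pairing.
#' @exportClass LRResult
setClass("LRResult", representation(
    table = "DataFrame", clusters = "character", nPerm = "integer",
    exhaustive = "logical", seed = "integer"))

setValidity("LRResult", function(object) {
    tb <- object@table
    msg <- character()
    if (nrow(tb)) {
        if (any(tb$p < 0 | tb$p > 1)) msg <- c(msg, "p-values must be in [0,1]")
        if (!all(tb$clusterA %in% object@clusters) ||
            !all(tb$clusterB %in% object@clusters))
            msg <- c(msg, "table clusters missing from the cluster set")
    }
    if (length(msg)) msg else TRUE
})

#' Kaplan-Meier curve
#'
#' Product-limit estimate over the distinct observed times of one group.
#'
#' @slot time distinct observed times, ascending.
#' @slot nRisk number at risk just before each time.
#' @slot nEvent events at each time.
#' @slot surv survival probability at each time (nonincreasing, starts from 1).
#' @slot group label of the stratum.
#' @exportClass KMCurve
setClass("KMCurve", representation(
    time = "numeric", nRisk = "numeric", nEvent = "numeric",
    surv = "numeric", group = "character"))

setValidity("KMCurve", function(object) {
    msg <- character()
    n <- length(object@time)
    if (length(object@surv) != n || length(object@nRisk) != n ||
        length(object@nEvent) != n)
        msg <- c(msg, "time, nRisk, nEvent and surv must have equal length")
    if (n) {
        if (is.unsorted(object@time)) msg <- c(msg, "times must be ascending")
        if (any(object@time < 0)) msg <- c(msg, "times must be nonnegative")
        if (any(object@surv < 0 | object@surv > 1))
            msg <- c(msg, "survival must lie in [0, 1]")
        if (any(diff(object@surv) > 1e-12))
            msg <- c(msg, "survival must be nonincreasing")
    }
    if (length(msg)) msg else TRUE
})
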