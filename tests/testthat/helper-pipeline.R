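# End-to-end pipeline runs at the study conditions (6 cell types, 200 bulk
# samples, generator defaults), shared by the calibration tests.

# Simulate, QC, normalize, find signatures and build the co-occurrence
# network for one seed; returns the recovered and planted undirected edges.
cooccurrenceRun <- function(seed, plantedPairs = list(c(1, 2), c(3, 4)),
                            latentR = 0.8, nBulk = 200) {
    pc <- diag(6)
    for (pp in plantedPairs) {
        pc[pp[1], pp[2]] <- latentR
        pc[pp[2], pp[1]] <- latentR
    }
    sp <- simParams(nBulkSamples = nBulk, proportionCorr = pc, seed = seed)
    sim <- simulateCells(sp)
    sce <- logNormalize(qcFilter(sim$sce))
    sigs <- buildSignatures(findMarkers(sce))
    sb <- simulateBulk(sim$sce, sim$truth, sp)
    net <- suppressWarnings(
        runCooccurrence(normalizeBulk(sb$bulk), sce, sigs))
    found <- edges(net)
    foundKeys <- if (nrow(found))
        paste(pmin(found$typeA, found$typeB),
              pmax(found$typeA, found$typeB)) else character()
    pl <- sb$truth@plantedEdges
    plantedKeys <- if (nrow(pl))
        paste(pmin(pl$typeA, pl$typeB), pmax(pl$typeA, pl$typeB))
    else character()
    list(found = foundKeys, planted = plantedKeys, net = net)
}

edgePrecision <- function(found, planted) {
    if (!length(found)) return(0)
    mean(found %in% planted)
}

edgeRecall <- function(found, planted) {
    if (!length(planted)) return(1)
    mean(planted %in% found)
}
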