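test_that("simulateCells bookkeeping, null case and determinism", {
    sp <- simParams(nGenes = 200, nCellTypes = 3, cellsPerType = 50,
                    markersPerType = 5, seed = 42L)
    sim <- simulateCells(sp)
    expect_equal(ncol(sim$sce), 150)
    expect_equal(unname(table(SummarizedExperiment::colData(sim$sce)$label)),
                 array(rep(50L, 3)), ignore_attr = TRUE)
    expect_equal(lengths(sim$truth@trueMarkers), c(type01 = 5L, type02 = 5L,
                                                   type03 = 5L))
    # same seed twice: identical counts
    sim2 <- simulateCells(sp)
    expect_identical(
        as.matrix(SummarizedExperiment::assay(sim$sce, "counts")),
        as.matrix(SummarizedExperiment::assay(sim2$sce, "counts")))
    # markerFold = 1 plants no differential expression: per-type means of
    # "marker" genes stay near baseline everywhere
    spNull <- simParams(nGenes = 200, nCellTypes = 3, cellsPerType = 80,
                        markersPerType = 5, markerFold = 1, seed = 7L)
    simN <- simulateCells(spNull)
    cnt <- as.matrix(SummarizedExperiment::assay(simN$sce, "counts"))
    lab <- SummarizedExperiment::colData(simN$sce)$label
    g <- simN$truth@trueMarkers[["type01"]]
    mIn <- mean(cnt[g, lab == "type01"]); mOut <- mean(cnt[g, lab != "type01"])
    expect_lt(abs(log2((mIn + 1) / (mOut + 1))), 0.35)
})

test_that("simulateCells validates its configuration", {
    expect_error(simParams(nGenes = 10, nCellTypes = 3, markersPerType = 5),
                 "markersPerType")
    expect_error(simParams(markerFold = -1), "markerFold")
    expect_error(simParams(proportionCorr = matrix(0.5, 2, 2),
                           nCellTypes = 2), "diagonal")
})

test_that("simulateBulk proportions honor the planted correlation structure", {
    # planted latent corr 0.8 between types 1-2 among 6 types: the realized
    # simplex correlation is attenuated by the softmax and by compositional
    # closure (small-sd limit ~0.67 for a single planted pair) but stays
    # clearly positive; under identity the closure makes off-diagonal
    # correlations mildly negative (~ -1/(T-1)), never substantially positive
    rPlanted <- rNull <- numeric(8)
    for (s in seq_len(8)) {
        pc <- diag(6); pc[1, 2] <- pc[2, 1] <- 0.8
        sp <- simParams(nGenes = 150, nCellTypes = 6, cellsPerType = 30,
                        markersPerType = 5, nBulkSamples = 200,
                        proportionCorr = pc, seed = 300L + s)
        sim <- simulateCells(sp)
        sb <- simulateBulk(sim$sce, sim$truth, sp)
        pr <- sb$truth@trueProportions
        expect_lt(max(abs(colSums(pr) - 1)), 1e-12)
        rPlanted[s] <- cor(pr[1, ], pr[2, ])
        spN <- simParams(nGenes = 150, nCellTypes = 6, cellsPerType = 30,
                         markersPerType = 5, nBulkSamples = 200,
                         seed = 400L + s)
        simN <- simulateCells(spN)
        prN <- simulateBulk(simN$sce, simN$truth, spN)$truth@trueProportions
        cc <- cor(t(prN))
        rNull[s] <- max(cc[upper.tri(cc)])
    }
    expect_true(all(rPlanted > 0.5 & rPlanted < 0.95))
    expect_true(all(rNull < 0.2))
    expect_equal(as.data.frame(sb$truth@plantedEdges)[, 1:2],
                 data.frame(typeA = "type01", typeB = "type02"))
})

test_that("a pure single-type mixture reproduces the type profile", {
    sp <- simParams(nGenes = 100, nCellTypes = 1, cellsPerType = 40,
                    markersPerType = 5, nBulkSamples = 5, bulkNoiseCv = 0,
                    proportionCorr = diag(1), seed = 5L)
    sim <- simulateCells(sp)
    sb <- simulateBulk(sim$sce, sim$truth, sp)
    prof <- rowMeans(as.matrix(
        SummarizedExperiment::assay(sim$sce, "counts")))
    vals <- SummarizedExperiment::assay(sb$bulk, 1)
    for (j in seq_len(ncol(vals)))
        expect_equal(unname(vals[, j]), unname(prof), tolerance = 1e-12)
})

test_that("non-PSD proportion correlations are repaired or rejected", {
    pc <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
    sp <- simParams(nGenes = 100, nCellTypes = 3, cellsPerType = 20,
                    markersPerType = 5, nBulkSamples = 10,
                    proportionCorr = pc, seed = 2L)
    sim <- simulateCells(sp)
    expect_error(simulateBulk(sim$sce, sim$truth, sp),
                 "positive semidefinite")
    pcMild <- matrix(c(1, 0.7, 0.7, 0.7, 1, -0.02, 0.7, -0.02, 1), 3, 3)
    spM <- simParams(nGenes = 100, nCellTypes = 3, cellsPerType = 20,
                     markersPerType = 5, nBulkSamples = 10,
                     proportionCorr = pcMild, seed = 2L)
    simM <- simulateCells(spM)
    expect_no_error(simulateBulk(simM$sce, simM$truth, spM))
})

test_that("simulateLRDatabase plants specificity and secreted bookkeeping", {
    sp <- simParams(nGenes = 300, nCellTypes = 4, cellsPerType = 40,
                    markersPerType = 10, lrPairs = 20,
                    plantedLR = list(c(1L, 2L), c(3L, 4L)),
                    secretedFrac = 0.4, seed = 9L)
    sim <- simulateCells(sp)
    lr <- simulateLRDatabase(sp, sim$sce, sim$truth)
    expect_equal(nrow(lr$db), 20)
    expect_equal(sum(lr$db$secreted), round(0.4 * 20))
    pl <- lr$truth@plantedLRPairs
    expect_equal(nrow(pl), 2)
    # planted ligand's cluster mean is maximal in its donor cluster
    cnt <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
    lab <- SummarizedExperiment::colData(sim$sce)$label
    m <- vapply(sort(unique(lab)), function(t)
        mean(cnt[pl$ligand[1], lab == t]), 0)
    expect_equal(names(which.max(m)), pl$ligandCluster[1])
    # decoys never reuse marker genes
    decoys <- lr$db[!(lr$db$pair %in% pl$pair), ]
    expect_length(intersect(c(decoys$ligand, decoys$receptor),
                            unlist(sim$truth@trueMarkers)), 0)
    expect_error(simulateLRDatabase(
        simParams(nGenes = 300, nCellTypes = 4, cellsPerType = 40,
                  markersPerType = 10, lrPairs = 1,
                  plantedLR = list(c(1L, 2L), c(3L, 4L)), seed = 9L),
        sim$sce, sim$truth), "more planted")
})

test_that("simulateSurvival plants a hazard effect and validates genes", {
    sim <- smallSim(seed = 21L)
    sb <- simulateBulk(sim$sce, sim$truth, sim$params)
    spBad <- simParams(nGenes = 300, nCellTypes = 4, cellsPerType = 40,
                       markersPerType = 10, nBulkSamples = 60,
                       survivalEffectGenes = "NOPE", seed = 21L)
    expect_error(simulateSurvival(sb$bulk, spBad), "NOPE")
    eff <- sim$truth@trueMarkers[["type01"]][1:3]
    spS <- simParams(nGenes = 300, nCellTypes = 4, cellsPerType = 40,
                     markersPerType = 10, nBulkSamples = 60,
                     survivalEffectGenes = eff, survivalLogHR = 1.5,
                     seed = 21L)
    sv <- simulateSurvival(sb$bulk, spS, sb$truth)
    expect_setequal(colnames(sb$bulk), sv$survival$sample)
    expect_true(all(sv$survival$event %in% 0:1))
    # high-hazard group dies faster on average among events
    grp <- sv$truth@survivalGroups[sv$survival$sample]
    ev <- sv$survival$event == 1
    expect_lt(median(sv$survival$time[ev & grp == "High"]),
              median(sv$survival$time[ev & grp == "Low"]))
})

test_that("writeSimulation round-trips through the standard formats", {
    dir <- withr::local_tempdir()
    sim <- smallSim(seed = 3L)
    sb <- simulateBulk(sim$sce, sim$truth, sim$params)
    lr <- simulateLRDatabase(sim$params, sim$sce, sb$truth)
    sv <- simulateSurvival(sb$bulk, sim$params, lr$truth)
    writeSimulation(dir, sce = sim$sce, bulk = sb$bulk, db = lr$db,
                    surv = sv$survival, truth = sv$truth)
    sce2 <- readCellMatrix(dir)
    expect_identical(dim(sce2), dim(sim$sce))
    expect_identical(SummarizedExperiment::colData(sce2)$label,
                     SummarizedExperiment::colData(sim$sce)$label)
    expect_equal(as.matrix(SummarizedExperiment::assay(sce2, "counts")),
                 as.matrix(SummarizedExperiment::assay(sim$sce, "counts")),
                 ignore_attr = TRUE)
    bulk2 <- readBulkMatrix(file.path(dir, "bulk.tsv"))
    expect_equal(as.matrix(SummarizedExperiment::assay(bulk2, 1)),
                 as.matrix(SummarizedExperiment::assay(sb$bulk, 1)),
                 tolerance = 1e-6)
    db2 <- readLRDatabase(file.path(dir, "lr_db.csv"))
    expect_equal(db2$ligand, lr$db$ligand)
    expect_equal(db2$secreted, lr$db$secreted)
    sv2 <- readSurvivalTable(file.path(dir, "survival.csv"))
    expect_equal(sv2$time, sv$survival$time, tolerance = 1e-6)
})
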