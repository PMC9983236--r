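normBulk <- function(m) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = m))
    S4Vectors::metadata(se)$normalized <- TRUE
    se
}

test_that("estimateAbundance averages log2 signature expression", {
    m <- matrix(3, 5, 4, dimnames = list(paste0("g", 1:5),
                                         paste0("s", 1:4)))
    sigs <- new("SignatureSet",
                signatures = list(A = c("g1", "g2"), B = c("g3", "gX")),
                markers = S4Vectors::DataFrame(),
                thresholds = list(minPct = 0.25, minLog2fc = 0.5,
                                  maxGenes = Inf))
    expect_warning(ab <- estimateAbundance(normBulk(m), sigs), "missing")
    expect_equal(unname(ab["A", ]), rep(2, 4))     # log2(3 + 1)
    expect_equal(unname(ab["B", ]), rep(2, 4))     # gX dropped
    sigsBad <- new("SignatureSet",
                   signatures = list(A = c("gY", "gZ")),
                   markers = S4Vectors::DataFrame(),
                   thresholds = list(minPct = 0.25, minLog2fc = 0.5,
                                     maxGenes = Inf))
    expect_error(estimateAbundance(normBulk(m), sigsBad), "'A'")
})

test_that("correlateGenes hits the self-correlation extremes", {
    set.seed(5)
    ab <- matrix(runif(2 * 10, 0, 1), 2, 10,
                 dimnames = list(c("A", "B"), paste0("s", 1:10)))
    m <- matrix(rexp(4 * 10), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
    m[1, ] <- 2^ab["A", ] - 1            # log2(x+1) equals abundance row
    m[2, ] <- 2^(2 - ab["A", ]) - 1      # log2(x+1) = 2 - abundance row
    m[3, ] <- 1                                      # constant
    r <- correlateGenes(normBulk(m), ab)
    expect_equal(r["g1", "A"], 1, tolerance = 1e-12)
    expect_equal(r["g2", "A"], -1, tolerance = 1e-12)
    expect_equal(r["g3", "A"], 0)
    expect_true("g3" %in% attr(r, "undefined"))
    expect_error(correlateGenes(normBulk(m[, 1:2]), ab[, 1:2]), "3 samples")
})

test_that("selectCandidateGenes removes self-expressed genes, strict bound", {
    ln <- matrix(0.2, 10, 20, dimnames = list(sprintf("g%02d", 1:10), NULL))
    labels <- rep(c("A", "B"), each = 10)
    ln["g01", labels == "A"] <- 1.5     # self for A: mean 1.5 > 1, freq 1
    ln["g02", labels == "A"] <- 1.0     # mean exactly 1: NOT self
    sce <- makeSCE(ln, labels)
    r <- matrix(seq(1, 0.1, length.out = 10), 10, 2,
                dimnames = list(rownames(ln), c("A", "B")))
    got <- selectCandidateGenes(r, sce, "A", k = 5)
    expect_false("g01" %in% got)
    expect_equal(got[1], "g02")                       # kept despite mean 1.0
    expect_equal(attr(got, "selfExcluded"), "g01")
    expect_length(selectCandidateGenes(r, sce, "A", k = 3), 3)
    expect_warning(selectCandidateGenes(r, sce, "A", k = 50), "only")
    expect_error(selectCandidateGenes(r, sce, "Z", k = 5), "'Z'")
})

test_that("enrichment z-scores use the sample sd and flag degeneracy", {
    # per-type means of the gene set engineered to (2, 0, 0, 0, 0)
    ln <- matrix(0, 4, 50, dimnames = list(paste0("g", 1:4), NULL))
    labels <- rep(paste0("T", 1:5), each = 10)
    ln[1:2, labels == "T1"] <- 2
    ln[3:4, ] <- 0.7                                   # constant genes
    sce <- makeSCE(ln, labels)
    z <- enrichmentZscores(sce, c("g1", "g2"))
    expect_equal(unname(z["T1"]), 1.6 / sd(c(2, 0, 0, 0, 0)),
                 tolerance = 1e-12)
    expect_equal(unname(z["T1"]), 1.78885438, tolerance = 1e-6)
    expect_gt(z["T1"], 1.28)
    expect_lt(abs(mean(z)), 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
    zd <- enrichmentZscores(sce, c("g3", "g4"))
    expect_true(all(zd == 0))
    expect_true(attr(zd, "degenerate"))
    # permuting type order permutes z identically
    perm <- c(31:50, 1:30)
    z2 <- enrichmentZscores(makeSCE(ln[, perm], labels[perm]), c("g1", "g2"))
    expect_equal(z2[names(z)], z, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("buildNetwork applies the strict 1.28 rule and mutual maximum", {
    types <- paste0("T", 1:3)
    z <- matrix(0, 3, 3, dimnames = list(types, types))
    z["T1", "T2"] <- 1.5; z["T2", "T1"] <- 2.0     # mutual: max chosen
    z["T1", "T3"] <- 1.28                           # exactly at threshold
    z["T2", "T3"] <- 1.5; z["T3", "T2"] <- 0.2     # one-directional
    net <- buildNetwork(z, degenerate = setNames(rep(TRUE, 3), types))
    ed <- as.data.frame(edges(net))
    e12 <- ed[ed$typeA == "T1" & ed$typeB == "T2", ]
    expect_equal(e12$weight, 2.0)
    expect_false(any(ed$typeA == "T1" & ed$typeB == "T3"))
    e23 <- ed[ed$typeA == "T2" & ed$typeB == "T3", ]
    expect_equal(e23$weight, 1.5)
    netM <- buildNetwork(z, mutualOnly = TRUE,
                         degenerate = setNames(rep(TRUE, 3), types))
    edM <- as.data.frame(edges(netM))
    expect_equal(nrow(edM), 1)
    expect_equal(edM$weight, 2.0)
})

test_that("hubRanking orders by degree, weighted degree, then id", {
    types <- paste0("T", 1:4)
    z <- matrix(0, 4, 4, dimnames = list(types, types))
    z["T2", "T1"] <- 2.0; z["T3", "T1"] <- 1.5; z["T4", "T1"] <- 1.6
    net <- buildNetwork(z, degenerate = setNames(rep(TRUE, 4), types))
    hr <- as.data.frame(hubRanking(net))
    expect_equal(hr$type[1], "T1")                  # star center
    expect_equal(hr$degree[1], 3)
    expect_equal(hr$type[2], "T2")                  # ties by weighted degree
    empty <- buildNetwork(matrix(0, 4, 4, dimnames = list(types, types)),
                          degenerate = setNames(rep(TRUE, 4), types))
    hrE <- as.data.frame(hubRanking(empty))
    expect_equal(hrE$type, types)                   # lexical on all-zero
    expect_true(all(hrE$degree == 0))
})

test_that("pure-mixture samples rank their own type's abundance first", {
    ok <- vapply(1:3, function(s) {
        sp <- simParams(seed = 600L + s)
        sim <- simulateCells(sp)
        sce <- logNormalize(qcFilter(sim$sce, minGenesPerCell = 50,
                                     minCellsPerGene = 3))
        sigs <- buildSignatures(findMarkers(sce))
        lab <- SummarizedExperiment::colData(sim$sce)$label
        cnt <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
        prof <- vapply(sort(unique(lab)), function(t)
            rowMeans(cnt[, lab == t, drop = FALSE]), numeric(nrow(cnt)))
        ab <- estimateAbundance(normBulk(prof), sigs)
        all(vapply(colnames(prof), function(t)
            names(which.max(ab[, t])) == t, TRUE))
    }, TRUE)
    expect_true(all(ok))
})

test_that("candidate lists never intersect the self-excluded genes", {
    sim <- smallSim(seed = 77L)
    sce <- logNormalize(qcFilter(sim$sce, minGenesPerCell = 50,
                                 minCellsPerGene = 3))
    sigs <- buildSignatures(findMarkers(sce))
    sb <- simulateBulk(sim$sce, sim$truth, sim$params)
    net <- suppressWarnings(
        runCooccurrence(normalizeBulk(sb$bulk), sce, sigs))
    for (t in names(candidateGenes(net)))
        expect_length(intersect(candidateGenes(net)[[t]],
                                net@selfExcluded[[t]]), 0)
    # z rows standardized unless degenerate (validity re-checked here)
    z <- zScores(net)
    for (i in seq_len(nrow(z))) if (!net@degenerate[i]) {
        expect_lt(abs(mean(z[i, ])), 1e-10)
        expect_lt(abs(sd(z[i, ]) - 1), 1e-10)
    }
})
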