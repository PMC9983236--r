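# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (enumeration, direct formula evaluation) and share no
# code with the implementation paths they check.

# SingleCellExperiment from an explicit log-normalized matrix (+ labels).
# A counts assay is synthesized as expm1(logcounts) so accessors relying on
# counts keep working.
makeSCE <- function(logcounts, labels) {
    if (is.null(rownames(logcounts)))
        rownames(logcounts) <- sprintf("g%03d", seq_len(nrow(logcounts)))
    if (is.null(colnames(logcounts)))
        colnames(logcounts) <- sprintf("c%03d", seq_len(ncol(logcounts)))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = expm1(logcounts), logcounts = logcounts),
        colData = S4Vectors::DataFrame(label = labels,
                                       row.names = colnames(logcounts)))
}

# All distinct orderings of a label vector, as a list of character vectors.
allLabelOrderings <- function(labels) {
    rec <- function(lab) {
        if (length(lab) <= 1) return(list(lab))
        out <- list()
        for (u in unique(lab)) {
            i <- which(lab == u)[1]
            for (tail in rec(lab[-i])) out[[length(out) + 1]] <- c(u, tail)
        }
        out
    }
    rec(labels)
}

# Brute-force exact permutation p-value for one (donor, acceptor, L-R pair):
# mean of ligand's donor-cluster mean and receptor's acceptor-cluster mean,
# null from every distinct labelling of the cells.
bruteForceLRP <- function(ln, labels, ligand, receptor, donor, acceptor) {
    statOf <- function(lab) {
        (mean(ln[ligand, lab == donor]) +
         mean(ln[receptor, lab == acceptor])) / 2
    }
    obs <- statOf(labels)
    null <- vapply(allLabelOrderings(labels), statOf, 0)
    mean(null >= obs)
}

# Direct product-limit evaluation: S(t) at each distinct observed time.
productLimitOracle <- function(time, event) {
    ut <- sort(unique(time))
    surv <- numeric(length(ut))
    s <- 1
    for (i in seq_along(ut)) {
        atRisk <- sum(time >= ut[i])
        d <- sum(time == ut[i] & event == 1)
        if (atRisk > 0) s <- s * (1 - d / atRisk)
        surv[i] <- s
    }
    list(time = ut, surv = surv)
}

# Small planted simulation shared by several module tests.
smallSim <- function(seed = 1L, ...) {
    sp <- simParams(nGenes = 300, nCellTypes = 4, cellsPerType = 40,
                    markersPerType = 10, nBulkSamples = 60, seed = seed, ...)
    sim <- simulateCells(sp)
    list(params = sp, sce = sim$sce, truth = sim$truth)
}
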