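# Gene-set scoring: per-cell binned-control module scores (set mean minus
# bin-matched control mean, after Tirosh et al. 2016) and single-sample
# rank-based enrichment (ssGSEA), with cross-group z-normalization for
# heatmap-style summaries.

#' Binned-control module score per cell
#'
#' Genes are binned into `nBins` equal-frequency bins by their average
#' log-normalized expression; for each gene-set gene, `nCtrl` control genes
#' are sampled with replacement from its bin. The score of a cell is the
#' mean expression of the gene set minus the mean expression of the pooled
#' control genes, so a global additive shift of the matrix cancels exactly.
#'
#' @param sce single-cell object with `logcounts` (>= `nBins` genes).
#' @param genes the gene set; genes missing from the matrix are dropped with
#'   a warning, an empty intersection is an error.
#' @param nBins number of average-expression bins (default 24).
#' @param nCtrl control genes sampled per gene-set gene (default 100).
#' @param seed seed for control sampling.
#' @return named per-cell numeric score vector.
#' @export
moduleScore <- function(sce, genes, nBins = 24, nCtrl = 100, seed = 1L) {
    ln <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    if (nrow(ln) < nBins)
        stop("matrix has fewer genes (", nrow(ln), ") than bins (", nBins,
             ")")
    found <- intersect(genes, rownames(ln))
    if (!length(found)) stop("no gene-set gene present in the matrix")
    if (length(found) < length(genes))
        warning(length(genes) - length(found),
                " gene-set gene(s) missing from the matrix; dropped")
    avg <- rowMeans(ln)
    bin <- cut(rank(avg, ties.method = "first"), breaks = nBins,
               labels = FALSE)
    byBin <- split(seq_len(nrow(ln)), bin)
    setIdx <- match(found, rownames(ln))
    withSeed(seed, {
        ctrlIdx <- unlist(lapply(setIdx, function(i) {
            pool <- byBin[[as.character(bin[i])]]
            pool[sample.int(length(pool), nCtrl, replace = TRUE)]
        }), use.names = FALSE)
    })
    colMeans(ln[setIdx, , drop = FALSE]) -
        colMeans(ln[ctrlIdx, , drop = FALSE])
}

#' Single-sample gene-set enrichment (ssGSEA) score
#'
#' Genes are ranked by expression descending (ties broken by gene id for
#' determinism); the score is the sum over ranks of the difference between
#' the weighted in-set ECDF (weights `rank^alpha`, top gene carrying the
#' largest rank) and the unweighted out-of-set ECDF, divided by the number
#' of genes to bound the scale. Depends on the expression values only
#' through their ranks.
#'
#' @param values named per-gene expression of one cell or pseudobulk group.
#' @param genes the gene set; must be a strict nonempty subset of the named
#'   genes.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return the normalized enrichment score.
#' @export
ssgseaScore <- function(values, genes, alpha = 0.25) {
    if (is.null(names(values))) stop("'values' must be named by gene")
    inSetGenes <- intersect(genes, names(values))
    N <- length(values)
    if (!length(inSetGenes) || length(inSetGenes) == N)
        stop("gene set must be a strict, nonempty subset of the ranked genes")
    ord <- order(-values, names(values))
    inSet <- names(values)[ord] %in% inSetGenes
    w <- (N - seq_len(N) + 1)^alpha
    stepIn <- cumsum(w * inSet) / sum(w[inSet])
    stepOut <- cumsum(!inSet) / (N - length(inSetGenes))
    sum(stepIn - stepOut) / N
}

#' Score gene sets across cells or groups
#'
#' Applies [moduleScore()] (per cell, optionally averaged per group) or
#' [ssgseaScore()] (per cell, or per group pseudobulk formed as the mean
#' log-normalized profile) to a collection of gene sets.
#'
#' @param sce single-cell object with `logcounts`.
#' @param geneSets named list of gene vectors (e.g. from [readGMT()]).
#' @param method "module" or "ssgsea".
#' @param groupBy NULL for per-cell scores, or the name of a `colData`
#'   column (e.g. "label") to score/aggregate per group.
#' @param ... passed on to the scorer.
#' @return gene set x cell (or x group) score matrix with attribute
#'   `method`.
#' @export
scoreGeneSets <- function(sce, geneSets, method = c("module", "ssgsea"),
                          groupBy = NULL, ...) {
    method <- match.arg(method)
    ln <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    groups <- if (!is.null(groupBy))
        as.character(SummarizedExperiment::colData(sce)[[groupBy]])
    if (method == "module") {
        sc <- t(vapply(geneSets, function(g) moduleScore(sce, g, ...),
                       numeric(ncol(ln))))
        rownames(sc) <- names(geneSets)
        if (!is.null(groups)) {
            lev <- sort(unique(groups))
            sc <- vapply(lev, function(g)
                rowMeans(sc[, groups == g, drop = FALSE]),
                numeric(nrow(sc)))
            if (is.null(dim(sc)))
                sc <- matrix(sc, nrow = length(geneSets),
                             dimnames = list(names(geneSets), lev))
        }
    } else {
        prof <- if (is.null(groups)) ln
        else vapply(sort(unique(groups)), function(g)
            rowMeans(ln[, groups == g, drop = FALSE]), numeric(nrow(ln)))
        sc <- t(vapply(geneSets, function(gset)
            apply(prof, 2, function(v)
                ssgseaScore(stats::setNames(v, rownames(ln)), gset, ...)),
            numeric(ncol(prof))))
        rownames(sc) <- names(geneSets)
    }
    attr(sc, "method") <- method
    sc
}

#' Z-normalize gene-set scores across groups
#'
#' Per gene set (row), subtracts the mean over groups and divides by the
#' sample standard deviation; rows with zero variance are set to 0 and
#' flagged in `attr(, "degenerate")`.
#'
#' @param scores gene set x group score matrix (>= 2 groups).
#' @return z-scored matrix of the same shape.
#' @export
zscoreAcrossGroups <- function(scores) {
    if (ncol(scores) < 2) stop("need at least 2 groups")
    mu <- rowMeans(scores)
    s <- apply(scores, 1, stats::sd)
    degen <- s == 0
    z <- (scores - mu) / ifelse(degen, 1, s)
    z[degen, ] <- 0
    attr(z, "degenerate") <- stats::setNames(degen, rownames(scores))
    z
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then genes, tab-separated).
#' @return named list of unique gene vectors.
#' @export
readGMT <- function(path) {
    lines <- strsplit(readLines(path), "\t")
    sets <- lapply(lines, function(x) unique(x[-(1:2)]))
    names(sets) <- vapply(lines, `[`, "", 1L)
    sets[lengths(sets) > 0]
}
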