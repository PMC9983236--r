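# Correlative cell-type co-occurrence network from paired bulk and
# single-cell data. Five steps per focal type: (1) signature-based abundance
# estimation in bulk, (2) gene-abundance Pearson correlation, (3) selection
# of the top correlated non-self-expressed genes, (4) enrichment of that gene
# set across all cell types with z-score transformation, (5) thresholding of
# directed hits (z > 1.28) into an undirected weighted network taking the
# maximum of mutual scores.

.assertNormalized <- function(bulk) {
    if (!isTRUE(S4Vectors::metadata(bulk)$normalized))
        warning("bulk matrix is not flagged as normalized; ",
                "run normalizeBulk() first")
}

#' Estimate cell-type abundance in bulk samples from signatures
#'
#' The relative abundance of a cell type in a bulk sample is the average over
#' its signature genes of `log2(normalized value + 1)`.
#'
#' @param bulk a normalized bulk
#'   [SummarizedExperiment::SummarizedExperiment].
#' @param sigs a [SignatureSet-class].
#' @return cell type x sample matrix of abundance scores; signature genes
#'   missing from bulk are dropped with a warning, an empty intersection for
#'   a type is an error.
#' @export
estimateAbundance <- function(bulk, sigs) {
    .assertNormalized(bulk)
    vals <- log2(as.matrix(SummarizedExperiment::assay(bulk, 1)) + 1)
    sg <- signatures(sigs)
    out <- matrix(NA_real_, length(sg), ncol(vals),
                  dimnames = list(names(sg), colnames(vals)))
    for (t in names(sg)) {
        genes <- sg[[t]]
        found <- intersect(genes, rownames(vals))
        if (!length(found))
            stop("no signature gene of cell type '", t,
                 "' is present in the bulk matrix")
        if (length(found) < length(genes))
            warning(length(genes) - length(found), " signature gene(s) of '",
                    t, "' missing from bulk; dropped")
        out[t, ] <- colMeans(vals[found, , drop = FALSE])
    }
    out
}

#' Correlate every bulk gene with every cell-type abundance profile
#'
#' Pearson correlation over samples between `log2(value + 1)` of each gene
#' and each abundance row. Genes with zero variance get r = 0 and are
#' recorded in `attr(, "undefined")`.
#'
#' @param bulk a normalized bulk
#'   [SummarizedExperiment::SummarizedExperiment] (>= 3 samples).
#' @param abundance cell type x sample matrix from [estimateAbundance()].
#' @return gene x cell type correlation matrix with attributes `undefined`
#'   (zero-variance genes) and `nSamples`.
#' @export
correlateGenes <- function(bulk, abundance) {
    vals <- log2(as.matrix(SummarizedExperiment::assay(bulk, 1)) + 1)
    if (ncol(vals) < 3) stop("need at least 3 samples for correlation")
    if (!identical(colnames(vals), colnames(abundance)))
        abundance <- abundance[, colnames(vals), drop = FALSE]
    sds <- apply(abundance, 1, stats::sd)
    if (any(sds == 0))
        stop("abundance row(s) with zero variance: ",
             paste(rownames(abundance)[sds == 0], collapse = ", "))
    geneSd <- apply(vals, 1, stats::sd)
    undef <- rownames(vals)[geneSd == 0]
    r <- suppressWarnings(stats::cor(t(vals), t(abundance)))
    r[geneSd == 0, ] <- 0
    attr(r, "undefined") <- undef
    attr(r, "nSamples") <- ncol(vals)
    r
}

.selfExpressed <- function(sce, cellType, exprMin, freqMin) {
    labels <- SummarizedExperiment::colData(sce)$label
    if (!cellType %in% labels)
        stop("cell type '", cellType, "' absent from single-cell labels")
    ln <- as.matrix(
        SummarizedExperiment::assay(sce, "logcounts"))[, labels == cellType,
                                                       drop = FALSE]
    meanExpr <- rowMeans(ln)
    frac <- rowMeans(ln > 0)
    rownames(ln)[meanExpr > exprMin & frac > freqMin]
}

#' Select a focal type's top correlated non-self-expressed genes
#'
#' A gene counts as self-expressed for the focal type when its mean
#' log-normalized expression over that type's cells is strictly above
#' `exprMin` AND its expressing-cell fraction there is strictly above
#' `freqMin` (so a mean of exactly `exprMin` does not exclude). Self genes
#' are removed, the rest ranked by their correlation with the focal type's
#' abundance, and the top `k` returned.
#'
#' @param corr gene x cell type matrix from [correlateGenes()].
#' @param sce single-cell object with `logcounts` and labels.
#' @param cellType the focal cell type.
#' @param exprMin mean-expression bound for the self filter (default 1.0).
#' @param freqMin expressing-fraction bound for the self filter
#'   (default 0.20).
#' @param k number of candidates to keep (default 20).
#' @param absCorr rank by |r| instead of signed r.
#' @return ordered character vector of candidate genes (fewer than `k` with
#'   a warning when not enough survive); `attr(, "selfExcluded")` lists the
#'   removed self-expressed genes.
#' @export
selectCandidateGenes <- function(corr, sce, cellType, exprMin = 1.0,
                                 freqMin = 0.20, k = 20, absCorr = FALSE) {
    shared <- intersect(rownames(corr), rownames(sce))
    self <- .selfExpressed(sce, cellType, exprMin, freqMin)
    undef <- attr(corr, "undefined")
    pool <- setdiff(shared, union(self, undef))
    r <- corr[pool, cellType]
    key <- if (absCorr) -abs(r) else -r
    ord <- pool[order(key, pool)]
    if (length(ord) < k)
        warning("only ", length(ord), " candidate genes available for '",
                cellType, "' (k = ", k, ")")
    out <- utils::head(ord, k)
    attr(out, "selfExcluded") <- intersect(self, shared)
    out
}

#' Enrichment z-scores of a gene set across cell types
#'
#' The enrichment of each cell type is the mean over the gene set of the
#' type's mean log-normalized expression; the enrichment vector is z-scored
#' across types using the sample standard deviation (denominator T - 1).
#'
#' @param sce single-cell object with `logcounts` and labels (>= 2 types).
#' @param genes nonempty gene list.
#' @return named z-score vector over cell types; when every type's
#'   enrichment is identical all z are 0 and `attr(, "degenerate")` is TRUE.
#' @export
enrichmentZscores <- function(sce, genes) {
    if (!length(genes)) stop("empty gene list")
    labels <- SummarizedExperiment::colData(sce)$label
    types <- sort(unique(labels))
    if (length(types) < 2) stop("need at least 2 cell types")
    ln <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    genes <- intersect(genes, rownames(ln))
    if (!length(genes)) stop("no gene of the list is present in the matrix")
    e <- vapply(types, function(t)
        mean(rowMeans(ln[genes, labels == t, drop = FALSE])), 0)
    s <- stats::sd(e)
    if (s == 0) {
        z <- stats::setNames(rep(0, length(e)), types)
        attr(z, "degenerate") <- TRUE
        return(z)
    }
    z <- (e - mean(e)) / s
    attr(z, "degenerate") <- FALSE
    z
}

#' Build the co-occurrence network from directed z-scores
#'
#' A directed hit i -> j (i != j) requires `z[i, j]` strictly above the
#' threshold. An undirected edge exists when at least one direction hits
#' (or both, with `mutualOnly`); its weight is the maximum of the two
#' directed scores when both hit, otherwise the single passing score.
#'
#' @param z directed cell type x cell type z matrix (rows = focal type).
#' @param threshold z cutoff, strictly exceeded (default 1.28).
#' @param mutualOnly require hits in both directions (default FALSE).
#' @param candidates,selfExcluded,degenerate optional per-type bookkeeping
#'   stored in the object (filled by [runCooccurrence()]).
#' @return a [CooccurrenceNetwork-class].
#' @export
buildNetwork <- function(z, threshold = 1.28, mutualOnly = FALSE,
                         candidates = list(), selfExcluded = list(),
                         degenerate = logical()) {
    types <- rownames(z)
    if (!length(degenerate))
        degenerate <- stats::setNames(rep(FALSE, length(types)), types)
    ta <- tb <- character(); w <- za <- zb <- numeric()
    for (i in seq_along(types)) for (j in seq_along(types)) {
        if (j <= i) next
        hij <- z[i, j] > threshold
        hji <- z[j, i] > threshold
        hit <- if (mutualOnly) hij && hji else hij || hji
        if (!hit) next
        ta <- c(ta, types[i]); tb <- c(tb, types[j])
        w <- c(w, if (hij && hji) max(z[i, j], z[j, i])
               else if (hij) z[i, j] else z[j, i])
        za <- c(za, z[i, j]); zb <- c(zb, z[j, i])
    }
    new("CooccurrenceNetwork", z = z, threshold = threshold,
        edges = S4Vectors::DataFrame(typeA = ta, typeB = tb, weight = w,
                                     zAB = za, zBA = zb),
        candidates = candidates, selfExcluded = selfExcluded,
        degenerate = degenerate)
}

#' Run the full co-occurrence pipeline
#'
#' Convenience wrapper chaining [estimateAbundance()], [correlateGenes()],
#' per-type [selectCandidateGenes()] and [enrichmentZscores()], and
#' [buildNetwork()].
#'
#' @param bulk normalized bulk matrix.
#' @param sce log-normalized, labelled single-cell object.
#' @param sigs [SignatureSet-class] (types must match the labels).
#' @param exprMin,freqMin,k,absCorr passed to [selectCandidateGenes()].
#' @param threshold,mutualOnly passed to [buildNetwork()].
#' @return a [CooccurrenceNetwork-class].
#' @export
runCooccurrence <- function(bulk, sce, sigs, exprMin = 1.0, freqMin = 0.20,
                            k = 20, absCorr = FALSE, threshold = 1.28,
                            mutualOnly = FALSE) {
    ab <- estimateAbundance(bulk, sigs)
    corr <- correlateGenes(bulk, ab)
    types <- rownames(ab)
    z <- matrix(NA_real_, length(types), length(types),
                dimnames = list(types, types))
    cand <- selfEx <- stats::setNames(vector("list", length(types)), types)
    degen <- stats::setNames(rep(FALSE, length(types)), types)
    for (t in types) {
        g <- selectCandidateGenes(corr, sce, t, exprMin = exprMin,
                                  freqMin = freqMin, k = k,
                                  absCorr = absCorr)
        zz <- enrichmentZscores(sce, g)
        z[t, names(zz)] <- zz
        degen[t] <- isTRUE(attr(zz, "degenerate"))
        cand[[t]] <- as.character(g)
        selfEx[[t]] <- attr(g, "selfExcluded")
    }
    buildNetwork(z, threshold = threshold, mutualOnly = mutualOnly,
                 candidates = cand, selfExcluded = selfEx,
                 degenerate = degen)
}

#' Write a network edge list to TSV
#'
#' @param net a [CooccurrenceNetwork-class].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeNetwork <- function(net, path) {
    utils::write.table(as.data.frame(edges(net)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
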