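# One-vs-rest marker detection by Wilcoxon rank-sum (normal approximation
# with tie correction) plus signature-set assembly under the strict
# pct/log2FC admission rules.

# Mann-Whitney U test per row of X between columns inIdx and the rest;
# normal approximation, tie-corrected, no continuity correction (matches
# wilcox.test(exact = FALSE, correct = FALSE)).
.wilcoxRows <- function(X, inIdx) {
    n <- ncol(X); n1 <- length(inIdx); n2 <- n - n1
    apply(X, 1, function(x) {
        r <- rank(x)
        U <- sum(r[inIdx]) - n1 * (n1 + 1) / 2
        ties <- table(x)
        sig2 <- n1 * n2 / 12 *
            ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        if (sig2 <= 0) return(1)
        z <- (U - n1 * n2 / 2) / sqrt(sig2)
        2 * stats::pnorm(-abs(z))
    })
}

#' Per-cluster marker genes by one-vs-rest Wilcoxon rank-sum
#'
#' For each cluster, genes are pre-filtered by the fraction of expressing
#' cells in the cluster (`pctIn >= minPct`) and log2 fold change
#' (`log2fc >= minLog2fc`) before testing; survivors are tested two-sided by
#' Wilcoxon rank-sum (normal approximation with tie correction) on the
#' log-normalized values and BH-adjusted within the cluster's tested set.
#' The fold change is `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`.
#' "Expressing" means log-normalized value > 0.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with `logcounts`
#'   and `colData()$label` (>= 2 clusters).
#' @param minPct minimum expressing fraction in the cluster (default 0.10).
#' @param minLog2fc minimum log2 fold change (default 0.5).
#' @return DataFrame with columns gene, cluster, log2fc, pctIn, pctOut, p,
#'   pAdj, one row per (cluster, tested gene), ordered by cluster then
#'   increasing pAdj. Clusters with fewer than 3 cells are skipped with a
#'   warning.
#' @export
findMarkers <- function(sce, minPct = 0.10, minLog2fc = 0.5) {
    ln <- SummarizedExperiment::assay(sce, "logcounts")
    labels <- SummarizedExperiment::colData(sce)$label
    if (is.null(labels)) stop("'sce' has no colData label column")
    clusters <- sort(unique(labels))
    if (length(clusters) < 2) stop("need at least 2 clusters")
    ln <- as.matrix(ln)
    expr <- ln > 0
    expm <- expm1(ln)
    out <- list()
    for (cl in clusters) {
        inIdx <- which(labels == cl)
        if (length(inIdx) < 3) {
            warning("cluster '", cl, "' has fewer than 3 cells; skipped")
            next
        }
        outIdx <- which(labels != cl)
        pctIn <- rowMeans(expr[, inIdx, drop = FALSE])
        pctOut <- rowMeans(expr[, outIdx, drop = FALSE])
        mIn <- rowMeans(expm[, inIdx, drop = FALSE])
        mOut <- rowMeans(expm[, outIdx, drop = FALSE])
        log2fc <- log2((mIn + 1) / (mOut + 1))
        keep <- which(pctIn >= minPct & log2fc >= minLog2fc)
        if (!length(keep)) next
        p <- .wilcoxRows(ln[keep, , drop = FALSE], inIdx)
        res <- S4Vectors::DataFrame(
            gene = rownames(ln)[keep], cluster = cl,
            log2fc = unname(log2fc[keep]), pctIn = unname(pctIn[keep]),
            pctOut = unname(pctOut[keep]), p = unname(p),
            pAdj = unname(stats::p.adjust(p, "BH")))
        out[[cl]] <- res[order(res$pAdj, res$p, -res$log2fc), ]
    }
    if (!length(out))
        return(S4Vectors::DataFrame(gene = character(), cluster = character(),
                                    log2fc = numeric(), pctIn = numeric(),
                                    pctOut = numeric(), p = numeric(),
                                    pAdj = numeric()))
    do.call(rbind, unname(out))
}

#' Assemble cell-type signature sets from marker records
#'
#' Admits, per cluster, the markers with expressing fraction strictly above
#' `minPct` and log2 fold change strictly above `minLog2fc` (both boundaries
#' excluded), ordered by decreasing log2 fold change and truncated to
#' `maxGenes` when set.
#'
#' @param markers DataFrame from [findMarkers()].
#' @param minPct strict lower bound on the expressing fraction
#'   (default 0.25).
#' @param minLog2fc strict lower bound on log2 fold change (default 0.5).
#' @param maxGenes optional cap per type (highest fold changes kept).
#' @return a [SignatureSet-class].
#' @export
buildSignatures <- function(markers, minPct = 0.25, minLog2fc = 0.5,
                            maxGenes = Inf) {
    keep <- markers$pctIn > minPct & markers$log2fc > minLog2fc
    adm <- markers[keep, , drop = FALSE]
    types <- sort(unique(markers$cluster))
    sigs <- list()
    rows <- list()
    for (t in types) {
        sub <- adm[adm$cluster == t, , drop = FALSE]
        if (!nrow(sub))
            stop("cell type '", t, "' has no genes passing the signature ",
                 "thresholds (pct_in > ", minPct, ", log2FC > ", minLog2fc,
                 ")")
        sub <- sub[order(-sub$log2fc, sub$gene), , drop = FALSE]
        if (is.finite(maxGenes) && nrow(sub) > maxGenes)
            sub <- sub[seq_len(maxGenes), , drop = FALSE]
        sigs[[t]] <- sub$gene
        rows[[t]] <- sub
    }
    new("SignatureSet", signatures = sigs, markers = do.call(rbind, rows),
        thresholds = list(minPct = minPct, minLog2fc = minLog2fc,
                          maxGenes = maxGenes))
}
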