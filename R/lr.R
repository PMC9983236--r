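# Ligand-receptor interaction scoring between annotated clusters with a
# cell-label permutation null (CellPhoneDB-style mean-of-cluster-means
# statistic), the secreted / P < 0.05 filter, the sqrt(mean(m1 x m2 + 1))
# display statistic, and the cluster-pair interaction-strength matrix.

#' Per-cluster mean expression and expressing fraction
#'
#' @param sce single-cell object with `logcounts` and labels.
#' @param minExprFrac a gene expressed in less than this fraction of a
#'   cluster's cells is masked (treated as not expressed) there.
#' @return list of gene x cluster matrices `mean`, `frac` and logical
#'   `masked` (`frac < minExprFrac`).
#' @export
clusterMeans <- function(sce, minExprFrac = 0.10) {
    ln <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    labels <- SummarizedExperiment::colData(sce)$label
    clusters <- sort(unique(labels))
    if (any(table(labels) == 0)) stop("empty cluster")
    mn <- vapply(clusters, function(cl)
        rowMeans(ln[, labels == cl, drop = FALSE]), numeric(nrow(ln)))
    fr <- vapply(clusters, function(cl)
        rowMeans(ln[, labels == cl, drop = FALSE] > 0), numeric(nrow(ln)))
    list(mean = mn, frac = fr, masked = fr < minExprFrac)
}

#' Mean interaction statistic of a ligand-receptor pair
#'
#' @param ligandMean,receptorMean cluster-mean expression of the ligand in
#'   the donor cluster and the receptor in the acceptor cluster; `NA` when
#'   masked, in which case the pair is skipped (returns `NA`), never scored
#'   as 0.
#' @return `(ligandMean + receptorMean) / 2`, or `NA` on masked input.
#' @export
lrMeanStat <- function(ligandMean, receptorMean) {
    if (is.na(ligandMean) || is.na(receptorMean)) return(NA_real_)
    (ligandMean + receptorMean) / 2
}

#' Display statistic sqrt(mean(ligand x receptor + 1))
#'
#' Cells of the two clusters are paired by resampling each side with
#' replacement to the larger cluster size (a full cross product is
#' quadratic); the statistic is the square root of the mean of
#' `ligand x receptor + 1` over the paired cells.
#'
#' @param ligandCells per-cell ligand values in the donor cluster.
#' @param receptorCells per-cell receptor values in the acceptor cluster.
#' @param seed seed for the resampled pairing.
#' @return the display statistic (>= 1).
#' @export
lrDisplayStat <- function(ligandCells, receptorCells, seed = 1L) {
    if (!length(ligandCells) || !length(receptorCells))
        stop("empty cell vector")
    m <- max(length(ligandCells), length(receptorCells))
    withSeed(seed, {
        a <- ligandCells[sample.int(length(ligandCells), m, replace = TRUE)]
        b <- receptorCells[sample.int(length(receptorCells), m,
                                      replace = TRUE)]
    })
    sqrt(mean(a * b + 1))
}

# All distinct assignments of a label multiset to positions, as an
# n x nAssignments integer matrix of class indices. Errors above `cap`.
.allAssignments <- function(labels, cap = 1e5) {
    f <- factor(labels)
    counts <- as.integer(table(f))
    total <- exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
    if (total > cap)
        stop("exhaustive enumeration would need ", format(total),
             " assignments (cap ", cap, ")")
    gen <- function(cnt) {
        n <- sum(cnt)
        if (n == 0L) return(matrix(integer(0), nrow = 0, ncol = 1))
        res <- NULL
        for (i in which(cnt > 0L)) {
            c2 <- cnt; c2[i] <- c2[i] - 1L
            sub <- gen(c2)
            res <- cbind(res, rbind(rep(i, ncol(sub)), sub))
        }
        res
    }
    out <- gen(counts)
    attr(out, "levels") <- levels(f)
    out
}

#' Permutation test for cluster-specific ligand-receptor interaction
#'
#' For every ordered cluster pair (donor A, acceptor B) and database pair,
#' the observed statistic is the mean of the ligand's cluster-A mean and the
#' receptor's cluster-B mean (log-normalized scale); pairs whose ligand is
#' masked in A or receptor masked in B (expressing fraction below
#' `minExprFrac` in the observed data) are skipped. The null shuffles cell
#' labels (same label multiset) `nPerm` times and recomputes; the p-value is
#' the plain proportion of null statistics >= observed (add-one correction
#' with `plusOne = TRUE`). With `exhaustive = TRUE` all distinct label
#' assignments are enumerated instead, making p exact.
#'
#' @param sce single-cell object with `logcounts` and labels (>= 2 clusters).
#' @param db DataFrame (pair, ligand, receptor, secreted) as returned by
#'   [readLRDatabase()] or [simulateLRDatabase()].
#' @param nPerm number of label permutations (ignored when exhaustive).
#' @param seed seed controlling the permutation stream and the display-stat
#'   pairing.
#' @param minExprFrac masking threshold, see [clusterMeans()].
#' @param exhaustive enumerate all distinct label assignments.
#' @param plusOne use the conservative (b + 1) / (n + 1) p-value.
#' @return an [LRResult-class]; skipped (masked) combinations carry no row.
#' @export
lrPermutationTest <- function(sce, db, nPerm = 1000, seed = 1L,
                              minExprFrac = 0.10, exhaustive = FALSE,
                              plusOne = FALSE) {
    if (!exhaustive && nPerm < 1) stop("'nPerm' must be >= 1")
    labels <- SummarizedExperiment::colData(sce)$label
    clusters <- sort(unique(labels))
    if (length(clusters) < 2) stop("need at least 2 clusters")
    genes <- unique(c(db$ligand, db$receptor))
    present <- genes %in% rownames(sce)
    if (!all(present)) {
        bad <- db$ligand %in% genes[!present] |
            db$receptor %in% genes[!present]
        warning(sum(bad), " pair(s) dropped: gene(s) absent from matrix")
        db <- db[!bad, , drop = FALSE]
    }
    genes <- unique(c(db$ligand, db$receptor))
    X <- as.matrix(SummarizedExperiment::assay(sce, "logcounts")[genes, ,
                                                                 drop = FALSE])
    cm <- clusterMeans(sce, minExprFrac = minExprFrac)
    obsMean <- cm$mean[genes, clusters, drop = FALSE]
    masked <- cm$masked[genes, clusters, drop = FALSE]
    K <- length(clusters)
    labIdx <- match(labels, clusters)
    sizes <- tabulate(labIdx, K)

    withSeed(seed, {
        if (exhaustive) {
            assigns <- .allAssignments(labels)
            P <- ncol(assigns)
        } else {
            P <- as.integer(nPerm)
            assigns <- vapply(seq_len(P), function(p) sample(labIdx),
                              integer(length(labIdx)))
        }
        # one sparse cell x (cluster, perm) membership matrix: null cluster
        # means for every permutation in a single product
        n <- length(labIdx)
        ind <- Matrix::sparseMatrix(
            i = rep(seq_len(n), P),
            j = as.integer(assigns) + rep((seq_len(P) - 1L) * K, each = n),
            x = 1 / sizes[as.integer(assigns)], dims = c(n, K * P))
        nulls <- array(as.matrix(X %*% ind), c(length(genes), K, P))
        pairIdx <- lapply(clusters, function(cl) which(labels == cl))
        names(pairIdx) <- clusters
        dispIdx <- list()
        for (a in clusters) for (b in clusters) {
            m <- max(sizes[match(a, clusters)], sizes[match(b, clusters)])
            dispIdx[[paste(a, b, sep = "\r")]] <- list(
                a = pairIdx[[a]][sample.int(length(pairIdx[[a]]), m,
                                            replace = TRUE)],
                b = pairIdx[[b]][sample.int(length(pairIdx[[b]]), m,
                                            replace = TRUE)])
        }
    })
    gi <- match(db$ligand, genes); ri <- match(db$receptor, genes)
    nMax <- K * K * nrow(db)
    cA <- cB <- pr <- lg <- rc <- character(nMax)
    ms <- ds <- pv <- numeric(nMax); sec <- logical(nMax)
    ri2 <- 0L
    for (ai in seq_len(K)) for (bi in seq_len(K)) {
        a <- clusters[ai]; b <- clusters[bi]
        dI <- dispIdx[[paste(a, b, sep = "\r")]]
        nullA <- nulls[, ai, , drop = FALSE]
        nullB <- nulls[, bi, , drop = FALSE]
        for (q in seq_len(nrow(db))) {
            if (masked[gi[q], ai] || masked[ri[q], bi]) next
            obs <- (obsMean[gi[q], ai] + obsMean[ri[q], bi]) / 2
            null <- (nullA[gi[q], 1, ] + nullB[ri[q], 1, ]) / 2
            # relative tolerance so the observed labelling (and exact ties)
            # count as >= despite order-of-summation rounding
            bGE <- sum(null >= obs - 1e-12 * max(1, abs(obs)))
            ri2 <- ri2 + 1L
            cA[ri2] <- a; cB[ri2] <- b; pr[ri2] <- db$pair[q]
            lg[ri2] <- db$ligand[q]; rc[ri2] <- db$receptor[q]
            ms[ri2] <- obs
            ds[ri2] <- sqrt(mean(X[gi[q], dI$a] * X[ri[q], dI$b] + 1))
            pv[ri2] <- if (plusOne) (bGE + 1) / (P + 1) else bGE / P
            sec[ri2] <- db$secreted[q]
        }
    }
    keep <- seq_len(ri2)
    tab <- S4Vectors::DataFrame(
        clusterA = cA[keep], clusterB = cB[keep], pair = pr[keep],
        ligand = lg[keep], receptor = rc[keep], meanStat = ms[keep],
        displayStat = ds[keep], p = pv[keep], secreted = sec[keep],
        significant = rep(NA, ri2))
    new("LRResult", table = tab, clusters = clusters, nPerm = as.integer(P),
        exhaustive = exhaustive, seed = as.integer(seed))
}

#' Filter ligand-receptor results to significant interactions
#'
#' Keeps rows with `p` strictly below `alpha` and, by default, a secreted
#' ligand-receptor pair.
#'
#' @param res an [LRResult-class].
#' @param alpha significance level (strict `<`; default 0.05).
#' @param requireSecreted also require the secreted flag (default TRUE).
#' @return an [LRResult-class] containing only the retained rows, with the
#'   `significant` column set to TRUE.
#' @export
filterSignificant <- function(res, alpha = 0.05, requireSecreted = TRUE) {
    tb <- lrTable(res)
    keep <- tb$p < alpha & (tb$secreted | !requireSecreted)
    tb <- tb[keep, , drop = FALSE]
    tb$significant <- rep(TRUE, nrow(tb))
    methods::initialize(res, table = tb)
}

#' Cluster-pair interaction-strength matrix
#'
#' Counts significant pairs per ordered (donor, acceptor) cluster pair; the
#' symmetric summary adds the transpose.
#'
#' @param res a filtered [LRResult-class] (significance flags set).
#' @return list with `strength` (donor x acceptor count matrix) and
#'   `symmetric` (`strength + t(strength)`).
#' @export
interactionStrength <- function(res) {
    tb <- lrTable(res)
    cl <- res@clusters
    m <- matrix(0L, length(cl), length(cl), dimnames = list(cl, cl))
    sig <- tb[!is.na(tb$significant) & tb$significant, , drop = FALSE]
    if (nrow(sig)) {
        cnt <- table(factor(sig$clusterA, cl), factor(sig$clusterB, cl))
        m <- m + unclass(cnt)
    }
    list(strength = m, symmetric = m + t(m))
}
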