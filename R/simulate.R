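# Synthetic paired single-cell / bulk generator with planted ground truth.
#
# The single-cell model draws negative-binomial counts around per-type mean
# profiles; each type's planted markers have their mean multiplied by
# `markerFold` in that type only. Bulk samples are noisy mixtures of the
# empirical per-type mean profiles with logistic-normal mixing proportions
# whose latent Gaussian carries a user-specified correlation structure, so
# cell-type co-occurrence can be planted and later recovered.

#' Evaluate an expression under a temporary RNG state
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`; the caller's RNG state is restored afterwards.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Nearest positive-semidefinite repair of a correlation matrix
#'
#' Eigenvalues below `tol` are clipped to `tol`, the matrix is reconstructed
#' and rescaled back to unit diagonal. If the most negative eigenvalue is
#' below `-maxRepair` the matrix is considered indefinite beyond repair.
#'
#' @keywords internal
#' @noRd
nearestPSD <- function(x, tol = 1e-8, maxRepair = 0.1) {
    eg <- eigen((x + t(x)) / 2, symmetric = TRUE)
    if (min(eg$values) < -maxRepair)
        stop("'proportionCorr' is not positive semidefinite beyond the ",
             "repair tolerance (smallest eigenvalue ",
             format(min(eg$values), digits = 4), ")")
    if (min(eg$values) >= tol) return((x + t(x)) / 2)
    lam <- pmax(eg$values, tol)
    y <- eg$vectors %*% (lam * t(eg$vectors))
    d <- 1 / sqrt(diag(y))
    y <- y * tcrossprod(d)
    diag(y) <- 1
    (y + t(y)) / 2
}

#' Construct simulation parameters
#'
#' Defaults describe a desk-scale tumor-microenvironment experiment: 1000
#' genes (the first 5% flagged mitochondrial, ids prefixed `MT-`), six
#' annotated cell types of 100 cells each, 25 planted markers per type at
#' four-fold mean elevation, shared NB dispersion 0.4, and 100 bulk samples
#' mixed with moderate compositional variability (logit sd 0.7) and 20%
#' multiplicative noise.
#'
#' @param nGenes,nCellTypes,cellsPerType,markersPerType counts.
#' @param markerFold mean multiplier for a type's markers in that type; 1
#'   plants no differential expression.
#' @param nbDispersion NB dispersion phi (variance mu + phi mu^2), shared
#'   across genes.
#' @param nBulkSamples number of bulk mixture samples.
#' @param proportionCorr symmetric correlation matrix (unit diagonal) for the
#'   latent Gaussian driving mixing proportions; defaults to identity.
#' @param propLogitSd sd of the latent Gaussian on the logit scale.
#' @param bulkNoiseCv CV of multiplicative lognormal noise on bulk values.
#' @param lrPairs number of ligand-receptor pairs in the simulated database.
#' @param plantedLR list of length-2 integer vectors (ligand cluster index,
#'   receptor cluster index) to receive cluster-specific pairs.
#' @param secretedFrac fraction of database pairs flagged secreted.
#' @param survivalEffectGenes genes whose standardized mean bulk expression
#'   multiplies the log hazard; empty means no planted effect.
#' @param survivalLogHR log hazard ratio per SD of the effect-gene score.
#' @param seed integer seed for all generator stages.
#' @return a validated [SimParams-class] object.
#' @examples
#' sp <- simParams(nCellTypes = 3, cellsPerType = 50, seed = 1)
#' sim <- simulateCells(sp)
#' table(SummarizedExperiment::colData(sim$sce)$label)
#' @export
simParams <- function(nGenes = 1000, nCellTypes = 6, cellsPerType = 100,
                      markersPerType = 25, markerFold = 4,
                      nbDispersion = 0.4, nBulkSamples = 100,
                      proportionCorr = diag(nCellTypes), propLogitSd = 0.7,
                      bulkNoiseCv = 0.2, lrPairs = 40, plantedLR = list(),
                      secretedFrac = 0.5, survivalEffectGenes = character(),
                      survivalLogHR = 0, seed = 1L) {
    obj <- new("SimParams",
               nGenes = as.integer(nGenes),
               nCellTypes = as.integer(nCellTypes),
               cellsPerType = as.integer(cellsPerType),
               markersPerType = as.integer(markersPerType),
               markerFold = as.numeric(markerFold),
               nbDispersion = as.numeric(nbDispersion),
               nBulkSamples = as.integer(nBulkSamples),
               proportionCorr = as.matrix(proportionCorr),
               propLogitSd = as.numeric(propLogitSd),
               bulkNoiseCv = as.numeric(bulkNoiseCv),
               lrPairs = as.integer(lrPairs),
               plantedLR = lapply(plantedLR, as.integer),
               secretedFrac = as.numeric(secretedFrac),
               survivalEffectGenes = as.character(survivalEffectGenes),
               survivalLogHR = as.numeric(survivalLogHR),
               seed = as.integer(seed))
    validObject(obj)
    obj
}

.typeNames <- function(k) sprintf("type%02d", seq_len(k))

#' Simulate an annotated single-cell count matrix
#'
#' Draws genes x cells negative-binomial counts around per-type mean
#' profiles. Baseline gene means are lognormal; each type's planted markers
#' (disjoint blocks of non-mitochondrial genes) have mean
#' `markerFold x baseline` in that type only. The first 5% of genes are
#' mitochondrial (`MT-` prefix) so QC filtering is exercised downstream.
#'
#' @param params a [SimParams-class] object.
#' @return list with `sce` (a [SingleCellExperiment::SingleCellExperiment]
#'   with assay `counts`, `colData(sce)$label` and `rowData(sce)$mito`) and
#'   `truth` (a [SimTruth-class] carrying labels and per-type marker lists).
#' @export
simulateCells <- function(params) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    G <- params@nGenes; Tn <- params@nCellTypes; n <- params@cellsPerType
    m <- params@markersPerType
    nMito <- ceiling(0.05 * G)
    if (m * Tn > G - nMito)
        stop("'markersPerType': ", m * Tn, " marker genes requested but only ",
             G - nMito, " non-mitochondrial genes available")
    w <- max(4, nchar(G))
    ids <- sprintf(paste0("G%0", w, "d"), seq_len(G))
    ids[seq_len(nMito)] <- paste0("MT-", ids[seq_len(nMito)])
    types <- .typeNames(Tn)
    withSeed(params@seed, {
        baseline <- stats::rlnorm(G, meanlog = log(0.5), sdlog = 1)
        mu <- matrix(baseline, G, Tn, dimnames = list(ids, types))
        markers <- vector("list", Tn); names(markers) <- types
        for (t in seq_len(Tn)) {
            idx <- nMito + (t - 1L) * m + seq_len(m)
            mu[idx, t] <- mu[idx, t] * params@markerFold
            markers[[t]] <- ids[idx]
        }
        counts <- matrix(0L, G, Tn * n)
        for (t in seq_len(Tn)) {
            counts[, (t - 1L) * n + seq_len(n)] <-
                stats::rnbinom(G * n, mu = mu[, t],
                               size = 1 / params@nbDispersion)
        }
    })
    labels <- rep(types, each = n)
    cellIds <- sprintf(paste0("cell%0", max(4, nchar(Tn * n)), "d"),
                       seq_len(Tn * n))
    dimnames(counts) <- list(ids, cellIds)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
        colData = S4Vectors::DataFrame(label = labels, row.names = cellIds),
        rowData = S4Vectors::DataFrame(
            mito = startsWith(ids, "MT-"), row.names = ids))
    truth <- new("SimTruth", trueLabels = stats::setNames(labels, cellIds),
                 trueMarkers = markers)
    list(sce = sce, truth = truth)
}

#' Simulate bulk samples as noisy mixtures of cell-type profiles
#'
#' Mixing proportions follow a logistic-normal model: a latent Gaussian with
#' correlation `proportionCorr` (nearest-PSD repaired by eigenvalue clipping)
#' and sd `propLogitSd` is passed through a softmax, so planted correlations
#' between cell-type proportions propagate (attenuated) to the simplex. Bulk
#' expression is the proportion-weighted sum of the empirical per-type mean
#' count profiles of `sce`, multiplied by lognormal noise with the configured
#' CV.
#'
#' @param sce annotated [SingleCellExperiment::SingleCellExperiment] from
#'   [simulateCells()].
#' @param truth [SimTruth-class] from [simulateCells()].
#' @param params the same [SimParams-class] used upstream.
#' @param edgeThreshold |latent correlation| above which an unordered type
#'   pair is recorded as a planted co-occurrence edge.
#' @return list with `bulk` (a
#'   [SummarizedExperiment::SummarizedExperiment], assay `values`,
#'   `metadata(bulk)$normalized = FALSE`) and the updated `truth` carrying
#'   `trueProportions` and `plantedEdges`.
#' @export
simulateBulk <- function(sce, truth, params, edgeThreshold = 0.2) {
    stopifnot(is(params, "SimParams"), is(truth, "SimTruth"))
    labels <- SummarizedExperiment::colData(sce)$label
    types <- .typeNames(params@nCellTypes)
    if (!all(types %in% labels))
        stop("'sce' lacks cells for some configured types")
    cnt <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
    profiles <- vapply(types, function(t) rowMeans(cnt[, labels == t,
                                                       drop = FALSE]),
                       numeric(nrow(cnt)))
    S <- params@nBulkSamples
    sigma <- nearestPSD(params@proportionCorr)
    eg <- eigen(sigma, symmetric = TRUE)
    L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(sigma))
    withSeed(params@seed + 1L, {
        zlat <- L %*% matrix(stats::rnorm(nrow(sigma) * S), nrow(sigma), S)
        logits <- params@propLogitSd * zlat
        ex <- exp(sweep(logits, 2, apply(logits, 2, max)))
        props <- sweep(ex, 2, colSums(ex), "/")
        sdlog <- sqrt(log(1 + params@bulkNoiseCv^2))
        noise <- matrix(stats::rlnorm(nrow(cnt) * S,
                                      meanlog = -sdlog^2 / 2, sdlog = sdlog),
                        nrow(cnt), S)
    })
    vals <- (profiles %*% props) * noise
    sampleIds <- sprintf("sample%03d", seq_len(S))
    dimnames(vals) <- list(rownames(cnt), sampleIds)
    dimnames(props) <- list(types, sampleIds)
    pc <- params@proportionCorr
    ii <- which(upper.tri(pc) & abs(pc) > edgeThreshold, arr.ind = TRUE)
    truth@trueProportions <- props
    truth@plantedEdges <- S4Vectors::DataFrame(
        typeA = types[ii[, 1]], typeB = types[ii[, 2]],
        latentCorr = pc[ii])
    truth@edgeThreshold <- edgeThreshold
    validObject(truth)
    bulk <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = vals))
    S4Vectors::metadata(bulk)$normalized <- FALSE
    list(bulk = bulk, truth = truth)
}

#' Simulate a ligand-receptor pair database with planted specificity
#'
#' Planted pairs take their ligand from the marker genes of the configured
#' ligand cluster and their receptor from those of the receptor cluster, so
#' both are genuinely up-regulated where the plant says. Decoy pairs use
#' baseline (uniformly expressed, non-marker, non-mitochondrial) genes.
#' Exactly `round(secretedFrac x lrPairs)` pairs are flagged secreted,
#' planted pairs first.
#'
#' @param params a [SimParams-class].
#' @param sce,truth outputs of [simulateCells()].
#' @return list with `db` (DataFrame: pair, ligand, receptor, secreted) and
#'   the updated `truth` carrying `plantedLRPairs`.
#' @export
simulateLRDatabase <- function(params, sce, truth) {
    stopifnot(is(params, "SimParams"), is(truth, "SimTruth"))
    nPairs <- params@lrPairs
    planted <- params@plantedLR
    if (length(planted) > nPairs)
        stop("more planted L-R pairs (", length(planted),
             ") than database pairs (", nPairs, ")")
    types <- .typeNames(params@nCellTypes)
    allGenes <- rownames(sce)
    markerGenes <- unlist(truth@trueMarkers, use.names = FALSE)
    pool <- setdiff(allGenes[!startsWith(allGenes, "MT-")], markerGenes)
    nDecoy <- nPairs - length(planted)
    if (2L * nDecoy > length(pool))
        stop("not enough uniformly expressed genes for ", nDecoy,
             " decoy pairs")
    used <- character()
    lig <- rec <- character(nPairs)
    ligCl <- recCl <- rep(NA_character_, nPairs)
    for (i in seq_along(planted)) {
        a <- types[planted[[i]][1]]; b <- types[planted[[i]][2]]
        la <- setdiff(truth@trueMarkers[[a]], used)
        rb <- setdiff(truth@trueMarkers[[b]], used)
        if (!length(la) || !length(rb))
            stop("marker genes of clusters ", a, "/", b,
                 " exhausted for planted pair ", i)
        lig[i] <- la[1]; used <- c(used, la[1])
        rec[i] <- rb[1]; used <- c(used, rec[i])
        ligCl[i] <- a; recCl[i] <- b
    }
    withSeed(params@seed + 2L, {
        decoyGenes <- sample(pool, 2L * nDecoy)
    })
    if (nDecoy > 0) {
        lig[length(planted) + seq_len(nDecoy)] <- decoyGenes[seq_len(nDecoy)]
        rec[length(planted) + seq_len(nDecoy)] <- decoyGenes[nDecoy +
                                                             seq_len(nDecoy)]
    }
    pairIds <- sprintf("LR%03d", seq_len(nPairs))
    nSecreted <- round(params@secretedFrac * nPairs)
    secreted <- seq_len(nPairs) <= nSecreted
    db <- S4Vectors::DataFrame(pair = pairIds, ligand = lig, receptor = rec,
                               secreted = secreted)
    if (length(planted)) {
        truth@plantedLRPairs <- S4Vectors::DataFrame(
            pair = pairIds[seq_along(planted)],
            ligandCluster = ligCl[seq_along(planted)],
            receptorCluster = recCl[seq_along(planted)],
            ligand = lig[seq_along(planted)],
            receptor = rec[seq_along(planted)])
    }
    list(db = db, truth = truth)
}

#' Simulate survival outcomes with a planted gene-signature hazard effect
#'
#' Event times are exponential with log hazard
#' `survivalLogHR x standardized mean log2 expression of the effect genes`;
#' censoring is independent uniform. With no effect genes (or log-HR 0) the
#' outcome is independent of expression, giving a calibrated null.
#'
#' @param bulk a bulk [SummarizedExperiment::SummarizedExperiment].
#' @param params a [SimParams-class].
#' @param truth optional [SimTruth-class] to update with latent hazard groups.
#' @param baselineHazard event rate at score 0 (default median time ~14).
#' @param censorMax upper end of the uniform censoring window.
#' @return list with `survival` (data.frame: sample, time, event) and `truth`
#'   (updated when supplied, otherwise a fresh SimTruth).
#' @export
simulateSurvival <- function(bulk, params, truth = NULL,
                             baselineHazard = log(2) / 20, censorMax = 60) {
    stopifnot(is(params, "SimParams"))
    if (is.null(truth)) truth <- new("SimTruth")
    vals <- SummarizedExperiment::assay(bulk, 1)
    genes <- params@survivalEffectGenes
    missing <- setdiff(genes, rownames(vals))
    if (length(missing))
        stop("survival effect gene(s) absent from bulk: ",
             paste(missing, collapse = ", "))
    n <- ncol(vals)
    if (length(genes)) {
        sc <- colMeans(log2(vals[genes, , drop = FALSE] + 1))
        score <- as.numeric(scale(sc))
    } else score <- numeric(n)
    withSeed(params@seed + 3L, {
        rate <- baselineHazard * exp(params@survivalLogHR * score)
        tEvent <- stats::rexp(n, rate = rate)
        tCens <- stats::runif(n, 0, censorMax)
    })
    surv <- data.frame(sample = colnames(vals),
                       time = pmin(tEvent, tCens),
                       event = as.integer(tEvent <= tCens))
    truth@survivalGroups <- stats::setNames(
        ifelse(score > stats::median(score), "High", "Low"), colnames(vals))
    list(survival = surv, truth = truth)
}

#' Write a simulated experiment to standard on-disk formats
#'
#' Writes MatrixMarket counts + `genes.tsv`/`barcodes.tsv`/`labels.tsv` for
#' the single-cell matrix, `bulk.tsv` (genes x samples), `lr_db.csv`
#' (ligand,receptor,secreted), `survival.csv` (sample,time,event) and
#' `truth.json`.
#'
#' @param dir output directory (created if needed).
#' @param sce,bulk,db,surv,truth simulation outputs; any may be NULL to skip.
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(dir, sce = NULL, bulk = NULL, db = NULL,
                            surv = NULL, truth = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    if (!is.null(sce)) {
        m <- methods::as(SummarizedExperiment::assay(sce, "counts"),
                         "CsparseMatrix")
        p <- file.path(dir, "matrix.mtx")
        Matrix::writeMM(m, p)
        writeLines(rownames(sce), file.path(dir, "genes.tsv"))
        writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
        utils::write.table(
            data.frame(cell_id = colnames(sce),
                       label = SummarizedExperiment::colData(sce)$label),
            file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        paths <- c(paths, p)
    }
    if (!is.null(bulk)) {
        p <- file.path(dir, "bulk.tsv")
        utils::write.table(
            data.frame(gene = rownames(bulk),
                       as.data.frame(SummarizedExperiment::assay(bulk, 1)),
                       check.names = FALSE),
            p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
    }
    if (!is.null(db)) {
        p <- file.path(dir, "lr_db.csv")
        utils::write.csv(as.data.frame(db)[, c("ligand", "receptor",
                                               "secreted")],
                         p, row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
    }
    if (!is.null(surv)) {
        p <- file.path(dir, "survival.csv")
        utils::write.csv(surv, p, row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
    }
    if (!is.null(truth)) {
        p <- file.path(dir, "truth.json")
        tl <- list(
            trueLabels = as.list(truth@trueLabels),
            trueMarkers = truth@trueMarkers,
            trueProportions = if (ncol(truth@trueProportions))
                as.data.frame(truth@trueProportions) else NULL,
            plantedEdges = as.data.frame(truth@plantedEdges),
            edgeThreshold = truth@edgeThreshold,
            plantedLRPairs = as.data.frame(truth@plantedLRPairs),
            survivalGroups = as.list(truth@survivalGroups))
        jsonlite::write_json(tl, p, auto_unbox = TRUE, digits = NA,
                             null = "null")
        paths <- c(paths, p)
    }
    invisible(paths)
}
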