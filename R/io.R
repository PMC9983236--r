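# Readers/writers for the standard on-disk formats, the QC filter and the
# normalization steps (single-cell log-normalization; bulk median-of-ratios
# size factors).

#' Read a single-cell matrix from MatrixMarket or dense TSV
#'
#' Accepts either a directory containing `matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv` (and optionally `labels.tsv` with columns cell_id, label),
#' or a dense genes x cells TSV whose first column holds gene ids.
#'
#' @param path directory (MTX layout) or a TSV file.
#' @param labels optional path to a labels TSV (cell_id, label); overrides a
#'   `labels.tsv` found in an MTX directory.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts`, `colData()$label` when labels are available, and
#'   `rowData()$mito` flagged from the `MT-` gene-id prefix.
#' @export
readCellMatrix <- function(path, labels = NULL) {
    if (dir.exists(path)) {
        m <- Matrix::readMM(file.path(path, "matrix.mtx"))
        genes <- readLines(file.path(path, "genes.tsv"))
        genes <- vapply(strsplit(genes, "\t"), `[`, "", 1L)
        cells <- readLines(file.path(path, "barcodes.tsv"))
        dimnames(m) <- list(genes, cells)
        if (is.null(labels) && file.exists(file.path(path, "labels.tsv")))
            labels <- file.path(path, "labels.tsv")
    } else {
        tab <- utils::read.delim(path, check.names = FALSE,
                                 stringsAsFactors = FALSE)
        genes <- as.character(tab[[1]])
        m <- as.matrix(tab[, -1, drop = FALSE])
        rownames(m) <- genes
        m <- Matrix::Matrix(m, sparse = TRUE)
    }
    if (anyDuplicated(rownames(m))) stop("duplicate gene ids in input")
    if (anyDuplicated(colnames(m))) stop("duplicate cell ids in input")
    cd <- S4Vectors::DataFrame(row.names = colnames(m))
    if (!is.null(labels)) {
        lt <- utils::read.delim(labels, stringsAsFactors = FALSE)
        lab <- stats::setNames(as.character(lt[[2]]), as.character(lt[[1]]))
        missing <- setdiff(colnames(m), names(lab))
        if (length(missing))
            stop("cells without labels: ",
                 paste(utils::head(missing, 5), collapse = ", "))
        cd$label <- unname(lab[colnames(m)])
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m), colData = cd,
        rowData = S4Vectors::DataFrame(
            mito = startsWith(rownames(m), "MT-"), row.names = rownames(m)))
}

#' Read a bulk expression matrix from TSV
#'
#' @param path genes x samples TSV; first column gene ids.
#' @param normalized whether the values are already normalized.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `values` and `metadata()$normalized`.
#' @export
readBulkMatrix <- function(path, normalized = FALSE) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
    if (anyDuplicated(rownames(m))) stop("duplicate gene ids in bulk input")
    if (any(m < 0)) stop("bulk matrix has negative entries")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = m))
    S4Vectors::metadata(se)$normalized <- normalized
    se
}

#' Read a ligand-receptor database CSV
#'
#' @param path CSV with columns ligand, receptor, secreted (0/1 or logical).
#' @return DataFrame (pair, ligand, receptor, secreted).
#' @export
readLRDatabase <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("ligand", "receptor", "secreted")
    if (!all(need %in% names(tab)))
        stop("lr database must have columns ", paste(need, collapse = ", "))
    S4Vectors::DataFrame(pair = sprintf("LR%03d", seq_len(nrow(tab))),
                         ligand = as.character(tab$ligand),
                         receptor = as.character(tab$receptor),
                         secreted = as.logical(as.integer(tab$secreted)))
}

#' Read a survival table CSV
#'
#' @param path CSV with columns sample, time, event.
#' @return data.frame (sample, time, event) with events coerced to 0/1.
#' @export
readSurvivalTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample", "time", "event")
    if (!all(need %in% names(tab)))
        stop("survival table must have columns ", paste(need, collapse = ", "))
    if (any(tab$time < 0)) stop("survival times must be nonnegative")
    data.frame(sample = as.character(tab$sample),
               time = as.numeric(tab$time),
               event = as.integer(tab$event))
}

.mitoMask <- function(sce) {
    rd <- SummarizedExperiment::rowData(sce)
    if (!is.null(rd$mito)) as.logical(rd$mito)
    else startsWith(rownames(sce), "MT-")
}

#' Quality-control filtering of cells then genes
#'
#' Removes cells detecting fewer than `minGenesPerCell` genes or with a
#' mitochondrial count fraction strictly above `maxMitoFrac`; afterwards
#' removes genes detected in fewer than `minCellsPerGene` of the remaining
#' cells. A cell detecting exactly `minGenesPerCell` genes is retained and a
#' mitochondrial fraction of exactly `maxMitoFrac` is tolerated: removal is
#' strict-less / strict-greater.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with raw counts.
#' @param minGenesPerCell minimum detected genes for a cell to survive.
#' @param minCellsPerGene minimum detecting cells for a gene to survive.
#' @param maxMitoFrac maximal tolerated mitochondrial count fraction.
#' @return the filtered object; `metadata()$qc` holds the per-rule report
#'   (cellsLowGenes, cellsHighMito, genesLowCells, cellsKept, genesKept).
#' @export
qcFilter <- function(sce, minGenesPerCell = 200, minCellsPerGene = 10,
                     maxMitoFrac = 0.10) {
    cnt <- SummarizedExperiment::assay(sce, "counts")
    detected <- Matrix::colSums(cnt > 0)
    total <- Matrix::colSums(cnt)
    mito <- .mitoMask(sce)
    mitoFrac <- if (any(mito))
        Matrix::colSums(cnt[mito, , drop = FALSE]) / pmax(total, 1)
    else numeric(ncol(cnt))
    lowGenes <- detected < minGenesPerCell
    highMito <- mitoFrac > maxMitoFrac
    keepCells <- !(lowGenes | highMito)
    cnt2 <- cnt[, keepCells, drop = FALSE]
    cellsPerGene <- Matrix::rowSums(cnt2 > 0)
    keepGenes <- cellsPerGene >= minCellsPerGene
    report <- list(cellsLowGenes = sum(lowGenes),
                   cellsHighMito = sum(highMito),
                   cellsRemoved = sum(!keepCells),
                   genesLowCells = sum(!keepGenes),
                   cellsKept = sum(keepCells),
                   genesKept = sum(keepGenes))
    if (!report$cellsKept || !report$genesKept) {
        e <- simpleError("no cells or genes survive QC filtering")
        e$qcReport <- report
        stop(e)
    }
    out <- sce[keepGenes, keepCells]
    S4Vectors::metadata(out)$qc <- report
    out
}

#' Log-normalize single-cell counts
#'
#' Adds a `logcounts` assay with
#' `log(1 + scaleFactor x count / cellTotal)`; raw counts are untouched.
#' A column is exactly invariant under rescaling of its counts.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with counts.
#' @param scaleFactor target per-cell total (default 1e4).
#' @return `sce` with a `logcounts` assay added.
#' @export
logNormalize <- function(sce, scaleFactor = 1e4) {
    cnt <- SummarizedExperiment::assay(sce, "counts")
    total <- Matrix::colSums(cnt)
    if (any(total == 0))
        stop("cell(s) with zero total counts: ",
             paste(utils::head(colnames(cnt)[total == 0], 5),
                   collapse = ", "),
             " (run qcFilter first)")
    ln <- log1p(sweep(as.matrix(cnt), 2, scaleFactor / total, "*"))
    SummarizedExperiment::assay(sce, "logcounts") <- ln
    sce
}

#' Median-of-ratios size factors for bulk counts
#'
#' Builds a reference as the per-gene geometric mean over samples (genes with
#' any zero excluded) and takes each sample's size factor as the median over
#' genes of value/reference.
#'
#' @param bulk a bulk [SummarizedExperiment::SummarizedExperiment] (assay 1)
#'   or a numeric genes x samples matrix of raw values.
#' @return named numeric vector of per-sample size factors.
#' @export
sizeFactorsMedianRatio <- function(bulk) {
    m <- if (is(bulk, "SummarizedExperiment"))
        as.matrix(SummarizedExperiment::assay(bulk, 1)) else as.matrix(bulk)
    if (any(m < 0)) stop("negative values in bulk matrix")
    ok <- rowSums(m == 0) == 0
    if (!any(ok))
        stop("no gene is nonzero in all samples; cannot form the ",
             "geometric-mean reference")
    lg <- log(m[ok, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- apply(lg, 2, function(col) exp(stats::median(col - ref)))
    stats::setNames(sf, colnames(m))
}

#' Normalize a bulk matrix by median-of-ratios size factors
#'
#' @param bulk a bulk [SummarizedExperiment::SummarizedExperiment].
#' @return `bulk` with columns divided by their size factors,
#'   `metadata()$normalized = TRUE` and `metadata()$sizeFactors` recorded.
#' @export
normalizeBulk <- function(bulk) {
    sf <- sizeFactorsMedianRatio(bulk)
    m <- sweep(as.matrix(SummarizedExperiment::assay(bulk, 1)), 2, sf, "/")
    SummarizedExperiment::assay(bulk, 1) <- m
    S4Vectors::metadata(bulk)$normalized <- TRUE
    S4Vectors::metadata(bulk)$sizeFactors <- sf
    bulk
}
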