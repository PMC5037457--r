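#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowData rowData<- colData
NULL

#' ProteinMatrix: protein-by-sample log2 abundance container
#'
#' An S4 container for rolled-up, normalized protein abundances, extending
#' [SummarizedExperiment::SummarizedExperiment]. The primary assay
#' `"log2intensity"` holds log2-transformed summed peptide intensities
#' (missing values allowed). Row metadata carries `n_peptides` (distinct
#' peptide sequences ever quantified for the protein) and `qc_cv` (coefficient
#' of variation across QC-pool injections on the linear scale, `NA` when fewer
#' than two QC pools were quantified). Column metadata is the sample design:
#' `condition`, `time_h`, `replicate`, `is_qc_pool`.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @seealso [rollupToProtein()], [qcPoolCV()], [zscoreMatrix()]
#' @export
setClass("ProteinMatrix", contains = "SummarizedExperiment")

setValidity("ProteinMatrix", function(object) {
    msg <- character()
    if (!"log2intensity" %in% names(assays(object)))
        msg <- c(msg, "assay 'log2intensity' is required")
    rd <- rowData(object)
    for (col in c("n_peptides", "qc_cv"))
        if (!col %in% names(rd))
            msg <- c(msg, sprintf("rowData column '%s' is required", col))
    if ("n_peptides" %in% names(rd) && nrow(object) > 0 &&
        any(rd$n_peptides < 1))
        msg <- c(msg, "every retained protein must have n_peptides >= 1")
    if ("qc_cv" %in% names(rd) && nrow(object) > 0 &&
        any(rd$qc_cv < 0, na.rm = TRUE))
        msg <- c(msg, "qc_cv must be non-negative where defined")
    cd <- colData(object)
    for (col in c("condition", "time_h", "replicate", "is_qc_pool"))
        if (!col %in% names(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (length(msg)) msg else TRUE
})

#' Construct a ProteinMatrix
#'
#' @param log2mat numeric matrix of log2 protein intensities, proteins in rows
#'   (rownames = accessions), samples in columns (colnames = sample ids).
#' @param design a sample-design `data.frame` as returned by [readDesign()],
#'   one row per column of `log2mat` (matched by `sample_id`).
#' @param nPeptides integer vector, distinct peptides per protein.
#' @param qcCV numeric vector, QC-pool coefficient of variation per protein
#'   (`NA` where undefined).
#' @return a [ProteinMatrix-class] object.
#' @export
ProteinMatrix <- function(log2mat, design, nPeptides, qcCV = NA_real_) {
    stopifnot(is.matrix(log2mat), !is.null(rownames(log2mat)),
              !is.null(colnames(log2mat)))
    design <- as.data.frame(design)
    idx <- match(colnames(log2mat), design$sample_id)
    if (anyNA(idx))
        stop("samples absent from design: ",
             paste(colnames(log2mat)[is.na(idx)], collapse = ", "))
    cd <- DataFrame(design[idx, c("condition", "time_h", "replicate",
                                  "is_qc_pool"), drop = FALSE],
                    row.names = colnames(log2mat))
    qcCV <- rep_len(qcCV, nrow(log2mat))
    rd <- DataFrame(n_peptides = as.integer(rep_len(nPeptides, nrow(log2mat))),
                    qc_cv = as.numeric(qcCV),
                    row.names = rownames(log2mat))
    new("ProteinMatrix",
        SummarizedExperiment(assays = list(log2intensity = log2mat),
                             rowData = rd, colData = cd))
}

#' @describeIn ProteinMatrix Number of distinct quantified peptides per protein.
#' @param x a `ProteinMatrix`.
#' @export
nPeptides <- function(x) {
    stopifnot(is(x, "ProteinMatrix"))
    stats::setNames(rowData(x)$n_peptides, rownames(x))
}

#' @describeIn ProteinMatrix Per-protein QC-pool coefficient of variation.
#' @export
qcCV <- function(x) {
    stopifnot(is(x, "ProteinMatrix"))
    stats::setNames(rowData(x)$qc_cv, rownames(x))
}

setMethod("show", "ProteinMatrix", function(object) {
    cd <- colData(object)
    nqc <- sum(cd$is_qc_pool)
    cat(sprintf(
        "ProteinMatrix: %d proteins x %d samples (%d QC pools)\n",
        nrow(object), ncol(object), nqc))
    cat(sprintf("  conditions: %s\n",
                paste(unique(cd$condition[!cd$is_qc_pool]), collapse = ", ")))
    cat(sprintf("  time points (h): %s\n",
                paste(sort(unique(cd$time_h[!cd$is_qc_pool])), collapse = ", ")))
    nd <- sum(!is.na(qcCV(object)))
    cat(sprintf("  assay 'log2intensity'; qc_cv defined for %d proteins\n", nd))
    invisible(NULL)
})
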