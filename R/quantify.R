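#' Total peptide intensity (heavy + light)
#'
#' Sums the light and heavy channel areas of a peptide into a single
#' label-free abundance. Missing channels are skipped; the result is missing
#' only when both channels are missing. Vectorized.
#'
#' @param iL,iH light / heavy channel AUC (non-negative; `NA` = missing).
#' @return numeric vector of totals.
#' @export
totalPeptideIntensity <- function(iL, iH) {
    if (any(iL < 0, na.rm = TRUE) || any(iH < 0, na.rm = TRUE))
        stop("channel intensities must be non-negative")
    out <- ifelse(is.na(iL), 0, iL) + ifelse(is.na(iH), 0, iH)
    out[is.na(iL) & is.na(iH)] <- NA_real_
    out
}

#' Peptide-by-sample matrix of total intensities
#'
#' @param records canonical peptide table ([peptide-table-format]).
#' @return numeric matrix, peptides (rownames = sequence) x samples.
#' @export
peptideTotalMatrix <- function(records) {
    tot <- totalPeptideIntensity(records$intensity_light,
                                 records$intensity_heavy)
    peps <- unique(records$peptide_sequence)
    samps <- unique(records$sample_id)
    mat <- matrix(NA_real_, length(peps), length(samps),
                  dimnames = list(peps, samps))
    mat[cbind(match(records$peptide_sequence, peps),
              match(records$sample_id, samps))] <- tot
    mat
}

#' Robust-median intensity scaling
#'
#' Scales every sample (column) so its median peptide intensity equals the
#' reference, taken as the median of the per-sample medians
#' (median-of-medians). Medians are computed over the peptides quantified in
#' that sample.
#'
#' @param mat peptide x sample matrix of total intensities (`NA` = missing).
#' @return list with `scaled` (matrix) and `factors` (named per-sample
#'   multipliers; reference in `attr(factors, "reference_median")`).
#' @export
normalizeRobustMedian <- function(mat) {
    med <- apply(mat, 2, stats::median, na.rm = TRUE)
    if (any(!is.finite(med)))
        stop("sample(s) with no quantified peptides: ",
             paste(colnames(mat)[!is.finite(med)], collapse = ", "))
    ref <- stats::median(med)
    factors <- ref / med
    scaled <- sweep(mat, 2, factors, "*")
    attr(factors, "reference_median") <- ref
    list(scaled = scaled, factors = factors)
}

#' Roll peptide intensities up to proteins
#'
#' Sums non-missing peptide totals per protein and sample, log2-transforms,
#' and packages the result as a [ProteinMatrix-class] with per-protein peptide
#' counts and QC-pool CV. A protein x sample cell with no quantified peptide
#' is missing, never zero.
#'
#' @param mat peptide x sample matrix (rownames = peptide sequences),
#'   typically [normalizeRobustMedian()] output.
#' @param mapping named character vector: peptide sequence -> protein
#'   accession.
#' @param design sample design ([readDesign()]), covering `colnames(mat)`.
#' @return a [ProteinMatrix-class]; linear-scale sums in assay `"linear"`,
#'   log2 in assay `"log2intensity"`.
#' @export
rollupToProtein <- function(mat, mapping, design) {
    unmapped <- setdiff(rownames(mat), names(mapping))
    if (length(unmapped))
        stop("peptide(s) with no protein mapping: ",
             paste(utils::head(unmapped, 5), collapse = ", "))
    prot <- mapping[rownames(mat)]
    quantified <- !is.na(mat)
    lin <- rowsum(ifelse(quantified, mat, 0), prot)
    anyQ <- rowsum(quantified + 0, prot) > 0
    lin[!anyQ] <- NA_real_
    # distinct peptide sequences ever quantified per protein
    everQ <- rowSums(quantified) > 0
    nPep <- table(prot[everQ])[rownames(lin)]
    nPep[is.na(nPep)] <- 0L
    keep <- nPep >= 1
    if (any(!keep))
        warning(sum(!keep), " protein(s) with no quantified peptide dropped")
    lin <- lin[keep, , drop = FALSE]
    log2mat <- log2(lin)
    log2mat[which(lin == 0)] <- NA_real_  # a zero sum has no log-scale abundance
    pm <- ProteinMatrix(log2mat, design, nPeptides = as.integer(nPep[keep]))
    SummarizedExperiment::assays(pm)$linear <- lin
    rowData(pm)$qc_cv <- qcPoolCV(pm)
    methods::validObject(pm)
    pm
}

#' QC-pool coefficient of variation per protein
#'
#' CV (sd/mean) of the linear-scale protein intensity across QC-pool
#' injections; `NA` when fewer than two QC pools quantified the protein.
#'
#' @param pm a [ProteinMatrix-class].
#' @return named numeric vector of fractions.
#' @export
qcPoolCV <- function(pm) {
    stopifnot(is(pm, "ProteinMatrix"))
    qcCols <- which(colData(pm)$is_qc_pool)
    lin <- if ("linear" %in% names(assays(pm)))
        assay(pm, "linear") else 2^assay(pm, "log2intensity")
    if (length(qcCols) < 2)
        return(stats::setNames(rep(NA_real_, nrow(pm)), rownames(pm)))
    vals <- lin[, qcCols, drop = FALSE]
    stats::setNames(apply(vals, 1, cvOf), rownames(pm))
}

#' Z-score a protein matrix row-wise
#'
#' Centers and scales each protein's log2 profile to mean 0, SD 1 over its
#' non-missing samples. Zero-variance rows are dropped with a warning.
#'
#' @param pm a [ProteinMatrix-class] (or a plain numeric matrix).
#' @return numeric matrix of z-scores (possibly fewer rows).
#' @export
zscoreMatrix <- function(pm) {
    mat <- if (is(pm, "ProteinMatrix")) assay(pm, "log2intensity") else pm
    mu <- rowMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 1, stats::sd, na.rm = TRUE)
    drop <- is.na(sdv) | sdv == 0
    if (any(drop))
        warning(sum(drop), " zero-variance protein(s) dropped from z-scoring")
    z <- (mat - mu) / sdv
    z[!drop, , drop = FALSE]
}

#' Full label-free quantification stage
#'
#' Peptide totals, optional robust-median scaling, protein rollup.
#'
#' @param records canonical peptide table.
#' @param design sample design.
#' @param config a [pipelineConfig()].
#' @return list: `proteinMatrix` ([ProteinMatrix-class]), `factors`
#'   (per-sample scaling factors), `peptideTotals` (scaled matrix).
#' @export
quantifyAbundance <- function(records, design, config = pipelineConfig()) {
    mat <- peptideTotalMatrix(records)
    if (config$normalization == "robust_median") {
        norm <- normalizeRobustMedian(mat)
    } else {
        norm <- list(scaled = mat,
                     factors = stats::setNames(rep(1, ncol(mat)),
                                               colnames(mat)))
    }
    mapping <- peptideProteinMap(records)
    pm <- rollupToProtein(norm$scaled, mapping, design)
    list(proteinMatrix = pm, factors = norm$factors,
         peptideTotals = norm$scaled)
}

# peptide sequence -> accession map from the records; a peptide mapped to two
# accessions violates the input contract
peptideProteinMap <- function(records) {
    u <- unique(records[, c("peptide_sequence", "protein_accession")])
    dup <- u$peptide_sequence[duplicated(u$peptide_sequence)]
    if (length(dup))
        stop("peptide(s) mapped to more than one protein: ",
             paste(utils::head(unique(dup), 5), collapse = ", "))
    stats::setNames(u$protein_accession, u$peptide_sequence)
}
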