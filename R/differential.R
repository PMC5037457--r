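#' One-way ANOVA with optional inverse-variance weighting
#'
#' Ordinary one-way ANOVA on log2 values when no per-observation variance
#' estimates are available; when they are (e.g. from peptide-level
#' replication), observations are weighted by inverse variance and the F-test
#' comes from the weighted least-squares fit.
#'
#' @param values numeric response (log2 intensities).
#' @param group grouping factor (>= 2 groups, each with >= 2 observations).
#' @param weights optional non-negative weights (inverse variances).
#' @return the p-value of the group effect (`NA` with a warning when
#'   replication is insufficient).
#' @export
weightedAnova <- function(values, group, weights = NULL) {
    ok <- !is.na(values) & !is.na(group)
    if (!is.null(weights)) ok <- ok & !is.na(weights)
    values <- values[ok]
    group <- droplevels(factor(group[ok]))
    if (nlevels(group) < 2 || any(table(group) < 2) ||
        length(values) <= nlevels(group)) {
        warning("insufficient replication for ANOVA; p undefined")
        return(NA_real_)
    }
    fit <- if (is.null(weights))
        stats::lm(values ~ group)
    else stats::lm(values ~ group, weights = weights[ok])
    tab <- stats::anova(fit)
    tab[["Pr(>F)"]][1]
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up, preserving the
#' input order. Thin, validated front-end to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values, same length and order.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "bh")) {
    method <- match.arg(method)
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    if (!length(p)) return(numeric(0))
    stats::p.adjust(p, method = c(bonferroni = "bonferroni", bh = "BH")[method])
}

#' Signed linear fold change
#'
#' Converts a log2 difference to the signed linear convention: the ratio when
#' the numerator group is higher, minus the reciprocal ratio when lower, so
#' `|FC| >= 1` and the sign gives direction.
#'
#' @param log2fc log2 fold change (numerator minus denominator group mean).
#' @return signed linear fold change.
#' @export
signedFoldChange <- function(log2fc) {
    ratio <- 2^log2fc
    ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Differential protein expression between gravity conditions
#'
#' At one time point, per protein: two-sided equal-variance Student's t-test
#' of `micro_g` vs `normal_g` log2 abundance, signed linear fold change from
#' the group-mean difference, BH adjustment across proteins, and the
#' four-criterion filter: raw p below `p_cut`, |FC| above `fc_cut`, at least
#' `min_peptides` matched peptides, and QC-pool CV defined and below
#' `cv_cut`.
#'
#' @param pm a [ProteinMatrix-class].
#' @param time_h time point to test (hours).
#' @param config a [pipelineConfig()].
#' @return data.frame (one row per testable protein): accession, fc_signed,
#'   p_raw, p_adjusted (BH), n_peptides, qc_cv, passes_filter, direction,
#'   fail_reasons.
#' @export
differentialExpression <- function(pm, time_h = 120,
                                   config = pipelineConfig()) {
    cd <- colData(pm)
    mat <- assay(pm, "log2intensity")
    a <- which(!cd$is_qc_pool & cd$condition == "micro_g" &
                   cd$time_h == time_h)
    b <- which(!cd$is_qc_pool & cd$condition == "normal_g" &
                   cd$time_h == time_h)
    if (length(a) < 2 || length(b) < 2)
        stop("need >= 2 replicates per condition at ", time_h, " h")
    res <- lapply(seq_len(nrow(mat)), function(i) {
        x <- mat[i, a]; y <- mat[i, b]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2 || length(y) < 2 ||
            (stats::var(x) + stats::var(y)) == 0) return(NULL)
        p <- stats::t.test(x, y, var.equal = TRUE)$p.value
        data.frame(protein_accession = rownames(mat)[i],
                   fc_signed = signedFoldChange(mean(x) - mean(y)),
                   p_raw = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adjusted <- adjustPvalues(res$p_raw, "bh")
    res$n_peptides <- nPeptides(pm)[res$protein_accession]
    res$qc_cv <- qcCV(pm)[res$protein_accession]
    res <- differentialFilter(res, config)
    rownames(res) <- NULL
    res
}

#' Apply the four-criterion differential-expression filter
#'
#' @param stats data.frame with `p_raw`, `fc_signed`, `n_peptides`, `qc_cv`.
#' @param config a [pipelineConfig()].
#' @return `stats` plus `passes_filter`, `direction` and `fail_reasons`
#'   columns; the counts of up/down calls are reported via [message()].
#' @export
differentialFilter <- function(stats, config = pipelineConfig()) {
    reasons <- mapply(function(p, fc, n, cv) {
        r <- character()
        if (!(p < config$p_cut)) r <- c(r, "p_value")
        if (!(abs(fc) > config$fc_cut)) r <- c(r, "fold_change")
        if (!(n >= config$min_peptides)) r <- c(r, "min_peptides")
        if (is.na(cv)) r <- c(r, "qc_cv_undefined")
        else if (!(cv < config$cv_cut)) r <- c(r, "qc_cv")
        paste(r, collapse = ",")
    }, stats$p_raw, stats$fc_signed, stats$n_peptides, stats$qc_cv)
    stats$passes_filter <- !nzchar(reasons)
    stats$direction <- ifelse(stats$fc_signed >= 0, "up", "down")
    stats$fail_reasons <- reasons
    nUp <- sum(stats$passes_filter & stats$direction == "up")
    nDn <- sum(stats$passes_filter & stats$direction == "down")
    noteLog("differential filter: %d pass (%d up, %d down) of %d proteins",
            nUp + nDn, nUp, nDn, nrow(stats))
    stats
}

#' Classify proteins into temporal-trend groups
#'
#' Per protein, two test families on log2 abundance: (i) one-way ANOVA over
#' time within each gravity condition (baseline 0 h samples enter both
#' conditions' series; Bonferroni over the 2 conditions); (ii) a
#' condition test at each shared post-switch time point (Bonferroni over the
#' number of time points). Classes: `no_change` when nothing is significant;
#' `similar_change` when time changes but conditions never differ;
#' `dissimilar_change` when any per-time condition test is significant.
#'
#' @param pm a [ProteinMatrix-class].
#' @param config a [pipelineConfig()] (`p_cut` is the significance level on
#'   the adjusted p-values).
#' @return list: `classes` (data.frame accession, trend_class, min adjusted
#'   p per family), `fractions` (named fractions over classified proteins).
#' @export
classifyTrends <- function(pm, config = pipelineConfig()) {
    cd <- colData(pm)
    mat <- assay(pm, "log2intensity")
    bio <- !cd$is_qc_pool
    times <- sort(unique(cd$time_h[bio & cd$time_h > 0]))
    conds <- c("normal_g", "micro_g")
    rows <- lapply(seq_len(nrow(mat)), function(i) {
        v <- mat[i, ]
        ## family (i): time ANOVA within each condition (baseline shared)
        pTime <- vapply(conds, function(cc) {
            sel <- bio & (cd$condition == cc | cd$time_h == 0)
            suppressWarnings(weightedAnova(v[sel], cd$time_h[sel]))
        }, numeric(1))
        ## family (ii): condition effect at each time point
        pCond <- vapply(times, function(t) {
            sel <- bio & cd$time_h == t & cd$condition %in% conds
            suppressWarnings(weightedAnova(v[sel], cd$condition[sel]))
        }, numeric(1))
        if (all(is.na(pTime)) || all(is.na(pCond)))
            return(data.frame(protein_accession = rownames(mat)[i],
                              trend_class = NA_character_,
                              p_time_min = NA_real_, p_cond_min = NA_real_,
                              stringsAsFactors = FALSE))
        pTimeAdj <- adjustPvalues(pTime, "bonferroni")
        pCondAdj <- adjustPvalues(pCond, "bonferroni")
        sigTime <- any(pTimeAdj < config$p_cut, na.rm = TRUE)
        sigCond <- any(pCondAdj < config$p_cut, na.rm = TRUE)
        cls <- if (sigCond) "dissimilar_change"
        else if (sigTime) "similar_change" else "no_change"
        data.frame(protein_accession = rownames(mat)[i], trend_class = cls,
                   p_time_min = suppressWarnings(min(pTimeAdj, na.rm = TRUE)),
                   p_cond_min = suppressWarnings(min(pCondAdj, na.rm = TRUE)),
                   stringsAsFactors = FALSE)
    })
    classes <- do.call(rbind, rows)
    done <- !is.na(classes$trend_class)
    if (any(!done))
        noteLog("%d protein(s) unclassifiable (missing whole condition)",
                sum(!done))
    fr <- table(factor(classes$trend_class[done],
                       c("no_change", "similar_change", "dissimilar_change")))
    fractions <- as.numeric(fr) / max(sum(fr), 1L)
    names(fractions) <- names(fr)
    list(classes = classes, fractions = fractions)
}

#' PCA quality control with group confidence ellipses
#'
#' Samples are projected by singular value decomposition of the z-scored
#' protein matrix (complete-case proteins only). For each group (time point
#' among biological samples; QC pools as their own group) a 2D Gaussian
#' confidence ellipse on (PC1, PC2) is parameterized at the chi-square(2)
#' quantile of the given confidence level (99.999% by default, so ellipses
#' bound essentially the whole group).
#'
#' @param z z-scored matrix from [zscoreMatrix()] (proteins x samples).
#' @param design sample design covering the columns of `z`.
#' @param confidence ellipse confidence level.
#' @return list: `scores` (samples x PCs data.frame with group labels),
#'   `explained` (variance fractions), `ellipses` (per group: center,
#'   semi-axes, angle), `n_complete` (proteins used).
#' @export
pcaQC <- function(z, design, confidence = 0.99999) {
    if (ncol(z) < 3) stop("PCA requires at least 3 samples")
    complete <- stats::complete.cases(z)
    noteLog("PCA on %d complete-case proteins (of %d)", sum(complete), nrow(z))
    zc <- z[complete, , drop = FALSE]
    pc <- stats::prcomp(t(zc), center = TRUE, scale. = FALSE)
    d <- design[match(colnames(z), design$sample_id), ]
    group <- ifelse(d$is_qc_pool, "QC_pool", sprintf("%g h", d$time_h))
    scores <- data.frame(sample_id = colnames(z), group = group,
                         condition = d$condition,
                         PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                         stringsAsFactors = FALSE)
    explained <- pc$sdev^2 / sum(pc$sdev^2)
    radius <- sqrt(stats::qchisq(confidence, df = 2))
    ell <- lapply(split(seq_len(nrow(scores)), group), function(i) {
        xy <- as.matrix(scores[i, c("PC1", "PC2")])
        if (nrow(xy) < 3) return(NULL)
        ctr <- colMeans(xy)
        eg <- eigen(stats::cov(xy))
        data.frame(group = group[i[1]], center_pc1 = ctr[1],
                   center_pc2 = ctr[2],
                   semi_major = radius * sqrt(max(eg$values[1], 0)),
                   semi_minor = radius * sqrt(max(eg$values[2], 0)),
                   angle_rad = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
                   n = nrow(xy), stringsAsFactors = FALSE)
    })
    ellipses <- do.call(rbind, ell)
    rownames(ellipses) <- NULL
    list(scores = scores, explained = explained, ellipses = ellipses,
         n_complete = sum(complete))
}
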