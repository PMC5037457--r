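#' Pipeline configuration
#'
#' Assemble the analysis thresholds used throughout the pipeline. Defaults are
#' the study values: raw p < 0.05, linear fold change > 1.5 in magnitude,
#' at least 2 matched peptides, QC-pool CV < 20% for differential expression;
#' retention-time tolerance 0.5 min and heavy-peak signal-to-noise >= 10 for
#' turnover peptide curation; 0.05 FDR for enrichment calls.
#'
#' @param p_cut raw p-value cutoff for the differential filter.
#' @param fc_cut linear fold-change magnitude cutoff.
#' @param min_peptides minimum matched peptides per protein.
#' @param cv_cut maximum QC-pool coefficient of variation (fraction).
#' @param gsea_fdr_cut FDR q cutoff for calling a gene set enriched.
#' @param rt_tolerance_min maximum |RT(light) - RT(heavy)| in minutes.
#' @param snr_min minimum (light intensity at T=0) / (heavy-channel noise).
#' @param n_permutations permutations for the enrichment null.
#' @param random_seed integer seed recorded in all outputs.
#' @param normalization `"robust_median"` (default) or `"none"`.
#' @return a named list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(p_cut = 0.05, fc_cut = 1.5, min_peptides = 2L,
                           cv_cut = 0.20, gsea_fdr_cut = 0.05,
                           rt_tolerance_min = 0.5, snr_min = 10,
                           n_permutations = 1000L, random_seed = 1L,
                           normalization = c("robust_median", "none")) {
    normalization <- match.arg(normalization)
    cfg <- list(p_cut = p_cut, fc_cut = fc_cut,
                min_peptides = as.integer(min_peptides), cv_cut = cv_cut,
                gsea_fdr_cut = gsea_fdr_cut,
                rt_tolerance_min = rt_tolerance_min, snr_min = snr_min,
                n_permutations = as.integer(n_permutations),
                random_seed = as.integer(random_seed),
                normalization = normalization)
    validatePipelineConfig(cfg)
    class(cfg) <- "PipelineConfig"
    cfg
}

validatePipelineConfig <- function(cfg) {
    num <- c("p_cut", "fc_cut", "min_peptides", "cv_cut", "gsea_fdr_cut",
             "rt_tolerance_min", "snr_min")
    for (f in num) {
        v <- cfg[[f]]
        if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
            stop("config threshold '", f, "' must be a single positive number")
    }
    if (cfg$n_permutations < 1) stop("n_permutations must be >= 1")
    invisible(TRUE)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unspecified fields fall back to [pipelineConfig()] defaults; a
#' `simulation:` section, if present, is forwarded to [simulationConfig()]
#' and attached as `attr(cfg, "simulation")`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path = NULL) {
    if (is.null(path)) return(pipelineConfig())
    raw <- yaml::read_yaml(path)
    sim <- raw$simulation
    raw$simulation <- NULL
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(raw), known)
    if (length(unknown))
        stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    cfg <- do.call(pipelineConfig, raw)
    if (!is.null(sim)) attr(cfg, "simulation") <- do.call(simulationConfig, sim)
    cfg
}
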