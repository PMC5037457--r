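options(dynaSILAC.quiet = TRUE)

# Minimal complete peptide record rows for IO and quantification tests:
# 3 records, 2 peptides, 2 proteins, 2 samples.
toyPeptideTable <- function() {
    data.frame(
        peptide_sequence = c("AAAGILK", "AAAGILK", "CCDEFPR"),
        protein_accession = c("P1", "P1", "P2"),
        sample_id = c("s1", "s2", "s1"),
        intensity_light = c(100, 120, 50),
        intensity_heavy = c(25, NA, 10),
        rt_light = c(21.1, 21.2, 44.0),
        rt_heavy = c(21.2, NA, 44.1),
        msms_identified_light = c(TRUE, TRUE, TRUE),
        msms_identified_heavy = c(TRUE, FALSE, TRUE),
        noise_heavy = c(2, 2, 1),
        n_labeled_residues = c(1L, 1L, 1L),
        isotopologue_hh = NA_real_,
        isotopologue_hl = NA_real_,
        stringsAsFactors = FALSE)
}

writeTempTSV <- function(df) {
    path <- tempfile(fileext = ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    path
}

# Study-shaped design: 3 baseline + 2 conditions x {12,48,120} h x 3 reps
# + 4 QC pools = 25 samples.
studyDesign <- function() {
    rbind(
        data.frame(sample_id = paste0("b", 1:3), condition = "baseline",
                   time_h = 0, replicate = 1:3, is_qc_pool = FALSE),
        expand.grid(replicate = 1:3, time_h = c(12, 48, 120),
                    condition = c("normal_g", "micro_g"),
                    stringsAsFactors = FALSE) |>
            (\(d) data.frame(sample_id = sprintf("%s_%g_r%d", d$condition,
                                                 d$time_h, d$replicate),
                             condition = d$condition, time_h = d$time_h,
                             replicate = d$replicate,
                             is_qc_pool = FALSE))(),
        data.frame(sample_id = paste0("qc", 1:4), condition = "baseline",
                   time_h = 0, replicate = 1:4, is_qc_pool = TRUE))
}

# Small null simulation config (no effects, homogeneous turnover) used by
# calibration tests.
nullSimConfig <- function(nProteins = 40, peptidesPerProtein = c(1, 3)) {
    simulationConfig(nProteins = nProteins,
                     peptidesPerProtein = peptidesPerProtein,
                     rateMultiplier = 1, halfLifeLogSD = 0,
                     trendFractions = c(no_change = 1, similar_change = 0,
                                        dissimilar_change = 0))
}
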