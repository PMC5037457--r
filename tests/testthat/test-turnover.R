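test_that("RIA is the heavy fraction of the channel total", {
    expect_equal(computeRIA(0.5, 0.5), 0.5)   # equal channels
    expect_equal(computeRIA(0.1, 0.4), 0.8)   # reduced-abundance state
    expect_equal(computeRIA(3, 0), 0)         # no incorporation yet
    expect_equal(computeRIA(0, 2.5), 1)       # complete labeling
    expect_true(is.na(computeRIA(0, 0)))      # undefined, flagged not thrown
    expect_true(is.na(computeRIA(NA, NA)))
    expect_error(computeRIA(-0.1, 0.4), "non-negative")
})

test_that("RIA and total intensity reconstruct the channels exactly", {
    set.seed(3)
    iL <- rlnorm(1000); iH <- rlnorm(1000)
    tot <- totalPeptideIntensity(iL, iH)
    ria <- computeRIA(iL, iH)
    expect_equal(ria * tot, iH, tolerance = 1e-12)
    expect_equal((1 - ria) * tot, iL, tolerance = 1e-12)
})

curationFixture <- function() {
    # 10 peptides x 2 samples (one at T=0): engineered violations
    # P01, P02: clean.  P03: heavy never MS/MS-identified.
    # P04: light never identified.  P05: RT off by 0.6 min in one sample.
    # P06: RT off in all samples.  P07: S/N = 5 (< 10).  P08: S/N = 9.9.
    # P09: no T=0 observation.  P10: clean, S/N exactly 10 (passes).
    design <- data.frame(sample_id = c("t0", "t48"),
                         condition = c("baseline", "normal_g"),
                         time_h = c(0, 48), replicate = c(1L, 1L),
                         is_qc_pool = FALSE)
    base <- expand.grid(peptide_sequence = sprintf("P%02d", 1:10),
                        sample_id = c("t0", "t48"), stringsAsFactors = FALSE)
    base$protein_accession <- "PR1"
    base$intensity_light <- 1000
    base$intensity_heavy <- ifelse(base$sample_id == "t0", 0, 400)
    base$rt_light <- 30
    base$rt_heavy <- 30.1
    base$msms_identified_light <- TRUE
    base$msms_identified_heavy <- base$sample_id == "t48"
    base$noise_heavy <- 50               # S/N = 20 by default
    base$n_labeled_residues <- 1L
    base$isotopologue_hh <- NA_real_
    base$isotopologue_hl <- NA_real_
    fix <- function(p, col, val, sample = NULL) {
        i <- base$peptide_sequence == p
        if (!is.null(sample)) i <- i & base$sample_id == sample
        base[i, col] <<- val
    }
    fix("P03", "msms_identified_heavy", FALSE)
    fix("P04", "msms_identified_light", FALSE)
    fix("P05", "rt_heavy", 30.6, sample = "t48")
    fix("P06", "rt_heavy", 32)
    fix("P07", "noise_heavy", 200)       # S/N 5
    fix("P08", "noise_heavy", 1000 / 9.9)
    fix("P10", "noise_heavy", 100)       # S/N exactly 10: retained
    base <- base[!(base$peptide_sequence == "P09" & base$sample_id == "t0"), ]
    list(records = base, design = design)
}

test_that("curation enumerates the three rejection criteria", {
    fx <- curationFixture()
    out <- curatePeptides(fx$records, fx$design)
    audit <- out$audit[order(out$audit$peptide_sequence), ]
    retained <- audit$peptide_sequence[audit$retained]
    expect_setequal(retained, c("P01", "P02", "P10"))
    reason <- setNames(audit$rejection_reasons, audit$peptide_sequence)
    expect_equal(unname(reason["P03"]), "not_dual_identified")
    expect_equal(unname(reason["P04"]), "not_dual_identified")
    expect_equal(unname(reason["P05"]), "rt_mismatch")
    expect_equal(unname(reason["P06"]), "rt_mismatch")
    expect_equal(unname(reason["P07"]), "snr_low")
    expect_equal(unname(reason["P08"]), "snr_low")
    expect_equal(unname(reason["P09"]), "snr_low")  # criterion 3 unevaluable
    expect_true(all(audit$rejection_reasons[audit$retained] == ""))
})

test_that("tightening curation thresholds never enlarges the retained set", {
    sim <- simulateExperiment(simulationConfig(nProteins = 60), seed = 13)
    loose <- pipelineConfig(rt_tolerance_min = 0.5, snr_min = 10)
    tight1 <- pipelineConfig(rt_tolerance_min = 0.2, snr_min = 10)
    tight2 <- pipelineConfig(rt_tolerance_min = 0.5, snr_min = 50)
    keep <- function(cfg) {
        a <- curatePeptides(sim$peptides, sim$design, cfg)$audit
        a$peptide_sequence[a$retained]
    }
    k0 <- keep(loose)
    expect_true(all(keep(tight1) %in% k0))
    expect_true(all(keep(tight2) %in% k0))
})

test_that("pool RIA estimator inverts the binomial identity", {
    design <- data.frame(sample_id = c("a", "b"),
                         condition = c("normal_g", "micro_g"),
                         time_h = c(48, 48), replicate = c(1L, 1L),
                         is_qc_pool = FALSE)
    mk <- function(hh, hl, sid) data.frame(
        peptide_sequence = "EATNPPIIQEEKPK", protein_accession = "PDIA3",
        sample_id = sid, intensity_light = 10, intensity_heavy = hh,
        rt_light = 55, rt_heavy = 55, msms_identified_light = TRUE,
        msms_identified_heavy = TRUE, noise_heavy = 1,
        n_labeled_residues = 2L, isotopologue_hh = hh, isotopologue_hl = hl)
    # I_HH = 2, I_HL = 1 forces r = 2*2 / (2*2 + 1) = 0.8
    recs <- rbind(mk(2, 1, "a"), mk(5, 0, "b"))
    est <- estimatePoolRIA(recs, design)
    expect_equal(est$per_sample$r_hat[est$per_sample$sample_id == "a"], 0.8)
    expect_equal(est$per_sample$r_hat[est$per_sample$sample_id == "b"], 1.0)
})

test_that("pool RIA recovery improves with molecule count", {
    # consistency: r_hat -> r as the simulated molecule count grows
    err <- vapply(c(100, 10000, 1e6), function(n) {
        rh <- vapply(1:20, function(s) {
            iso <- simulateDoubleKPeptide(0.95, n, 0.7, seed = 100 + s)
            2 * iso[["I_HH"]] / (2 * iso[["I_HH"]] + iso[["I_HL"]])
        }, numeric(1))
        abs(mean(rh) - 0.95)
    }, numeric(1))
    expect_equal(err, sort(err, decreasing = TRUE))
    expect_lt(err[3], 1e-3)
})

test_that("identical RIA distributions give p near 1, distinct give small p", {
    design <- studyDesign()
    bio <- design[!design$is_qc_pool & design$time_h == 48, ]
    mkria <- function(vals) {
        data.frame(peptide_sequence = sprintf("P%03d", seq_along(vals)),
                   protein_accession = "PR1",
                   sample_id = rep(bio$sample_id, length.out = length(vals)),
                   ria = vals, curated = TRUE, rejection_reasons = "")
    }
    v <- seq(0.2, 0.8, length.out = 60)
    ria <- rbind(
        within(mkria(v), sample_id <- rep(bio$sample_id[bio$condition ==
            "normal_g"], length.out = 60)),
        within(mkria(v), sample_id <- rep(bio$sample_id[bio$condition ==
            "micro_g"], length.out = 60)))
    cmp <- compareRIAGroups(ria, design, times = 48)
    expect_equal(cmp$tests$p_value, 1, tolerance = 1e-12)
    expect_equal(cmp$summaries$median, rep(median(v), 2))
})

test_that("slowed micro_g turnover is detected in study-shaped data", {
    sim <- simulateExperiment(
        simulationConfig(nProteins = 60, rateMultiplier = 0.4), seed = 17)
    cur <- curatePeptides(sim$peptides, sim$design)
    ria <- riaTable(sim$peptides, cur$audit)
    cmp <- compareRIAGroups(ria, sim$design)
    tests <- cmp$tests
    expect_lt(tests$p_value[tests$time_h == 120], 1e-6)
    sm <- cmp$summaries
    for (t in c(48, 120)) {
        expect_lt(sm$median[sm$time_h == t & sm$condition == "micro_g"],
                  sm$median[sm$time_h == t & sm$condition == "normal_g"])
    }
    # while the precursor pool itself shows no condition difference
    est <- estimatePoolRIA(sim$peptides, sim$design)
    expect_equal(unname(diff(range(est$by_condition))), 0, tolerance = 0.02)
})

test_that("turnover-rate fitting inverts the generating model", {
    t <- c(0, 12, 24, 48, 72, 120)
    ria <- riaExpected(t, 0.01, 1)
    fit <- fitTurnoverRate(t, ria, r = 1)
    expect_equal(fit$k_hat, 0.01, tolerance = 1e-4)
    expect_true(fit$converged)

    # 5% multiplicative noise: median relative error under 10% over 20 seeds
    relerr <- vapply(1:20, function(s) {
        noisy <- withr::with_seed(200 + s,
            riaExpected(t, 0.01, 0.95) * rlnorm(length(t), 0, 0.05))
        f <- fitTurnoverRate(t, pmin(noisy, 0.95), r = 0.95)
        abs(f$k_hat - 0.01) / 0.01
    }, numeric(1))
    expect_lt(median(relerr), 0.10)

    # saturated series drives k to the bound and is flagged
    sat <- fitTurnoverRate(c(0, 12, 48, 120), c(0, 0.9, 0.9, 0.9), r = 0.9)
    expect_true(sat$at_bound)

    # an all-zero series cannot be fit
    zero <- fitTurnoverRate(c(0, 12, 48), c(0, 0, 0), r = 0.9)
    expect_false(zero$converged)
    expect_true(is.na(zero$k_hat))

    expect_error(fitTurnoverRate(c(0, 12), c(0, 0.1), r = 0.9), ">= 3 time")
})

test_that("per-protein rate recovery works on simulated data", {
    cfg <- simulationConfig(nProteins = 40, peptidesPerProtein = c(3, 6),
                            noiseCV = 0.05, missingRateBase = 0.01,
                            rtOutlierRate = 0, snrLogSD = 0.3)
    sim <- simulateExperiment(cfg, seed = 19)
    cur <- curatePeptides(sim$peptides, sim$design)
    ria <- riaTable(sim$peptides, cur$audit)
    fits <- fitTurnoverRates(ria, sim$design, r = 0.95,
                             condition = "normal_g")
    truth <- sim$truth[match(fits$protein_accession,
                             sim$truth$protein_accession), ]
    relerr <- abs(fits$k_hat - truth$turnover_rate_k) / truth$turnover_rate_k
    expect_lt(median(relerr, na.rm = TRUE), 0.25)
})
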