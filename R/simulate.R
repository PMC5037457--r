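#' Expected relative isotope abundance under first-order turnover
#'
#' One-pool kinetics with an instantaneous switch to heavy media at `t = 0`:
#' newly synthesized protein draws lysine/arginine from a precursor pool whose
#' heavy fraction is `r`, and protein is replaced with first-order rate
#' constant `k`, so `RIA(t) = r * (1 - exp(-k * t))`. The curve starts at 0,
#' is non-decreasing in `t`, and saturates at the pool RIA `r` (below 1 when
#' labeling is incomplete).
#'
#' @param t time since label switch, hours (vectorized, `>= 0`).
#' @param k first-order turnover rate constant, per hour (`> 0`).
#' @param r precursor-pool relative isotope abundance, fraction in (0, 1].
#' @return expected peptide RIA, same length as `t`.
#' @export
riaExpected <- function(t, k, r) {
    if (any(t < 0)) stop("time must be non-negative")
    if (any(k <= 0)) stop("turnover rate k must be positive")
    if (any(r <= 0 | r > 1)) stop("pool RIA r must be in (0, 1]")
    r * (1 - exp(-k * t))
}

#' Simulation configuration
#'
#' Defaults emulate the study design: two gravity conditions (`normal_g`,
#' `micro_g`) at 12/48/120 h with 3 biological replicates each, 3 baseline
#' (0 h) samples, 4 QC-pool injections, a heavy-label switch at t = 0, and
#' one doubly lysine-labeled reporter peptide per sample. Ground truth
#' (per-protein turnover rate, trend class, fold change; global pool RIA) is
#' returned alongside the data. Trend-class fractions default to the 44/25/31%
#' no-change / similar-change / dissimilar-change split and the microgravity
#' turnover-rate multiplier to 0.4 (a marked slowing).
#'
#' @param nProteins number of simulated proteins.
#' @param peptidesPerProtein integer range (min, max) of peptides per protein.
#' @param timePoints post-switch sampling times, hours.
#' @param nReplicates biological replicates per condition x time.
#' @param nBaseline baseline (0 h) samples.
#' @param nQCPools QC-pool injections (mean of all biological samples plus
#'   technical noise).
#' @param poolRIA precursor-pool heavy fraction `r` (< 1: incomplete labeling).
#' @param halfLifeMedianH median protein half-life, hours; `k = ln(2) / t1/2`.
#' @param halfLifeLogSD log-scale SD of the half-life distribution (0 gives a
#'   homogeneous-turnover population).
#' @param rateMultiplier multiplier on `k` under `micro_g` (< 1 slows turnover).
#' @param trendFractions fractions of proteins in the `no_change`,
#'   `similar_change`, `dissimilar_change` abundance classes (sums to 1).
#' @param similarFC linear fold change at 120 h shared by both conditions for
#'   `similar_change` proteins.
#' @param dissimilarFC micro_g-specific linear fold change at 120 h for
#'   `dissimilar_change` proteins.
#' @param noiseCV biological/measurement CV of channel intensities.
#' @param qcNoiseCV technical CV of QC-pool injections.
#' @param missingRateBase channel missingness probability at the median
#'   intensity (missingness is logistic in log-intensity, low-abundance
#'   peptides drop out preferentially).
#' @param missingSlope logistic slope of missingness per decade of intensity.
#' @param msmsProbMid MS/MS identification probability at the median intensity.
#' @param msmsSlope logistic slope of identification per decade of intensity.
#' @param rtSDMin retention-time jitter SD, minutes, per channel.
#' @param rtOutlierRate fraction of peptides with a misaligned heavy feature
#'   (RT shift of 0.6-3 min; these should fail curation).
#' @param snrMedian median true heavy-channel signal-to-noise at T = 0.
#' @param snrLogSD log-scale SD of the S/N distribution.
#' @param reporterHalfLifeH half-life of the reporter peptide's parent protein.
#' @param reporterMolecules molecule count for the reporter's isotopologue
#'   multinomial sampling.
#' @return a named list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nProteins = 300L,
                             peptidesPerProtein = c(1L, 10L),
                             timePoints = c(12, 48, 120),
                             nReplicates = 3L, nBaseline = 3L, nQCPools = 4L,
                             poolRIA = 0.95,
                             halfLifeMedianH = 60, halfLifeLogSD = 0.75,
                             rateMultiplier = 0.4,
                             trendFractions = c(no_change = 0.44,
                                                similar_change = 0.25,
                                                dissimilar_change = 0.31),
                             similarFC = 2, dissimilarFC = 3,
                             noiseCV = 0.20, qcNoiseCV = 0.05,
                             missingRateBase = 0.05, missingSlope = 1.5,
                             msmsProbMid = 0.9, msmsSlope = 2,
                             rtSDMin = 0.05, rtOutlierRate = 0.03,
                             snrMedian = 50, snrLogSD = 1.0,
                             reporterHalfLifeH = 40,
                             reporterMolecules = 10000L) {
    cfg <- as.list(environment())
    if (cfg$nProteins < 1) stop("nProteins must be >= 1")
    if (cfg$nReplicates < 1) stop("nReplicates must be >= 1")
    if (cfg$nBaseline < 1) stop("nBaseline must be >= 1")
    if (cfg$poolRIA <= 0 || cfg$poolRIA > 1) stop("poolRIA must be in (0, 1]")
    if (cfg$rateMultiplier <= 0) stop("rateMultiplier must be positive")
    if (length(cfg$trendFractions) != 3 ||
        abs(sum(cfg$trendFractions) - 1) > 1e-8)
        stop("trendFractions must be three fractions summing to 1")
    if (any(cfg$timePoints <= 0)) stop("timePoints must be positive hours")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate isotopologue intensities of a doubly lysine-labeled peptide
#'
#' Protein synthesized before the label switch is entirely light/light (LL).
#' For protein synthesized after the switch each of the two lysines is heavy
#' independently with probability `r`, so new molecules split
#' HH : HL : LL = r^2 : 2r(1-r) : (1-r)^2. The heavy/heavy vs heavy/light
#' ratio therefore reports the precursor pool alone, independent of turnover.
#'
#' @param r precursor-pool heavy fraction in \[0, 1\].
#' @param totalMolecules total molecule count to allocate.
#' @param newFraction fraction of molecules synthesized after the switch
#'   (in \[0, 1\]).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return named numeric vector `c(I_HH, I_HL, I_LL)` of molecule counts.
#' @export
simulateDoubleKPeptide <- function(r, totalMolecules, newFraction,
                                   seed = NULL) {
    if (r < 0 || r > 1) stop("pool RIA r must be in [0, 1]")
    if (newFraction < 0 || newFraction > 1)
        stop("newFraction must be in [0, 1]")
    withSeed(seed, {
        total <- as.integer(round(totalMolecules))
        nNew <- stats::rbinom(1L, total, newFraction)
        split <- stats::rmultinom(1L, nNew,
                                  c(r^2, 2 * r * (1 - r), (1 - r)^2))[, 1]
        c(I_HH = split[[1]], I_HL = split[[2]],
          I_LL = split[[3]] + (total - nNew))
    })
}

#' Simulate a dynamic SILAC experiment with known ground truth
#'
#' Generates the canonical long peptide table, a design table and a truth
#' table. Per-protein total abundance follows
#' baseline x trend fold change x log-normal noise; the heavy fraction of
#' each peptide follows [riaExpected()] with the protein's rate constant
#' (multiplied by `rateMultiplier` under `micro_g`); channel missingness and
#' MS/MS identification are logistic in log-intensity; retention times carry
#' independent Gaussian jitter per channel; QC pools are the per-peptide mean
#' of all biological samples plus technical noise; one doubly lysine-labeled
#' reporter peptide per sample carries isotopologue intensities with expected
#' proportions r^2 : 2r(1-r) : (1-r)^2 among post-switch synthesis.
#' Identical seeds give identical outputs.
#'
#' @param config a [simulationConfig()] list.
#' @param seed integer seed.
#' @return a list of class `"SilacSimulation"` with elements `peptides`
#'   (canonical peptide table), `design`, `truth` (one row per protein:
#'   accession, baseline abundance, `k` per hour, rate multiplier, fold
#'   change at 120 h in micro_g, trend class) and `config`; the pool RIA is
#'   `attr(truth, "pool_ria")`.
#' @export
simulateExperiment <- function(config = simulationConfig(), seed = 1L) {
    stopifnot(inherits(config, "SimulationConfig"))
    withSeed(seed, {
        sim <- simulateExperimentImpl(config)
    })
    sim$seed <- as.integer(seed)
    class(sim) <- "SilacSimulation"
    sim
}

simulateExperimentImpl <- function(cfg) {
    design <- buildDesign(cfg)
    bio <- design[!design$is_qc_pool, ]

    ## --- ground truth -------------------------------------------------
    n <- cfg$nProteins
    counts <- diff(round(cumsum(c(0, cfg$trendFractions)) * n))
    trend <- sample(rep(c("no_change", "similar_change", "dissimilar_change"),
                        counts))
    acc <- sprintf("PROT%04d", seq_len(n))
    k <- stats::rlnorm(n, log(log(2) / cfg$halfLifeMedianH), cfg$halfLifeLogSD)
    baseAb <- stats::rlnorm(n, log(1e6), 1.2)
    dir <- sample(c(1, -1), n, replace = TRUE)
    fc120 <- ifelse(trend == "no_change", 1,
             ifelse(trend == "similar_change", cfg$similarFC^dir,
                    cfg$dissimilarFC^dir))
    truth <- data.frame(protein_accession = acc,
                        baseline_abundance = baseAb,
                        turnover_rate_k = k,
                        condition_rate_multiplier = cfg$rateMultiplier,
                        abundance_fc_120h = fc120,
                        trend_class = trend,
                        stringsAsFactors = FALSE)

    ## --- peptide-level fixed properties -------------------------------
    nPep <- sample(seq(cfg$peptidesPerProtein[1], cfg$peptidesPerProtein[2]),
                   n, replace = TRUE)
    pidx <- rep(seq_len(n), nPep)
    m <- length(pidx)
    pep <- data.frame(protein = acc[pidx],
                      sequence = randomPeptideSequences(m),
                      share = stats::rlnorm(m, 0, 1),
                      rt_ref = stats::runif(m, 10, 100),
                      snr_true = stats::rlnorm(m, log(cfg$snrMedian),
                                               cfg$snrLogSD),
                      rt_shift = ifelse(stats::runif(m) < cfg$rtOutlierRate,
                                        stats::runif(m, 0.6, 3), 0),
                      k = k[pidx], base = baseAb[pidx], trend = trend[pidx],
                      dir = dir[pidx], stringsAsFactors = FALSE)

    ## --- peptide x biological-sample grid ------------------------------
    g <- expand.grid(p = seq_len(m), s = seq_len(nrow(bio)),
                     KEEP.OUT.ATTRS = FALSE)
    cond <- bio$condition[g$s]
    t_h <- bio$time_h[g$s]
    kEff <- pep$k[g$p] * ifelse(cond == "micro_g", cfg$rateMultiplier, 1)
    ria <- ifelse(t_h > 0, riaExpected(pmax(t_h, 0), kEff, cfg$poolRIA), 0)
    tmult <- trendMultiplier(pep$trend[g$p], pep$dir[g$p], cond, t_h,
                             cfg$similarFC, cfg$dissimilarFC)
    total <- pep$base[g$p] * pep$share[g$p] * tmult
    iH <- total * ria * rlnormMean1(length(total), cfg$noiseCV)
    iL <- total * (1 - ria) * rlnormMean1(length(total), cfg$noiseCV)

    ## --- QC pools: per-peptide mean over biological samples -----------
    qc <- design[design$is_qc_pool, ]
    meanH <- rowsumMean(iH, g$p, m)
    meanL <- rowsumMean(iL, g$p, m)
    nQ <- nrow(qc)
    qg <- expand.grid(p = seq_len(m), s = seq_len(nQ), KEEP.OUT.ATTRS = FALSE)
    qH <- meanH[qg$p] * rlnormMean1(nrow(qg), cfg$qcNoiseCV)
    qL <- meanL[qg$p] * rlnormMean1(nrow(qg), cfg$qcNoiseCV)

    rows <- rbind(
        assembleRows(pep, g$p, bio$sample_id[g$s], iL, iH, cfg),
        assembleRows(pep, qg$p, qc$sample_id[qg$s], qL, qH, cfg))

    ## --- doubly lysine-labeled reporter peptide ------------------------
    rep_rows <- reporterRows(cfg, design, bio)
    truth <- rbind(truth, data.frame(
        protein_accession = "PROT_PDIA3",
        baseline_abundance = 100 * cfg$reporterMolecules,
        turnover_rate_k = log(2) / cfg$reporterHalfLifeH,
        condition_rate_multiplier = cfg$rateMultiplier,
        abundance_fc_120h = 1, trend_class = "no_change",
        stringsAsFactors = FALSE))
    attr(truth, "pool_ria") <- cfg$poolRIA
    peptides <- rbind(rows, rep_rows)
    rownames(peptides) <- NULL
    list(peptides = peptides, design = design, truth = truth, config = cfg)
}

buildDesign <- function(cfg) {
    base <- data.frame(sample_id = sprintf("base_0h_r%d", seq_len(cfg$nBaseline)),
                       condition = "baseline", time_h = 0,
                       replicate = seq_len(cfg$nBaseline), is_qc_pool = FALSE,
                       stringsAsFactors = FALSE)
    bio <- expand.grid(replicate = seq_len(cfg$nReplicates),
                       time_h = cfg$timePoints,
                       condition = c("normal_g", "micro_g"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    bio <- data.frame(sample_id = sprintf("%s_%gh_r%d",
                                          sub("_g$", "g", bio$condition),
                                          bio$time_h, bio$replicate),
                      condition = bio$condition, time_h = bio$time_h,
                      replicate = bio$replicate, is_qc_pool = FALSE,
                      stringsAsFactors = FALSE)
    qc <- data.frame(sample_id = sprintf("QC_pool_%d", seq_len(cfg$nQCPools)),
                     condition = "baseline", time_h = 0,
                     replicate = seq_len(cfg$nQCPools), is_qc_pool = TRUE,
                     stringsAsFactors = FALSE)
    design <- rbind(base, bio, qc)
    validateDesign(design)
    design
}

trendMultiplier <- function(trend, dir, cond, t_h, similarFC, dissimilarFC) {
    frac <- t_h / 120
    out <- rep(1, length(trend))
    i <- trend == "similar_change"
    out[i] <- similarFC^(dir[i] * frac[i])
    i <- trend == "dissimilar_change" & cond == "micro_g"
    out[i] <- dissimilarFC^(dir[i] * frac[i])
    out
}

rowsumMean <- function(x, index, n) {
    s <- rowsum(x, index)
    cnt <- rowsum(rep(1, length(index)), index)
    out <- numeric(n)
    out[as.integer(rownames(s))] <- s / cnt
    out
}

randomPeptideSequences <- function(m) {
    aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R internally
    repeat {
        len <- sample(7:17, m, replace = TRUE)
        body <- vapply(len, function(l)
            paste(sample(aa, l, replace = TRUE), collapse = ""), character(1))
        seqs <- paste0(body, sample(c("K", "R"), m, replace = TRUE))
        if (!anyDuplicated(seqs)) return(seqs)
    }
}

# Channel-level missingness, MS/MS flags, RTs and noise for a block of rows.
assembleRows <- function(pep, pIdx, sampleId, iL, iH, cfg) {
    nr <- length(pIdx)
    med <- stats::median(c(iL[iL > 0], iH[iH > 0]))
    missProb <- function(x) ifelse(x <= 0, 0,
        stats::plogis(stats::qlogis(cfg$missingRateBase) -
                      cfg$missingSlope * (log10(x) - log10(med))))
    idProb <- function(x) ifelse(x <= 0, 0,
        stats::plogis(stats::qlogis(cfg$msmsProbMid) +
                      cfg$msmsSlope * (log10(x) - log10(med))))
    missL <- stats::runif(nr) < missProb(iL)
    missH <- stats::runif(nr) < missProb(iH)
    idL <- !missL & stats::runif(nr) < idProb(iL)
    idH <- !missH & iH > 0 & stats::runif(nr) < idProb(iH)
    rtL <- pep$rt_ref[pIdx] + stats::rnorm(nr, 0, cfg$rtSDMin)
    rtH <- pep$rt_ref[pIdx] + pep$rt_shift[pIdx] +
        stats::rnorm(nr, 0, cfg$rtSDMin)
    noiseH <- pep$base[pIdx] * pep$share[pIdx] / pep$snr_true[pIdx] *
        rlnormMean1(nr, 0.1)
    data.frame(peptide_sequence = pep$sequence[pIdx],
               protein_accession = pep$protein[pIdx],
               sample_id = sampleId,
               intensity_light = ifelse(missL, NA_real_, iL),
               intensity_heavy = ifelse(missH, NA_real_, iH),
               rt_light = ifelse(missL, NA_real_, rtL),
               rt_heavy = ifelse(missH, NA_real_, rtH),
               msms_identified_light = idL,
               msms_identified_heavy = idH,
               noise_heavy = noiseH,
               n_labeled_residues = 1L,
               isotopologue_hh = NA_real_, isotopologue_hl = NA_real_,
               stringsAsFactors = FALSE)
}

reporterRows <- function(cfg, design, bio) {
    kRep <- log(2) / cfg$reporterHalfLifeH
    scale <- 100
    one <- function(sid, cond, t_h) {
        kEff <- kRep * if (identical(cond, "micro_g")) cfg$rateMultiplier else 1
        newFrac <- 1 - exp(-kEff * t_h)
        iso <- simulateDoubleKPeptide(cfg$poolRIA, cfg$reporterMolecules,
                                      newFrac)
        data.frame(peptide_sequence = "EATNPPIIQEEKPK",
                   protein_accession = "PROT_PDIA3",
                   sample_id = sid,
                   intensity_light = iso[["I_LL"]] * scale,
                   intensity_heavy = iso[["I_HH"]] * scale,
                   rt_light = 55, rt_heavy = 55,
                   msms_identified_light = TRUE,
                   msms_identified_heavy = iso[["I_HH"]] > 0,
                   noise_heavy = cfg$reporterMolecules * scale / 100,
                   n_labeled_residues = 2L,
                   isotopologue_hh = iso[["I_HH"]] * scale,
                   isotopologue_hl = iso[["I_HL"]] * scale,
                   stringsAsFactors = FALSE)
    }
    rows <- do.call(rbind, lapply(seq_len(nrow(bio)), function(i)
        one(bio$sample_id[i], bio$condition[i], bio$time_h[i])))
    qc <- design[design$is_qc_pool, ]
    if (nrow(qc)) {
        pooled <- colMeans(rows[, c("intensity_light", "intensity_heavy",
                                    "isotopologue_hh", "isotopologue_hl")])
        qcRows <- do.call(rbind, lapply(qc$sample_id, function(sid) {
            r <- rows[1, ]
            r$sample_id <- sid
            jit <- rlnormMean1(4, cfg$qcNoiseCV)
            r$intensity_light <- pooled[["intensity_light"]] * jit[1]
            r$intensity_heavy <- pooled[["intensity_heavy"]] * jit[2]
            r$isotopologue_hh <- pooled[["isotopologue_hh"]] * jit[3]
            r$isotopologue_hl <- pooled[["isotopologue_hl"]] * jit[4]
            r
        }))
        rows <- rbind(rows, qcRows)
    }
    rows
}

#' Simulate a gene-set collection over a gene universe
#'
#' Random sets drawn uniformly from `genes`; optionally a number of sets are
#' biased toward a subset of interest (e.g. truly perturbed genes) so that
#' enrichment has signal to find.
#'
#' @param genes character vector, the gene universe.
#' @param nSets number of sets.
#' @param sizeRange set-size range (min, max).
#' @param enrichedIn optional character vector of genes to over-represent.
#' @param nEnriched number of sets biased toward `enrichedIn`.
#' @param enrichedProp proportion of a biased set drawn from `enrichedIn`.
#' @param seed integer seed (`NULL`: current RNG stream).
#' @return named list of character vectors ([readGMT()] shape).
#' @export
simulateGeneSets <- function(genes, nSets = 25L, sizeRange = c(10L, 40L),
                             enrichedIn = NULL, nEnriched = 0L,
                             enrichedProp = 0.75, seed = NULL) {
    withSeed(seed, {
        sets <- list()
        for (i in seq_len(nSets)) {
            sz <- sample(seq(sizeRange[1], min(sizeRange[2], length(genes))), 1)
            if (i <= nEnriched && length(enrichedIn)) {
                nIn <- min(round(enrichedProp * sz), length(enrichedIn))
                g <- unique(c(sample(enrichedIn, nIn),
                              sample(genes, sz - nIn)))
            } else g <- sample(genes, sz)
            attr(g, "description") <- sprintf("simulated gene set %d", i)
            sets[[sprintf("SET_%03d", i)]] <- g
        }
        sets
    })
}

#' @export
print.SilacSimulation <- function(x, ...) {
    cat(sprintf(
        "SilacSimulation: %d peptide records, %d samples, %d proteins (seed %d)\n",
        nrow(x$peptides), nrow(x$design), nrow(x$truth), x$seed))
    cat(sprintf("  pool RIA r = %.3f; micro_g rate multiplier = %.2f\n",
                attr(x$truth, "pool_ria"),
                x$config$rateMultiplier))
    print(table(x$truth$trend_class))
    invisible(x)
}
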