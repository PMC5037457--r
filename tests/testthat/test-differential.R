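test_that("one-way ANOVA matches the hand F formula", {
    # textbook 3-group example
    y <- c(6, 8, 4, 5, 3, 4,   8, 12, 9, 11, 6, 8,   13, 9, 11, 8, 7, 12)
    g <- rep(c("a", "b", "c"), each = 6)
    grand <- mean(y)
    ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
    ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    Fstat <- (ssb / 2) / (ssw / 15)
    pHand <- pf(Fstat, 2, 15, lower.tail = FALSE)
    expect_equal(weightedAnova(y, g), pHand, tolerance = 1e-12)

    # clear separation drives p below 1e-6
    expect_lt(weightedAnova(c(0, 0.01, -0.01, 5, 5.01, 4.99),
                            rep(c("a", "b"), each = 3)), 1e-6)

    # insufficient replication is flagged, not silently computed
    expect_warning(p <- weightedAnova(c(1, 2), c("a", "b")), "insufficient")
    expect_true(is.na(p))
})

test_that("inverse-variance weighting changes the fit as WLS", {
    set.seed(5)
    y <- rnorm(12); g <- rep(c("a", "b"), each = 6)
    w <- c(rep(10, 6), rep(0.1, 6))
    pW <- weightedAnova(y, g, weights = w)
    ref <- anova(lm(y ~ factor(g), weights = w))[["Pr(>F)"]][1]
    expect_equal(pW, ref, tolerance = 1e-12)
})

test_that("ANOVA p-values are calibrated on null groups", {
    set.seed(8)
    pv <- replicate(500, weightedAnova(rnorm(12), rep(1:4, each = 3)))
    frac <- mean(pv < 0.05)
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("p-value adjustment follows Bonferroni and BH step-up", {
    expect_equal(adjustPvalues(rep(0.01, 5), "bonferroni"),
                 rep(0.05, 5))
    # hand step-up: (0.01,0.02,0.03,0.04)*4/(1,2,3,4) = .04,.04,.04,.04
    expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
                 rep(0.04, 4))
    expect_equal(adjustPvalues(numeric(0), "bh"), numeric(0))
    expect_error(adjustPvalues(c(0.1, 1.2), "bh"), "\\[0, 1\\]")
    # Bonferroni dominates raw p; BH bounded by 1 and order-preserving
    set.seed(2)
    p <- runif(50)
    expect_true(all(adjustPvalues(p, "bonferroni") >= p))
    bh <- adjustPvalues(p, "bh")
    expect_true(all(bh <= 1))
    expect_true(all(diff(bh[order(p)]) >= 0))  # monotone in the order stats
})

test_that("signed fold change keeps |FC| >= 1 with direction in the sign", {
    expect_equal(signedFoldChange(1), 2)
    expect_equal(signedFoldChange(-1), -2)
    expect_equal(signedFoldChange(0), 1)
    expect_true(all(abs(signedFoldChange(rnorm(100))) >= 1))
})

test_that("the four-criterion filter enumerates pass/fail reasons", {
    cfg <- pipelineConfig()
    toy <- data.frame(
        protein_accession = sprintf("PR%d", 1:7),
        p_raw      = c(0.01, 0.01, 0.20, 0.01, 0.01, 0.049, 0.01),
        fc_signed  = c(2.0, 1.4, 2.0, -3.0, 2.0, -1.51, 1.6),
        n_peptides = c(3L, 3L, 3L, 1L, 2L, 2L, 2L),
        qc_cv      = c(0.10, 0.10, 0.10, 0.10, 0.25, 0.19, NA))
    out <- differentialFilter(toy, cfg)
    # hand enumeration: PR1 passes; PR2 fails FC (1.4 < 1.5); PR3 fails p;
    # PR4 fails peptides; PR5 fails CV; PR6 passes (all strict); PR7 fails
    # on undefined CV
    expect_equal(out$passes_filter,
                 c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
    expect_equal(sum(out$passes_filter), 2)
    expect_equal(out$fail_reasons[2], "fold_change")
    expect_equal(out$fail_reasons[3], "p_value")
    expect_equal(out$fail_reasons[4], "min_peptides")
    expect_equal(out$fail_reasons[5], "qc_cv")
    expect_equal(out$fail_reasons[7], "qc_cv_undefined")
    expect_equal(out$direction[c(1, 4)], c("up", "down"))
})

test_that("filter counts never grow as thresholds tighten", {
    sim <- simulateExperiment(simulationConfig(nProteins = 150), seed = 23)
    q <- quantifyAbundance(sim$peptides, sim$design)
    de <- differentialExpression(q$proteinMatrix, 120)
    n0 <- sum(de$passes_filter)
    for (cfg in list(pipelineConfig(p_cut = 0.01),
                     pipelineConfig(fc_cut = 2),
                     pipelineConfig(min_peptides = 4),
                     pipelineConfig(cv_cut = 0.10))) {
        expect_lte(sum(differentialFilter(de, cfg)$passes_filter), n0)
    }
    # type-I containment: adding the FC criterion can only shrink the set
    expect_lte(sum(de$p_raw < 0.05 & abs(de$fc_signed) > 1.5),
               sum(de$p_raw < 0.05))
})

test_that("trend classification follows the decision rule", {
    design <- studyDesign()
    mkpm <- function(f) {
        # f(condition, time) -> mean log2 value
        vals <- vapply(seq_len(nrow(design)), function(i) {
            d <- design[i, ]
            if (d$is_qc_pool) return(10)
            f(d$condition, d$time_h) + c(-0.01, 0, 0.01)[d$replicate %% 3 + 1]
        }, numeric(1))
        m <- matrix(vals, 1, nrow(design),
                    dimnames = list("PR1", design$sample_id))
        ProteinMatrix(m, design, nPeptides = 2L, qcCV = 0.05)
    }
    flat <- mkpm(function(cc, t) 10)
    expect_equal(classifyTrends(flat)$classes$trend_class, "no_change")

    rising <- mkpm(function(cc, t) 10 + t / 60)  # identical 2-fold per 60 h
    expect_equal(classifyTrends(rising)$classes$trend_class, "similar_change")

    diverging <- mkpm(function(cc, t) 10 + (cc == "micro_g") * t / 60)
    expect_equal(classifyTrends(diverging)$classes$trend_class,
                 "dissimilar_change")
})

test_that("trend classes partition the classifiable proteins", {
    sim <- simulateExperiment(simulationConfig(nProteins = 150), seed = 29)
    q <- quantifyAbundance(sim$peptides, sim$design)
    tr <- classifyTrends(q$proteinMatrix)
    done <- !is.na(tr$classes$trend_class)
    expect_equal(sum(table(tr$classes$trend_class[done])), sum(done))
    expect_equal(sum(tr$fractions), 1, tolerance = 1e-12)
})

test_that("PCA scores, variance bookkeeping and QC-pool geometry behave", {
    sim <- simulateExperiment(simulationConfig(nProteins = 150), seed = 31)
    q <- quantifyAbundance(sim$peptides, sim$design)
    z <- suppressWarnings(zscoreMatrix(q$proteinMatrix))
    pca <- pcaQC(z, sim$design)
    expect_equal(sum(pca$explained), 1, tolerance = 1e-10)

    # duplicated samples land on identical coordinates
    z2 <- cbind(z, dup = z[, 1])
    design2 <- rbind(sim$design,
                     data.frame(sample_id = "dup", condition = "baseline",
                                time_h = 0, replicate = 9L,
                                is_qc_pool = FALSE))
    pca2 <- pcaQC(z2, design2)
    expect_equal(unname(unlist(pca2$scores[pca2$scores$sample_id == "dup",
                                           c("PC1", "PC2")])),
                 unname(unlist(pca2$scores[1, c("PC1", "PC2")])),
                 tolerance = 1e-8)

    # QC pools sit nearer the grand centroid than biological samples
    sc <- pca$scores
    ctr <- colMeans(sc[, c("PC1", "PC2")])
    dist2 <- sqrt((sc$PC1 - ctr[1])^2 + (sc$PC2 - ctr[2])^2)
    expect_lt(mean(dist2[sc$group == "QC_pool"]),
              mean(dist2[sc$group != "QC_pool"]))

    # ellipses exist per group with positive axes
    expect_true(all(c("0 h", "12 h", "48 h", "120 h", "QC_pool") %in%
                    pca$ellipses$group))
    expect_true(all(pca$ellipses$semi_major >= pca$ellipses$semi_minor))
    expect_error(pcaQC(z[, 1:2], sim$design), "3 samples")
})
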