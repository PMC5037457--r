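test_that("accession-to-symbol collapse reproduces collision arithmetic", {
    # 478 accessions with two symbol collisions (one absorbing 4 accessions,
    # one absorbing 2) collapse onto 478 - 3 - 1 = 474 distinct symbols
    accs <- sprintf("ACC%03d", 1:478)
    syms <- sprintf("GENE%03d", 1:478)
    syms[2:4] <- "GENE001"      # 3 extra accessions onto GENE001
    syms[10] <- "GENE009"       # 1 extra onto GENE009
    map <- setNames(syms, accs)
    scores <- setNames(seq(-1, 1, length.out = 478), accs)
    collapsed <- mapAndCollapse(scores, map)
    expect_equal(length(collapsed), 474)
    # collapse keeps the most extreme score
    expect_equal(unname(collapsed["GENE001"]),
                 scores[c(1:4)][which.max(abs(scores[1:4]))][[1]])

    # injective map: sizes match; unmapped accessions are dropped
    inj <- setNames(paste0("G", 1:10), paste0("A", 1:10))
    s <- setNames(rnorm(10), paste0("A", 1:10))
    expect_equal(length(mapAndCollapse(s, inj)), 10)
    expect_equal(length(mapAndCollapse(s, inj[1:6])), 6)
    expect_error(mapAndCollapse(s, setNames("G", "other")), "no input")
})

test_that("enrichment score matches its closed form for a top block", {
    # set = the top |S| ranks with all-equal positive scores: the running sum
    # peaks at the last hit with ES = 1 - (|S| - ... ) ... with equal weights
    # the peak is exactly 1 - 0 = 1 at the final hit minus no misses: ES = 1
    N <- 200; k <- 10
    ranks <- setNames(rep(c(2, 1), c(k, N - k)) + seq(N, 1) * 1e-9,
                      sprintf("G%03d", 1:N))
    res <- gsea(ranks, list(top = names(ranks)[1:k]), nPerm = 100, seed = 1)
    expect_gt(res$es, 0.9)
    expect_equal(res$es, 1 - 0, tolerance = 0.01)

    # at weight 0 the classic KS closed form holds exactly:
    # ES = max_i (i/k - (h_i - i)/(N - k)) with h = 1..k -> 1 - 0 = 1
    res0 <- gsea(ranks, list(top = names(ranks)[1:k]), nPerm = 100, seed = 1,
                 weightP = 0)
    expect_equal(res0$es, 1)
})

test_that("ES is invariant to positive rescaling of the scores", {
    set.seed(4)
    ranks <- setNames(rnorm(300), sprintf("G%03d", 1:300))
    sets <- list(a = sample(names(ranks), 20), b = sample(names(ranks), 15))
    for (p in c(0, 1)) {
        e1 <- gsea(ranks, sets, nPerm = 50, seed = 9, weightP = p)$es
        e2 <- gsea(ranks * 7.3, sets, nPerm = 50, seed = 9, weightP = p)$es
        expect_equal(e1, e2, tolerance = 1e-12)
    }
})

test_that("enrichment scores agree with an independent implementation", {
    set.seed(6)
    ranks <- setNames(rnorm(400), sprintf("G%03d", 1:400))
    sets <- lapply(1:10, function(i) sample(names(ranks), 25))
    names(sets) <- paste0("S", 1:10)
    ours <- gsea(ranks, sets, nPerm = 100, seed = 2)
    fg <- fgsea::fgseaSimple(sets, ranks, nperm = 50, gseaParam = 1,
                             minSize = 1, maxSize = 500)
    expect_equal(ours$es, fg$ES[match(ours$set_name, fg$pathway)],
                 tolerance = 1e-10)
})

test_that("permutation FDR is deterministic under a fixed seed", {
    set.seed(10)
    ranks <- setNames(rnorm(300), sprintf("G%03d", 1:300))
    sets <- lapply(1:8, function(i) sample(names(ranks), 20))
    names(sets) <- paste0("S", 1:8)
    a <- gsea(ranks, sets, nPerm = 200, seed = 33)
    b <- gsea(ranks, sets, nPerm = 200, seed = 33)
    expect_identical(a, b)
    expect_true(all(a$fdr_q >= 0 & a$fdr_q <= 1))
    expect_true(all(abs(a$es) <= 1))
})

test_that("a planted set is called, sets below minimum size are skipped", {
    set.seed(12)
    N <- 500
    ranks <- setNames(rnorm(N), sprintf("G%03d", 1:N))
    top <- names(sort(ranks, decreasing = TRUE))[1:20]
    sets <- list(planted = top, tiny = names(ranks)[1:3],
                 rand = sample(names(ranks), 20))
    res <- gsea(ranks, sets, nPerm = 500, seed = 3)
    expect_false("tiny" %in% res$set_name)
    expect_lt(res$fdr_q[res$set_name == "planted"], 0.05)
    expect_equal(res$direction[res$set_name == "planted"], "up")
    # leading edge of the planted set is drawn from the set itself
    le <- strsplit(res$leading_edge[res$set_name == "planted"], ",")[[1]]
    expect_true(all(le %in% top))
    expect_gt(length(le), 10)
})

test_that("enrichment report classifies shared and unique sets", {
    mk <- function(names, qs, le = "G1,G2") {
        data.frame(set_name = names, size = 10, es = 0.5, nes = 1.5,
                   p_value = 0.01, fdr_q = qs, direction = "up",
                   significant = qs < 0.05, leading_edge = le)
    }
    a <- mk(c("S1", "S2", "S3"), c(0.01, 0.5, 0.01), "G1,G2,G3")
    b <- mk(c("S1", "S2", "S4"), c(0.02, 0.01, 0.9), "G2,G3,G9")
    rep <- enrichmentReport(a, b, 0.05)
    expect_equal(rep$status[rep$set_name == "S1"], "shared")
    expect_equal(rep$status[rep$set_name == "S2"], "turnover_only")
    expect_equal(rep$status[rep$set_name == "S3"], "abundance_only")
    expect_equal(rep$status[rep$set_name == "S4"], "ns")
    expect_equal(rep$leading_edge_overlap[rep$set_name == "S1"], "G2,G3")

    # identical inputs: everything significant is shared; disjoint: none
    same <- enrichmentReport(a, a, 0.05)
    expect_true(all(same$status[same$fdr_q_abundance < 0.05] == "shared"))
    disj <- enrichmentReport(mk("S1", 0.01), mk("S9", 0.01), 0.05)
    expect_equal(sum(disj$status == "shared"), 0)
})

test_that("gene overlap bookkeeping reproduces a 2/13/25 style split", {
    # 27 genes significant for abundance, 38 for turnover, 25 in common:
    # 2 unique to abundance, 13 unique to turnover
    abSig <- sprintf("G%02d", 1:27)
    tuSig <- sprintf("G%02d", 3:40)
    shared <- intersect(abSig, tuSig)
    expect_equal(length(setdiff(abSig, tuSig)), 2)
    expect_equal(length(setdiff(tuSig, abSig)), 13)
    expect_equal(length(shared), 25)
    mk <- function(nm, le) data.frame(set_name = nm, size = 40, es = 0.5,
                                      nes = 2, p_value = 0.001, fdr_q = 0.001,
                                      direction = "up", significant = TRUE,
                                      leading_edge = paste(le, collapse = ","))
    rep <- enrichmentReport(mk("SET", abSig), mk("SET", tuSig), 0.05)
    expect_equal(strsplit(rep$leading_edge_overlap, ",")[[1]], shared)
})
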