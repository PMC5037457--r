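#' Map protein scores to gene symbols and collapse duplicates
#'
#' Protein accessions are translated via the user-supplied ID map; accessions
#' sharing a gene symbol are collapsed to the score of largest absolute value
#' (the most extreme evidence). Unmapped accessions are dropped and counted.
#'
#' @param scores named numeric vector: accession -> signed rank score (e.g.
#'   signed log2 fold change, or mean RIA difference).
#' @param idmap named character vector from [readIDMap()].
#' @return named numeric vector gene_symbol -> score, with attributes
#'   `n_unmapped` and `collapse_rule`.
#' @export
mapAndCollapse <- function(scores, idmap) {
    genes <- idmap[names(scores)]
    keep <- !is.na(genes)
    if (!any(keep))
        stop("no input accession is covered by the ID map")
    nUnmapped <- sum(!keep)
    if (nUnmapped)
        noteLog("%d accession(s) not in ID map, excluded", nUnmapped)
    s <- scores[keep]; g <- genes[keep]
    collapsed <- vapply(split(s, g), function(v) v[which.max(abs(v))],
                        numeric(1))
    noteLog("mapped %d accessions to %d distinct gene symbols",
            sum(keep), length(collapsed))
    attr(collapsed, "n_unmapped") <- nUnmapped
    attr(collapsed, "collapse_rule") <- "max_abs_score"
    collapsed
}

# Enrichment score from sorted hit positions in a fixed ranked list.
# absW: |score|^p per rank (descending scores); hp: sorted hit positions.
# Returns c(es, peak_index_within_hits) -- peak index < 0 marks a trough.
esFromHits <- function(absW, hp, N) {
    k <- length(hp)
    w <- absW[hp]
    NR <- sum(w)
    if (NR == 0) { w <- rep(1, k); NR <- k }
    cums <- cumsum(w) / NR
    missBefore <- (hp - seq_len(k)) / (N - k)
    top <- cums - missBefore
    bot <- c(0, cums[-k]) - missBefore
    iTop <- which.max(top); iBot <- which.min(bot)
    if (top[iTop] >= -bot[iBot]) c(top[iTop], iTop) else c(bot[iBot], -iBot)
}

#' Gene set enrichment analysis with permutation FDR
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment over a ranked gene
#' list: walking down the list, hits increment the sum proportionally to
#' `|score|^weightP` and misses decrement uniformly; the enrichment score
#' (ES) is the maximum deviation from zero. The null is built by gene-label
#' permutation (one shared relabeling of the list per permutation, seeded);
#' per-set NES divides the ES by the mean magnitude of same-sign null ES, and
#' the FDR q is the classic ratio-of-tails estimator on the pooled null NES,
#' with monotonicity enforced within each sign.
#'
#' @param ranks named numeric vector gene -> signed score (ties broken by
#'   name for determinism).
#' @param sets named list of gene-symbol vectors ([readGMT()]).
#' @param nPerm number of permutations (>= 100 recommended).
#' @param seed integer seed for the permutation null.
#' @param weightP hit-weight exponent (0 = classic KS, 1 = weighted, default).
#' @param minSize,maxSize set-size bounds after intersection with the list.
#' @param fdrCut FDR cutoff used only for the significance flag.
#' @return data.frame (one row per retained set): set_name, size, es, nes,
#'   p_value (per-set permutation p), fdr_q, direction, significant,
#'   leading_edge (comma-separated genes up to the ES extremum).
#' @export
gsea <- function(ranks, sets, nPerm = 1000L, seed = 1L, weightP = 1,
                 minSize = 5L, maxSize = 500L, fdrCut = 0.05) {
    stopifnot(length(ranks) > 1, !is.null(names(ranks)))
    if (any(!is.finite(ranks))) stop("rank scores must be finite")
    ord <- order(-ranks, names(ranks))  # deterministic tie-break
    ranks <- ranks[ord]
    N <- length(ranks)
    absW <- abs(ranks)^weightP
    hits <- lapply(sets, function(g) {
        idx <- match(unique(g), names(ranks))
        sort(idx[!is.na(idx)])
    })
    sizes <- lengths(hits)
    keep <- sizes >= minSize & sizes <= maxSize & sizes < N
    if (any(!keep))
        noteLog("%d set(s) outside size bounds [%d, %d] skipped",
                sum(!keep), minSize, maxSize)
    hits <- hits[keep]
    if (!length(hits)) stop("no gene set passes the size filter")
    nm <- names(hits)

    obs <- vapply(hits, function(hp) esFromHits(absW, hp, N), numeric(2))
    es <- obs[1, ]; peak <- obs[2, ]

    nullES <- withSeed(seed, {
        vapply(seq_len(nPerm), function(b) {
            posOf <- sample.int(N)
            vapply(hits, function(hp)
                esFromHits(absW, sort(posOf[hp]), N)[1], numeric(1))
        }, numeric(length(hits)))
    })
    nullES <- matrix(nullES, nrow = length(hits))

    nes <- pval <- rep(NA_real_, length(hits))
    nullNES <- nullES
    for (i in seq_along(hits)) {
        nv <- nullES[i, ]
        same <- if (es[i] >= 0) nv[nv >= 0] else nv[nv < 0]
        denom <- mean(abs(same))
        posMean <- mean(nv[nv >= 0]); negMean <- mean(abs(nv[nv < 0]))
        if (is.finite(denom) && denom > 0) {
            nes[i] <- es[i] / denom
            pval[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
        }
        # normalize the null the same way for the pooled FDR reference
        nullNES[i, ] <- ifelse(nv >= 0,
                               if (is.finite(posMean) && posMean > 0)
                                   nv / posMean else NA_real_,
                               if (is.finite(negMean) && negMean > 0)
                                   nv / negMean else NA_real_)
    }
    fdr <- ratioOfTailsFDR(nes, as.vector(nullNES))

    leading <- vapply(seq_along(hits), function(i) {
        hp <- hits[[i]]
        g <- if (peak[i] > 0) names(ranks)[hp[seq_len(peak[i])]]
        else names(ranks)[hp[seq(-peak[i], length(hp))]]
        paste(g, collapse = ",")
    }, character(1))

    out <- data.frame(set_name = nm, size = lengths(hits), es = es,
                      nes = nes, p_value = pval, fdr_q = fdr,
                      direction = ifelse(es >= 0, "up", "down"),
                      significant = !is.na(fdr) & fdr < fdrCut,
                      leading_edge = leading, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

# Classic GSEA FDR: for each observed NES, the fraction of pooled null NES at
# least as extreme (same sign) over the fraction of observed NES at least as
# extreme, clipped to [0, 1]; monotone in |NES| within each sign.
ratioOfTailsFDR <- function(nes, nullNES) {
    nullNES <- nullNES[is.finite(nullNES)]
    q <- rep(NA_real_, length(nes))
    for (i in seq_along(nes)) {
        v <- nes[i]
        if (!is.finite(v)) next
        if (v >= 0) {
            nullTail <- sum(nullNES >= v) / max(sum(nullNES >= 0), 1)
            obsTail <- sum(nes >= v, na.rm = TRUE) /
                max(sum(nes >= 0, na.rm = TRUE), 1)
        } else {
            nullTail <- sum(nullNES <= v) / max(sum(nullNES < 0), 1)
            obsTail <- sum(nes <= v, na.rm = TRUE) /
                max(sum(nes < 0, na.rm = TRUE), 1)
        }
        q[i] <- min(1, nullTail / max(obsTail, .Machine$double.eps))
    }
    ## q-value step: the q of a set is the best achievable FDR among
    ## thresholds loose enough to include it, so q is computed as a running
    ## minimum from the least extreme NES toward the most extreme (per sign)
    for (sgn in c(1, -1)) {
        idx <- which(if (sgn > 0) nes >= 0 else nes < 0)
        if (length(idx) < 2) next
        ordx <- idx[order(abs(nes[idx]))]
        q[ordx] <- cummin(q[ordx])
    }
    q
}

#' Compare enrichment between the abundance and turnover datasets
#'
#' Joins two [gsea()] result tables on set name and marks each set as
#' significant in the abundance data only, the turnover data only, both
#' (shared) or neither at the FDR cutoff; for shared sets the leading-edge
#' gene overlap is reported.
#'
#' @param abundance,turnover [gsea()] result data.frames.
#' @param fdrCut FDR cutoff.
#' @return data.frame: set_name, fdr_q and direction per dataset, status
#'   (`abundance_only` / `turnover_only` / `shared` / `ns`),
#'   leading_edge_overlap (comma-separated genes, shared sets only).
#' @export
enrichmentReport <- function(abundance, turnover, fdrCut = 0.05) {
    m <- merge(abundance[, c("set_name", "fdr_q", "direction",
                             "leading_edge")],
               turnover[, c("set_name", "fdr_q", "direction",
                            "leading_edge")],
               by = "set_name", all = TRUE,
               suffixes = c("_abundance", "_turnover"))
    sigA <- !is.na(m$fdr_q_abundance) & m$fdr_q_abundance < fdrCut
    sigT <- !is.na(m$fdr_q_turnover) & m$fdr_q_turnover < fdrCut
    m$status <- ifelse(sigA & sigT, "shared",
                ifelse(sigA, "abundance_only",
                ifelse(sigT, "turnover_only", "ns")))
    m$leading_edge_overlap <- ifelse(
        m$status == "shared",
        mapply(function(a, b) paste(intersect(strsplit(a, ",")[[1]],
                                              strsplit(b, ",")[[1]]),
                                    collapse = ","),
               m$leading_edge_abundance, m$leading_edge_turnover),
        "")
    m$leading_edge_abundance <- NULL
    m$leading_edge_turnover <- NULL
    noteLog("enrichment overlap: %d shared, %d abundance-only, %d turnover-only",
            sum(m$status == "shared"), sum(m$status == "abundance_only"),
            sum(m$status == "turnover_only"))
    m
}
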