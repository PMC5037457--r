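#' Run the full pipeline on simulated or supplied data
#'
#' Chains every stage: simulation (or reading of supplied tables),
#' label-free quantification, turnover (curation, RIA, precursor-pool RIA,
#' per-time comparisons), differential expression at the last time point,
#' temporal-trend classification, PCA QC, and gene set enrichment on the
#' abundance and turnover rankings. All outputs are TSV plus a JSON run
#' manifest recording the seed, configuration and file checksums; repeated
#' runs with the same seed are byte-identical.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving every random stage.
#' @param config a [pipelineConfig()].
#' @param simConfig a [simulationConfig()]; ignored when `peptides` is given.
#' @param peptides,design optional paths to a canonical peptide table and
#'   design table; when `NULL` the experiment is simulated.
#' @param gmt,idmap optional paths to a GMT file and accession-to-symbol
#'   map; when `NULL` synthetic ones are derived from the data.
#' @return (invisibly) a list with all stage results.
#' @export
runAll <- function(outDir, seed = 1L, config = pipelineConfig(),
                   simConfig = simulationConfig(), peptides = NULL,
                   design = NULL, gmt = NULL, idmap = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(seed)

    if (is.null(peptides)) {
        sim <- simulateExperiment(simConfig, seed)
        records <- sim$peptides; des <- sim$design
        writePeptideTable(records, file.path(outDir, "peptides.tsv"))
        writeDesign(des, file.path(outDir, "design.tsv"))
        writeTSV(sim$truth, file.path(outDir, "truth.tsv"))
    } else {
        sim <- NULL
        records <- readPeptideTable(peptides)
        des <- readDesign(design)
    }

    quant <- stageQuantify(records, des, config, outDir)
    turn <- stageTurnover(records, des, config, outDir)
    diff <- stageDifferential(quant$proteinMatrix, des, config, outDir)
    enr <- stageEnrichment(quant$proteinMatrix, turn, diff, des, config,
                           seed, gmt, idmap, outDir,
                           truth = if (is.null(sim)) NULL else sim$truth)

    writeManifest(outDir, seed, config)
    invisible(list(simulation = sim, quantification = quant, turnover = turn,
                   differential = diff, enrichment = enr))
}

stageQuantify <- function(records, des, config, outDir = NULL) {
    quant <- quantifyAbundance(records, des, config)
    if (!is.null(outDir)) {
        pm <- quant$proteinMatrix
        mat <- assay(pm, "log2intensity")
        writeTSV(data.frame(protein_accession = rownames(mat),
                            round(mat, 6), check.names = FALSE),
                 file.path(outDir, "protein_matrix.tsv"))
        writeTSV(data.frame(sample_id = names(quant$factors),
                            scaling_factor = round(quant$factors, 6)),
                 file.path(outDir, "scaling_factors.tsv"))
        writeTSV(data.frame(protein_accession = rownames(mat),
                            n_peptides = nPeptides(pm),
                            qc_cv = round(qcCV(pm), 6)),
                 file.path(outDir, "protein_qc.tsv"))
    }
    quant
}

stageTurnover <- function(records, des, config, outDir = NULL) {
    cur <- curatePeptides(records, des, config)
    ria <- riaTable(records, cur$audit)
    pool <- estimatePoolRIA(records, des)
    cmp <- compareRIAGroups(ria, des)
    if (!is.null(outDir)) {
        out <- ria
        out$ria <- round(out$ria, 6)
        writeTSV(out, file.path(outDir, "curated_ria.tsv"))
        writeTSV(within(pool$per_sample, r_hat <- round(r_hat, 6)),
                 file.path(outDir, "pool_ria.tsv"))
        writeTSV(cur$audit, file.path(outDir, "curation_audit.tsv"))
        if (!is.null(cmp$tests))
            writeTSV(cmp$tests, file.path(outDir, "ria_tests.tsv"))
        if (!is.null(cmp$summaries))
            writeTSV(cmp$summaries, file.path(outDir, "ria_summaries.tsv"))
    }
    list(curation = cur, ria = ria, pool = pool, comparison = cmp)
}

stageDifferential <- function(pm, des, config, outDir = NULL) {
    tmax <- max(colData(pm)$time_h[!colData(pm)$is_qc_pool])
    de <- differentialExpression(pm, time_h = tmax, config)
    tr <- classifyTrends(pm, config)
    z <- suppressWarnings(zscoreMatrix(pm))
    pca <- pcaQC(z, des)
    if (!is.null(outDir)) {
        writeTSV(de, file.path(outDir, "differential.tsv"))
        writeTSV(tr$classes, file.path(outDir, "trends.tsv"))
        writeTSV(data.frame(trend_class = names(tr$fractions),
                            fraction = round(tr$fractions, 6)),
                 file.path(outDir, "trend_fractions.tsv"))
        sc <- pca$scores
        sc$PC1 <- round(sc$PC1, 6); sc$PC2 <- round(sc$PC2, 6)
        writeTSV(sc, file.path(outDir, "pca_scores.tsv"))
        writeTSV(pca$ellipses, file.path(outDir, "pca_ellipses.tsv"))
    }
    list(de = de, trends = tr, pca = pca, time_h = tmax)
}

stageEnrichment <- function(pm, turn, diff, des, config, seed,
                            gmt = NULL, idmap = NULL, outDir = NULL,
                            truth = NULL) {
    map <- if (is.null(idmap)) {
        accs <- rownames(pm)
        stats::setNames(sub("^PROT", "GENE", accs), accs)
    } else readIDMap(idmap)

    ## abundance ranking: signed log2 fold change at the tested time point
    de <- diff$de
    abScores <- stats::setNames(sign(de$fc_signed) * log2(abs(de$fc_signed)),
                                de$protein_accession)
    ## turnover ranking: per-protein difference in mean curated RIA
    ## (micro_g - normal_g) at the last time point
    ria <- turn$ria
    d <- des[match(ria$sample_id, des$sample_id), ]
    tmax <- diff$time_h
    ok <- ria$curated & !is.na(ria$ria) & !d$is_qc_pool & d$time_h == tmax
    x <- ria[ok, ]; cond <- d$condition[ok]
    byProt <- split(seq_len(nrow(x)), x$protein_accession)
    tuScores <- vapply(byProt, function(i) {
        a <- x$ria[i][cond[i] == "micro_g"]
        b <- x$ria[i][cond[i] == "normal_g"]
        if (!length(a) || !length(b)) return(NA_real_)
        mean(a) - mean(b)
    }, numeric(1))
    tuScores <- tuScores[is.finite(tuScores)]

    abRanks <- mapAndCollapse(abScores, map)
    tuRanks <- mapAndCollapse(tuScores, map)

    sets <- if (is.null(gmt)) {
        enriched <- if (!is.null(truth))
            map[truth$protein_accession[truth$trend_class ==
                                        "dissimilar_change"]] else NULL
        simulateGeneSets(unique(map), nSets = 30L,
                         enrichedIn = enriched[!is.na(enriched)],
                         nEnriched = if (length(enriched)) 5L else 0L,
                         seed = seed + 1000L)
    } else readGMT(gmt)

    resA <- gsea(abRanks, sets, nPerm = config$n_permutations,
                 seed = seed + 2000L, fdrCut = config$gsea_fdr_cut)
    resT <- gsea(tuRanks, sets, nPerm = config$n_permutations,
                 seed = seed + 3000L, fdrCut = config$gsea_fdr_cut)
    rep <- enrichmentReport(resA, resT, config$gsea_fdr_cut)
    if (!is.null(outDir)) {
        writeTSV(roundNum(resA), file.path(outDir, "enrichment_abundance.tsv"))
        writeTSV(roundNum(resT), file.path(outDir, "enrichment_turnover.tsv"))
        writeTSV(roundNum(rep), file.path(outDir, "enrichment_report.tsv"))
    }
    list(abundance = resA, turnover = resT, report = rep)
}

roundNum <- function(df, digits = 6) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
    df
}

writeManifest <- function(outDir, seed, config) {
    files <- sort(setdiff(list.files(outDir), "manifest.json"))
    sums <- tools::md5sum(file.path(outDir, files))
    manifest <- list(
        pipeline = "dynaSILAC",
        version = as.character(utils::packageVersion("dynaSILAC")),
        seed = seed,
        config = unclass(config),
        outputs = stats::setNames(as.list(unname(sums)), files))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `silac-pipeline.R` script (see
#' `system.file("scripts", "silac-pipeline.R", package = "dynaSILAC")`).
#' Subcommands: `simulate`, `quantify`, `turnover`, `differential`, `enrich`,
#' `run-all`. Returns the exit status instead of quitting so it can be used
#' programmatically.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return (invisibly) integer exit status: 0 on success.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
    usage <- paste(
        "usage: silac-pipeline.R <subcommand> [options]",
        "subcommands:",
        "  simulate     --out DIR [--seed N] [--config FILE]",
        "  quantify     --peptides TSV --design TSV --out DIR [--config FILE]",
        "  turnover     --peptides TSV --design TSV --out DIR [--config FILE]",
        "  differential --peptides TSV --design TSV --out DIR [--config FILE]",
        "  enrich       --peptides TSV --design TSV --out DIR",
        "               [--gmt GMT --idmap TSV] [--seed N] [--config FILE]",
        "  run-all      --out DIR [--seed N] [--config FILE]",
        sep = "\n")
    if (!length(args)) { message(usage); return(invisible(1L)) }
    cmd <- args[[1]]
    opts <- parseCliOptions(args[-1])
    known <- c("simulate", "quantify", "turnover", "differential", "enrich",
               "run-all")
    if (!cmd %in% known) {
        message("unknown subcommand: ", cmd, "\n", usage)
        return(invisible(1L))
    }
    status <- tryCatch({
        cfg <- readPipelineConfig(opts$config)
        seed <- as.integer(opts$seed %||% cfg$random_seed)
        simCfg <- attr(cfg, "simulation") %||% simulationConfig()
        out <- opts$out
        if (is.null(out)) stop("--out is required")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        needInput <- function() {
            if (is.null(opts$peptides) || is.null(opts$design))
                stop("--peptides and --design are required for ", cmd)
            list(records = readPeptideTable(opts$peptides),
                 design = readDesign(opts$design))
        }
        switch(cmd,
            "simulate" = {
                sim <- simulateExperiment(simCfg, seed)
                writePeptideTable(sim$peptides, file.path(out, "peptides.tsv"))
                writeDesign(sim$design, file.path(out, "design.tsv"))
                writeTSV(sim$truth, file.path(out, "truth.tsv"))
                writeManifest(out, seed, cfg)
            },
            "quantify" = {
                inp <- needInput()
                stageQuantify(inp$records, inp$design, cfg, out)
                writeManifest(out, seed, cfg)
            },
            "turnover" = {
                inp <- needInput()
                stageTurnover(inp$records, inp$design, cfg, out)
                writeManifest(out, seed, cfg)
            },
            "differential" = {
                inp <- needInput()
                q <- stageQuantify(inp$records, inp$design, cfg, NULL)
                stageDifferential(q$proteinMatrix, inp$design, cfg, out)
                writeManifest(out, seed, cfg)
            },
            "enrich" = {
                inp <- needInput()
                q <- stageQuantify(inp$records, inp$design, cfg, NULL)
                tu <- stageTurnover(inp$records, inp$design, cfg, NULL)
                df <- stageDifferential(q$proteinMatrix, inp$design, cfg, NULL)
                stageEnrichment(q$proteinMatrix, tu, df, inp$design, cfg,
                                seed, opts$gmt, opts$idmap, out)
                writeManifest(out, seed, cfg)
            },
            "run-all" = {
                runAll(out, seed, cfg, simCfg,
                       peptides = opts$peptides, design = opts$design,
                       gmt = opts$gmt, idmap = opts$idmap)
            })
        0L
    }, error = function(e) {
        message("error: ", conditionMessage(e))
        1L
    })
    invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parseCliOptions <- function(args) {
    opts <- list()
    i <- 1L
    while (i <= length(args)) {
        a <- args[[i]]
        if (!startsWith(a, "--"))
            stop("unexpected argument: ", a)
        key <- substring(a, 3)
        if (i == length(args)) stop("option --", key, " needs a value")
        opts[[key]] <- args[[i + 1L]]
        i <- i + 2L
    }
    opts
}
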