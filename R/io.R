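#' @name peptide-table-format
#' @title Canonical peptide table format
#' @description
#' The canonical input is a long-format tab-separated table with one row per
#' peptide x sample and the columns below. Empty fields or `NA` are missing
#' values and are distinct from a measured `0`.
#'
#' \describe{
#'   \item{peptide_sequence}{amino-acid string}
#'   \item{protein_accession}{single protein identifier (razor assignment is
#'     left to the upstream producer)}
#'   \item{sample_id}{must match the design table}
#'   \item{intensity_light, intensity_heavy}{non-negative AUC, arbitrary units}
#'   \item{rt_light, rt_heavy}{retention time, minutes}
#'   \item{msms_identified_light, msms_identified_heavy}{logical flags}
#'   \item{noise_heavy}{noise estimate of the heavy-isotope peak}
#'   \item{n_labeled_residues}{count of labelable K/R residues}
#'   \item{isotopologue_hh, isotopologue_hl}{doubly-heavy and mixed
#'     heavy/light AUC; only meaningful when `n_labeled_residues >= 2`}
#' }
NULL

peptideColumns <- c("peptide_sequence", "protein_accession", "sample_id",
                    "intensity_light", "intensity_heavy",
                    "rt_light", "rt_heavy",
                    "msms_identified_light", "msms_identified_heavy",
                    "noise_heavy", "n_labeled_residues",
                    "isotopologue_hh", "isotopologue_hl")

peptideNumericCols <- c("intensity_light", "intensity_heavy", "rt_light",
                        "rt_heavy", "noise_heavy", "isotopologue_hh",
                        "isotopologue_hl")

#' Read a peptide-level intensity table
#'
#' @param path TSV/CSV file (delimiter sniffed from the header line).
#' @param dialect `"long"` (canonical, see [peptide-table-format]) or
#'   `"wide"` (one row per peptide; per-sample column pairs
#'   `<sample>_light` / `<sample>_heavy`).
#' @return a validated `data.frame` of peptide records (long format).
#' @export
readPeptideTable <- function(path, dialect = c("long", "wide")) {
    dialect <- match.arg(dialect)
    df <- readDelim(path)
    if (dialect == "wide") df <- widenToLong(df)
    required <- setdiff(peptideColumns, c("isotopologue_hh", "isotopologue_hl"))
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("peptide table is missing required column(s): ",
             paste(missing, collapse = ", "))
    for (col in c("isotopologue_hh", "isotopologue_hl"))
        if (!col %in% names(df)) df[[col]] <- NA_real_
    df <- df[peptideColumns]
    df <- validatePeptideTable(df)
    if (nrow(df) == 0) warning("peptide table '", path, "' has no data rows")
    noteLog("read %d peptide records (%d peptides, %d proteins) from %s",
            nrow(df), length(unique(df$peptide_sequence)),
            length(unique(df$protein_accession)), path)
    df
}

#' Validate an in-memory peptide table
#'
#' Checks column types, non-negativity of intensities, and that isotopologue
#' intensities only occur for peptides with at least two labeled residues.
#'
#' @param df a data.frame with the canonical columns.
#' @return the coerced, validated data.frame (invisibly the same shape).
#' @export
validatePeptideTable <- function(df) {
    for (col in peptideNumericCols) df[[col]] <- as.numeric(df[[col]])
    for (col in c("msms_identified_light", "msms_identified_heavy"))
        df[[col]] <- as.logical(df[[col]])
    df$n_labeled_residues <- as.integer(df$n_labeled_residues)
    for (col in c("intensity_light", "intensity_heavy", "noise_heavy",
                  "isotopologue_hh", "isotopologue_hl")) {
        bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
        if (length(bad))
            stop("negative ", col, " at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", "))
    }
    bad <- which((!is.na(df$isotopologue_hh) | !is.na(df$isotopologue_hl)) &
                     df$n_labeled_residues < 2)
    if (length(bad))
        stop("isotopologue intensities require n_labeled_residues >= 2; ",
             "offending row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    df
}

#' Read a sample design table
#'
#' Expects columns `sample_id`, `condition` (one of `baseline`, `normal_g`,
#' `micro_g`), `time_h`, `replicate`, `is_qc_pool`.
#'
#' @param path delimited text file.
#' @return validated design `data.frame`.
#' @export
readDesign <- function(path) {
    df <- readDelim(path)
    required <- c("sample_id", "condition", "time_h", "replicate", "is_qc_pool")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("design table is missing required column(s): ",
             paste(missing, collapse = ", "))
    df <- df[required]
    df$time_h <- as.numeric(df$time_h)
    df$replicate <- as.integer(df$replicate)
    df$is_qc_pool <- as.logical(df$is_qc_pool)
    validateDesign(df)
    noteLog("read design: %d samples (%d QC pools) from %s",
            nrow(df), sum(df$is_qc_pool), path)
    df
}

validateDesign <- function(df) {
    ok <- c("baseline", "normal_g", "micro_g")
    bad <- setdiff(unique(df$condition[!df$is_qc_pool]), ok)
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "),
             " (expected ", paste(ok, collapse = "/"), ")")
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in design")
    if (any(df$condition == "baseline" & df$time_h != 0 & !df$is_qc_pool))
        stop("baseline samples must have time_h = 0")
    bio <- df[!df$is_qc_pool, ]
    key <- paste(bio$condition, bio$time_h, bio$replicate)
    if (anyDuplicated(key))
        stop("duplicate (condition, time_h, replicate) among non-QC samples: ",
             key[duplicated(key)][1])
    if (nrow(bio) < 2)
        warning("fewer than two biological samples; ",
                "group statistics are undefined")
    invisible(TRUE)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a set are removed.
#'
#' @param path GMT file.
#' @return a named list of character vectors with a `description` attribute
#'   per element.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list()
    for (i in seq_along(lines)) {
        parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3)
            stop("malformed GMT line ", i,
                 ": expected name, description and >= 1 gene")
        genes <- unique(parts[-(1:2)])
        genes <- genes[nzchar(genes)]
        if (!length(genes)) stop("malformed GMT line ", i, ": empty gene set")
        nm <- parts[[1]]
        if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
        attr(genes, "description") <- parts[[2]]
        sets[[nm]] <- genes
    }
    noteLog("read %d gene sets (median size %s) from %s", length(sets),
            if (length(sets)) stats::median(lengths(sets)) else "NA", path)
    sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors ([readGMT()] shape).
#' @param path output file.
#' @export
writeGMT <- function(sets, path) {
    lines <- vapply(names(sets), function(nm) {
        desc <- attr(sets[[nm]], "description")
        if (is.null(desc)) desc <- nm
        paste(c(nm, desc, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a protein-accession to gene-symbol map
#'
#' Two-column delimited file (`protein_accession`, `gene_symbol`);
#' many accessions may map to one symbol but no accession to two.
#'
#' @param path delimited text file.
#' @return named character vector: `map[accession] -> symbol`.
#' @export
readIDMap <- function(path) {
    df <- readDelim(path)
    if (!all(c("protein_accession", "gene_symbol") %in% names(df)))
        stop("ID map must have columns protein_accession, gene_symbol")
    if (anyDuplicated(df$protein_accession))
        stop("ID map assigns multiple symbols to accession(s): ",
             df$protein_accession[duplicated(df$protein_accession)][1])
    stats::setNames(as.character(df$gene_symbol),
                    as.character(df$protein_accession))
}

#' Write a peptide table in the canonical long TSV format
#' @param df peptide records ([peptide-table-format]).
#' @param path output TSV.
#' @export
writePeptideTable <- function(df, path) writeTSV(df[peptideColumns], path)

#' Write a sample design table
#' @param design design data.frame.
#' @param path output TSV.
#' @export
writeDesign <- function(design, path) writeTSV(design, path)

# Delimiter-sniffing reader: tab if the header contains one, else comma.
readDelim <- function(path) {
    header <- readLines(path, n = 1L)
    if (!length(header)) stop("empty file: ", path)
    sep <- if (grepl("\t", header)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      na.strings = c("NA", ""), stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = "")
}

# Wide peptide table -> canonical long records. Wide tables carry intensities
# only; identification flags and RTs are unavailable and left missing.
widenToLong <- function(df) {
    key <- c("peptide_sequence", "protein_accession")
    if (!all(key %in% names(df)))
        stop("peptide table is missing required column(s): ",
             paste(setdiff(key, names(df)), collapse = ", "))
    lc <- grep("_light$", names(df), value = TRUE)
    samples <- sub("_light$", "", lc)
    if (!length(samples)) stop("wide peptide table has no *_light columns")
    long <- do.call(rbind, lapply(samples, function(s) {
        hv <- paste0(s, "_heavy")
        data.frame(peptide_sequence = df$peptide_sequence,
                   protein_accession = df$protein_accession,
                   sample_id = s,
                   intensity_light = as.numeric(df[[paste0(s, "_light")]]),
                   intensity_heavy = if (hv %in% names(df))
                       as.numeric(df[[hv]]) else NA_real_,
                   rt_light = NA_real_, rt_heavy = NA_real_,
                   msms_identified_light = NA, msms_identified_heavy = NA,
                   noise_heavy = NA_real_, n_labeled_residues = 1L,
                   isotopologue_hh = NA_real_, isotopologue_hl = NA_real_,
                   stringsAsFactors = FALSE)
    }))
    rownames(long) <- NULL
    long
}
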