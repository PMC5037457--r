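#' Relative isotope abundance of a peptide
#'
#' `RIA = I_H / (I_L + I_H)`: the fraction of a peptide's signal carried by
#' the heavy-labeled form. 0 means no post-switch synthesis, values near the
#' precursor-pool RIA mean near-complete replacement. Vectorized; rows where
#' both channels are missing or the total is zero return `NA` (undefined RIA)
#' rather than raising an error.
#'
#' @param iL,iH light / heavy channel AUC (non-negative; `NA` = missing).
#' @return numeric vector of fractions in \[0, 1\] (`NA` where undefined).
#' @export
computeRIA <- function(iL, iH) {
    if (any(iL < 0, na.rm = TRUE) || any(iH < 0, na.rm = TRUE))
        stop("channel intensities must be non-negative")
    l <- ifelse(is.na(iL), 0, iL)
    h <- ifelse(is.na(iH), 0, iH)
    tot <- l + h
    out <- ifelse(tot > 0, h / tot, NA_real_)
    out[is.na(iL) & is.na(iH)] <- NA_real_
    out
}

#' Curate peptides for turnover analysis
#'
#' A peptide (globally, across all samples) is retained only when all three
#' criteria hold:
#' 1. its heavy and its light form were each identified by MS/MS in at least
#'    one sample (`not_dual_identified` otherwise);
#' 2. the light/heavy retention times never differ by more than
#'    `config$rt_tolerance_min` minutes where both are measured
#'    (`rt_mismatch`);
#' 3. the light-channel intensity at T = 0 is at least `config$snr_min` times
#'    the heavy-channel noise estimate, i.e. heavy noise below 1/10 of the
#'    light T = 0 peak at the default S/N 10 (`snr_low`; also assigned when
#'    no T = 0 observation exists, since the criterion cannot be evaluated).
#'
#' @param records canonical peptide table ([peptide-table-format]).
#' @param design sample design ([readDesign()]).
#' @param config a [pipelineConfig()].
#' @return list with `curated` (records of retained peptides) and `audit`
#'   (one row per peptide: retained flag and comma-separated
#'   `rejection_reasons` among `not_dual_identified`, `rt_mismatch`,
#'   `snr_low`).
#' @export
curatePeptides <- function(records, design, config = pipelineConfig()) {
    t0 <- design$sample_id[design$time_h == 0 & !design$is_qc_pool]
    sp <- split(seq_len(nrow(records)), records$peptide_sequence)
    audit <- lapply(names(sp), function(pep) {
        r <- records[sp[[pep]], ]
        reasons <- character()
        if (!any(r$msms_identified_light, na.rm = TRUE) ||
            !any(r$msms_identified_heavy, na.rm = TRUE))
            reasons <- c(reasons, "not_dual_identified")
        both <- !is.na(r$rt_light) & !is.na(r$rt_heavy)
        if (any(abs(r$rt_light[both] - r$rt_heavy[both]) >
                config$rt_tolerance_min))
            reasons <- c(reasons, "rt_mismatch")
        r0 <- r[r$sample_id %in% t0 & !is.na(r$intensity_light), ]
        if (nrow(r0) == 0) {
            reasons <- c(reasons, "snr_low")  # criterion 3 not evaluable
        } else {
            snr <- mean(r0$intensity_light) / mean(r0$noise_heavy, na.rm = TRUE)
            if (!is.finite(snr) || snr < config$snr_min)
                reasons <- c(reasons, "snr_low")
        }
        data.frame(peptide_sequence = pep, retained = !length(reasons),
                   rejection_reasons = paste(reasons, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    audit <- do.call(rbind, audit)
    keep <- audit$peptide_sequence[audit$retained]
    noteLog("curation retained %d / %d peptides", length(keep), nrow(audit))
    list(curated = records[records$peptide_sequence %in% keep, ],
         audit = audit)
}

#' Per-observation RIA table with curation status
#'
#' @param records canonical peptide table.
#' @param audit curation audit from [curatePeptides()] (`NULL`: all curated).
#' @return data.frame: `peptide_sequence`, `protein_accession`, `sample_id`,
#'   `ria`, `curated`, `rejection_reasons`.
#' @export
riaTable <- function(records, audit = NULL) {
    out <- data.frame(peptide_sequence = records$peptide_sequence,
                      protein_accession = records$protein_accession,
                      sample_id = records$sample_id,
                      ria = computeRIA(records$intensity_light,
                                       records$intensity_heavy),
                      stringsAsFactors = FALSE)
    if (is.null(audit)) {
        out$curated <- TRUE
        out$rejection_reasons <- ""
    } else {
        i <- match(out$peptide_sequence, audit$peptide_sequence)
        out$curated <- audit$retained[i]
        out$rejection_reasons <- audit$rejection_reasons[i]
    }
    out
}

#' Precursor-pool RIA from a doubly labeled peptide
#'
#' For a peptide with two labelable lysines, post-switch molecules are
#' heavy/heavy vs heavy/light in ratio `r^2 : 2r(1-r)`, so the pool RIA is
#' `2*I_HH / (2*I_HH + I_HL)`, independent of turnover. Estimates r per
#' sample, averages within condition, and reports a two-sample Student's
#' t-test between the two gravity conditions (by default pooling the 48 h and
#' 120 h samples, where label incorporation is substantial).
#'
#' @param records canonical peptide table (rows with `n_labeled_residues >= 2`
#'   and isotopologue intensities are used).
#' @param design sample design.
#' @param times time points (h) whose biological samples enter the estimate.
#' @return list of class `"PoolRIAEstimate"`: `r_hat` (grand mean),
#'   `per_sample` (data.frame), `by_condition` (means), `p_value`
#'   (between-condition t-test), `n_observations`.
#' @export
estimatePoolRIA <- function(records, design, times = c(48, 120)) {
    rr <- records[!is.na(records$n_labeled_residues) &
                  records$n_labeled_residues >= 2 &
                  !(is.na(records$isotopologue_hh) &
                    is.na(records$isotopologue_hl)), ]
    if (!nrow(rr)) stop("no doubly labeled peptide observations available")
    d <- design[match(rr$sample_id, design$sample_id), ]
    keep <- !d$is_qc_pool & d$time_h %in% times
    rr <- rr[keep, ]; d <- d[keep, ]
    hh <- ifelse(is.na(rr$isotopologue_hh), 0, rr$isotopologue_hh)
    hl <- ifelse(is.na(rr$isotopologue_hl), 0, rr$isotopologue_hl)
    def <- hh + hl > 0
    if (any(!def))
        warning(sum(!def), " sample(s) with zero isotopologue signal excluded")
    rr <- rr[def, ]; d <- d[def, ]; hh <- hh[def]; hl <- hl[def]
    rhat <- 2 * hh / (2 * hh + hl)
    perSample <- data.frame(sample_id = rr$sample_id, condition = d$condition,
                            time_h = d$time_h, r_hat = rhat,
                            stringsAsFactors = FALSE)
    byCond <- tapply(rhat, d$condition, mean)
    conds <- intersect(c("normal_g", "micro_g"), names(byCond))
    p <- if (length(conds) == 2 &&
             all(table(d$condition)[conds] >= 2)) {
        stats::t.test(rhat[d$condition == conds[1]],
                      rhat[d$condition == conds[2]],
                      var.equal = TRUE)$p.value
    } else NA_real_
    out <- list(r_hat = mean(rhat), per_sample = perSample,
                by_condition = byCond, p_value = p,
                n_observations = length(rhat))
    class(out) <- "PoolRIAEstimate"
    out
}

#' @export
print.PoolRIAEstimate <- function(x, ...) {
    cat(sprintf("Precursor-pool RIA: r_hat = %.4f (n = %d samples)\n",
                x$r_hat, x$n_observations))
    for (nm in names(x$by_condition))
        cat(sprintf("  %-9s %.4f\n", nm, x$by_condition[[nm]]))
    cat(sprintf("  between-condition t-test p = %.3g\n", x$p_value))
    invisible(x)
}

#' Compare peptide RIA between conditions over time
#'
#' At each requested time point, runs a two-sided equal-variance Student's
#' t-test (Welch by flag) on curated peptide-level RIA observations between
#' the two gravity conditions, and emits boxplot-style quartile summaries per
#' condition and time.
#'
#' @param ria [riaTable()] output (only `curated` rows with defined `ria`
#'   are used).
#' @param design sample design.
#' @param times time points (h) to test; default all shared post-switch times.
#' @param welch use Welch's unequal-variance t-test.
#' @return list: `tests` (data.frame time_h, n per condition, p_value),
#'   `summaries` (condition x time quartiles).
#' @export
compareRIAGroups <- function(ria, design, times = NULL, welch = FALSE) {
    d <- design[match(ria$sample_id, design$sample_id), ]
    ok <- ria$curated & !is.na(ria$ria) & !d$is_qc_pool &
        d$condition %in% c("normal_g", "micro_g")
    x <- ria[ok, ]; d <- d[ok, ]
    if (is.null(times)) times <- sort(unique(d$time_h[d$time_h > 0]))
    tests <- list(); summaries <- list()
    for (t in times) {
        a <- x$ria[d$time_h == t & d$condition == "normal_g"]
        b <- x$ria[d$time_h == t & d$condition == "micro_g"]
        if (length(a) < 2 || length(b) < 2) {
            warning("time ", t, " h skipped: a condition has < 2 observations")
            next
        }
        p <- stats::t.test(a, b, var.equal = !welch)$p.value
        tests[[length(tests) + 1L]] <-
            data.frame(time_h = t, n_normal_g = length(a),
                       n_micro_g = length(b), p_value = p)
        for (cond in c("normal_g", "micro_g")) {
            v <- if (cond == "normal_g") a else b
            q <- stats::quantile(v, c(0.25, 0.5, 0.75))
            summaries[[length(summaries) + 1L]] <-
                data.frame(condition = cond, time_h = t, n = length(v),
                           q25 = q[[1]], median = q[[2]], q75 = q[[3]],
                           mean = mean(v))
        }
    }
    list(tests = do.call(rbind, tests), summaries = do.call(rbind, summaries))
}

#' Fit a first-order turnover rate to an RIA time series
#'
#' Least-squares fit of `RIA(t) = r * (1 - exp(-k t))` for `k > 0` with the
#' pool RIA `r` held fixed (the curve's asymptote). Primary fit via
#' [stats::nls()]; on failure a log-grid search plus golden-section refine is
#' used. A series pinned at the asymptote for all t > 0 drives k to the upper
#' bound and is flagged.
#'
#' @param t time points, hours.
#' @param ria observed (mean) RIA at each time.
#' @param r pool RIA in (0, 1].
#' @param kMax upper bound for k, per hour.
#' @return list of class `"TurnoverFit"`: `k_hat`, `r_used`, `residual` (sum
#'   of squares), `n_timepoints`, `converged`, `at_bound`.
#' @export
fitTurnoverRate <- function(t, ria, r, kMax = 10) {
    ok <- !is.na(ria) & !is.na(t)
    t <- t[ok]; ria <- ria[ok]
    if (length(unique(t)) < 3)
        stop("need >= 3 time points with defined RIA")
    if (r <= 0 || r > 1) stop("pool RIA r must be in (0, 1]")
    out <- list(k_hat = NA_real_, r_used = r, residual = NA_real_,
                n_timepoints = length(unique(t)), converged = FALSE,
                at_bound = FALSE)
    class(out) <- "TurnoverFit"
    if (all(ria == 0)) return(out)
    sse <- function(k) sum((ria - r * (1 - exp(-k * t)))^2)
    fit <- tryCatch({
        frac <- pmin(pmax(ria / r, NA), 0.999)
        k0 <- stats::median(-log(1 - frac[t > 0]) / t[t > 0], na.rm = TRUE)
        k0 <- min(max(k0, 1e-6, na.rm = TRUE), kMax)
        stats::nls(ria ~ r * (1 - exp(-k * t)), start = list(k = k0),
                   lower = 1e-8, upper = kMax, algorithm = "port")
    }, error = function(e) NULL)
    if (!is.null(fit)) {
        out$k_hat <- stats::coef(fit)[["k"]]
    } else {
        grid <- 10^seq(-6, log10(kMax), length.out = 200)
        kg <- grid[which.min(vapply(grid, sse, numeric(1)))]
        opt <- stats::optimize(sse, c(kg / 10, min(kg * 10, kMax)))
        out$k_hat <- opt$minimum
    }
    out$residual <- sse(out$k_hat)
    out$converged <- TRUE
    out$at_bound <- out$k_hat > 0.95 * kMax
    out
}

#' @export
print.TurnoverFit <- function(x, ...) {
    cat(sprintf(
        "TurnoverFit: k_hat = %.5g /h (t1/2 = %.3g h), r = %.3f, SSE = %.3g%s\n",
        x$k_hat, log(2) / x$k_hat, x$r_used, x$residual,
        if (x$at_bound) " [at bound]" else if (!x$converged)
            " [not converged]" else ""))
    invisible(x)
}

#' Fit turnover rates for all proteins
#'
#' Aggregates curated RIA observations to per-protein mean RIA per time point
#' within a condition and fits [fitTurnoverRate()] for each protein with
#' enough time points.
#'
#' @param ria [riaTable()] output.
#' @param design sample design.
#' @param r pool RIA (e.g. from [estimatePoolRIA()]).
#' @param condition which condition's samples to use.
#' @return data.frame: accession, k_hat, residual, n_timepoints, converged,
#'   at_bound.
#' @export
fitTurnoverRates <- function(ria, design, r, condition = "normal_g") {
    d <- design[match(ria$sample_id, design$sample_id), ]
    ok <- ria$curated & !is.na(ria$ria) & !d$is_qc_pool &
        (d$condition == condition | d$time_h == 0)
    x <- ria[ok, ]; t_h <- d$time_h[ok]
    res <- lapply(split(seq_len(nrow(x)), x$protein_accession), function(i) {
        agg <- tapply(x$ria[i], t_h[i], mean)
        tt <- as.numeric(names(agg))
        if (length(tt) < 3) return(NULL)
        f <- fitTurnoverRate(tt, as.numeric(agg), r)
        data.frame(protein_accession = x$protein_accession[i[1]],
                   k_hat = f$k_hat, residual = f$residual,
                   n_timepoints = f$n_timepoints, converged = f$converged,
                   at_bound = f$at_bound, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
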