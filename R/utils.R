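# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
# All seeded entry points funnel through here so that identical seeds give
# identical results regardless of surrounding RNG use.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed), kind = "Mersenne-Twister",
                 normal.kind = "Inversion", sample.kind = "Rejection")
    }
    expr
}

# Multiplicative log-normal noise with mean exactly 1 at the given CV.
rlnormMean1 <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Coefficient of variation over non-missing values; NA when < 2 values.
cvOf <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / mean(x)
}

# message()-based progress note, silenced via option(dynaSILAC.quiet = TRUE)
noteLog <- function(fmt, ...) {
    if (!isTRUE(getOption("dynaSILAC.quiet", FALSE)))
        message(sprintf(fmt, ...))
    invisible(NULL)
}

# write.table with fixed, locale-independent settings so repeated runs are
# byte-identical
writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA",
                       fileEncoding = "UTF-8")
    invisible(path)
}
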