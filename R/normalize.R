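#' Log10-transform raw intensities
#'
#' Metabolite intensities are log10-transformed so that replicate variation
#' better resembles a normal distribution. Masked (NA) cells stay masked.
#'
#' @param x a \linkS4class{DiallelExperiment} on the raw intensity scale.
#' @return the experiment with log10 values (\code{isLogScale(x)} TRUE).
#' @export
logTransform <- function(x) {
    if (isLogScale(x))
        stop("experiment is already on the log10 scale")
    v <- intensities(x)
    bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop("non-positive intensities cannot be log-transformed, e.g. ",
             "metabolite ", rownames(v)[bad[1L, 1L]], ", sample ",
             colnames(v)[bad[1L, 2L]])
    intensities(x) <- log10(v)
    S4Vectors::metadata(x)$logScale <- TRUE
    x
}

# per-metabolite additive two-factor fit (genotype + batch, no interaction,
# sum-to-zero batch contrasts); shared workhorse of batch removal and
# outlier detection
fitGenotypeBatch <- function(y, genotype, batch) {
    df <- data.frame(y = y, genotype = factor(genotype),
                     batch = factor(batch))
    if (nlevels(df$batch) < 2L)
        return(lm(y ~ genotype, data = df,
                  na.action = stats::na.exclude))
    lm(y ~ genotype + batch, data = df, na.action = stats::na.exclude,
       contrasts = list(batch = "contr.sum"))
}

#' Remove measurement-batch effects by two-factor ANOVA
#'
#' Per metabolite, fits an additive two-way model with genotype and batch
#' as factors (sum-to-zero batch constraint) and subtracts the estimated
#' batch effects; genotype effects are untouched. With a single batch this
#' is the identity transform. Inestimable batch effects (aliased
#' coefficients) are set to 0 with a warning.
#'
#' @param x a \linkS4class{DiallelExperiment}, log10 scale.
#' @return list with \code{experiment} (corrected) and \code{report}
#'   (element \code{batchEffectsRemoved}: metabolites x batches matrix of
#'   subtracted offsets).
#' @export
removeBatchEffects <- function(x) {
    stopifnot(isLogScale(x))
    v <- intensities(x)
    batches <- sort(unique(x$batch))
    eff <- matrix(0, nrow(v), length(batches),
                  dimnames = list(rownames(v), paste0("batch", batches)))
    if (length(batches) > 1L) {
        bf <- factor(x$batch)
        anyAliased <- FALSE
        for (j in seq_len(nrow(v))) {
            fit <- fitGenotypeBatch(v[j, ], x$genotype, x$batch)
            cf <- coef(fit)
            bc <- cf[grep("^batch", names(cf))]
            if (anyNA(bc)) { bc[is.na(bc)] <- 0; anyAliased <- TRUE }
            be <- c(bc, -sum(bc))   # sum-to-zero: last level implied
            eff[j, ] <- be
            v[j, ] <- v[j, ] - be[as.integer(bf)]
        }
        if (anyAliased)
            warning("some batch effects were inestimable and set to 0")
    }
    intensities(x) <- v
    list(experiment = x,
         report = list(batchEffectsRemoved = eff))
}

#' Mask outlying cells by externally studentized residuals
#'
#' Cells whose externally studentized residual from the per-metabolite
#' genotype + batch fit exceeds \code{threshold} in absolute value are
#' masked (set NA). A single pass is made; the model is not refit after
#' masking. Zero removals is a valid outcome.
#'
#' @param x a \linkS4class{DiallelExperiment}, log10 scale.
#' @param threshold studentized-residual cutoff (default 4).
#' @return list with \code{experiment} and \code{report} (element
#'   \code{outliersRemoved}: data.frame of masked (metabolite, sample)
#'   cells with their residuals).
#' @export
removeOutliers <- function(x, threshold = 4) {
    stopifnot(isLogScale(x))
    v <- intensities(x)
    out <- list()
    for (j in seq_len(nrow(v))) {
        fit <- fitGenotypeBatch(v[j, ], x$genotype, x$batch)
        rs <- suppressWarnings(rstudent(fit))
        hit <- which(!is.na(rs) & abs(rs) > threshold)
        if (length(hit)) {
            out[[length(out) + 1L]] <- data.frame(
                metabolite = rownames(v)[j],
                sample = colnames(v)[hit],
                residual = unname(rs[hit]),
                stringsAsFactors = FALSE)
            v[j, hit] <- NA_real_
        }
    }
    intensities(x) <- v
    rep <- if (length(out)) do.call(rbind, out) else
        data.frame(metabolite = character(), sample = character(),
                   residual = numeric(), stringsAsFactors = FALSE)
    list(experiment = x, report = list(outliersRemoved = rep))
}

#' Scale samples to a common median within each genotype
#'
#' Corrects for differences in initial sample amount: each sample's
#' correction factor is the ratio of its median metabolite level to the
#' median level over all replicates of the same genotype. On the log10
#' scale the division becomes a subtraction, which is what is applied.
#'
#' @param x a \linkS4class{DiallelExperiment}, log10 scale.
#' @return list with \code{experiment} and \code{report} (element
#'   \code{scaleFactors}: per-sample log10 factors subtracted).
#' @export
scaleSamples <- function(x) {
    stopifnot(isLogScale(x))
    v <- intensities(x)
    allNA <- colSums(!is.na(v)) == 0L
    if (any(allNA))
        stop("sample(s) fully masked: ",
             paste(colnames(v)[allNA], collapse = ", "))
    sampleMed <- apply(v, 2L, median, na.rm = TRUE)
    factors <- numeric(ncol(v))
    for (g in unique(x$genotype)) {
        cols <- genotypeCols(x, g)
        grpMed <- median(v[, cols], na.rm = TRUE)
        factors[cols] <- sampleMed[cols] - grpMed
    }
    names(factors) <- colnames(v)
    intensities(x) <- sweep(v, 2L, factors, "-")
    list(experiment = x, report = list(scaleFactors = factors))
}

#' Autoscale the columns of a feature matrix
#'
#' Mean-centers every column and scales it to unit variance, ignoring
#' masked cells. Constant columns are an error unless \code{dropConstant}
#' is set, in which case they are removed and reported.
#'
#' @param m numeric matrix, observations x features.
#' @param dropConstant drop zero-variance columns instead of failing.
#' @return list with \code{matrix} (autoscaled) and \code{report} (element
#'   \code{columnsScaled}: per-column mean and sd used; \code{dropped}:
#'   ids of removed constant columns).
#' @export
autoscaleColumns <- function(m, dropConstant = FALSE) {
    mu <- colMeans(m, na.rm = TRUE)
    s <- apply(m, 2L, sd, na.rm = TRUE)
    const <- !is.na(s) & s == 0
    if (any(const)) {
        if (!dropConstant)
            stop("constant column(s): ",
                 paste(colnames(m)[const], collapse = ", "))
        m <- m[, !const, drop = FALSE]
        mu <- mu[!const]; s <- s[!const]
    }
    scaled <- sweep(sweep(m, 2L, mu, "-"), 2L, s, "/")
    list(matrix = scaled,
         report = list(
             columnsScaled = data.frame(column = colnames(m), mean = mu,
                                        sd = s, row.names = NULL,
                                        stringsAsFactors = FALSE),
             dropped = if (any(const)) names(const)[const] else character()))
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: log10 transform (skipped when the data are already on the
#' log scale), ANOVA batch-effect removal, studentized-residual outlier
#' masking, median-based per-sample scaling. Column autoscaling is applied
#' later, when the parental-pair matrix is built.
#'
#' @param x a \linkS4class{DiallelExperiment}.
#' @param outlierThreshold studentized-residual cutoff (default 4).
#' @return list with \code{experiment} (normalized) and \code{report}
#'   (merged per-step reports).
#' @export
normalizeDiallel <- function(x, outlierThreshold = 4) {
    if (!isLogScale(x))
        x <- logTransform(x)
    st1 <- removeBatchEffects(x)
    st2 <- removeOutliers(st1$experiment, threshold = outlierThreshold)
    st3 <- scaleSamples(st2$experiment)
    list(experiment = st3$experiment,
         report = c(st1$report, st2$report, st3$report))
}
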