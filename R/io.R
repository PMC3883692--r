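#' Write a diallel fixture to disk
#'
#' Emits three plain-text files: \code{values.tsv} (samples x metabolites,
#' first column \code{sample}, header row of metabolite ids, full double
#' precision), \code{design.tsv} (columns \code{sample}, \code{genotype},
#' \code{mother}, \code{father}, \code{replicate}, \code{batch},
#' \code{biomass}; mother/father empty for inbreds) and \code{truth.json}
#' (ground-truth sidecar, omitted when \code{truth} is NULL). Round-trips
#' losslessly through [readFixture()].
#'
#' @param experiment a \linkS4class{DiallelExperiment}.
#' @param truth a \linkS4class{GroundTruth} or NULL.
#' @param dir output directory (created if missing).
#' @return manifest: list of per-file entries with row/column counts.
#' @export
writeFixture <- function(experiment, truth, dir) {
    if (!dir.exists(dir)) {
        ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        if (!ok) stop("cannot create directory: ", dir)
    }
    if (file.access(dir, 2L) != 0L)
        stop("directory not writable: ", dir)
    vals <- t(intensities(experiment))        # samples x metabolites
    vdf <- data.frame(sample = rownames(vals),
                      apply(vals, 2L, fmtNum),
                      check.names = FALSE, stringsAsFactors = FALSE)
    vPath <- file.path(dir, "values.tsv")
    write.table(vdf, vPath, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    cd <- SummarizedExperiment::colData(experiment)
    ddf <- data.frame(sample = rownames(cd),
                      genotype = cd$genotype,
                      mother = ifelse(is.na(cd$mother), "", cd$mother),
                      father = ifelse(is.na(cd$father), "", cd$father),
                      replicate = cd$replicate,
                      batch = cd$batch,
                      biomass = fmtNum(cd$biomass),
                      stringsAsFactors = FALSE)
    dPath <- file.path(dir, "design.tsv")
    write.table(ddf, dPath, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    manifest <- list(
        values = list(file = "values.tsv", rows = nrow(vdf),
                      columns = ncol(vals)),
        design = list(file = "design.tsv", rows = nrow(ddf),
                      columns = ncol(ddf)),
        logScale = isLogScale(experiment))
    if (!is.null(truth)) {
        tPath <- file.path(dir, "truth.json")
        jsonlite::write_json(list(
            driverFeatures = truth@driverFeatures,
            drivenMetabolites = truth@drivenMetabolites,
            trueLabels = list(
                hybrids = rownames(truth@trueLabels),
                metabolites = colnames(truth@trueLabels),
                labels = unname(apply(truth@trueLabels, 1L, as.integer,
                                      simplify = FALSE))),
            biomassWeights = as.list(truth@biomassWeights),
            noiseSd = truth@noiseSd,
            batchEffects = list(
                batches = rownames(truth@batchEffects),
                metabolites = colnames(truth@batchEffects),
                values = unname(apply(truth@batchEffects, 1L, as.numeric,
                                      simplify = FALSE)))),
            tPath, auto_unbox = TRUE, digits = NA)
        manifest$truth <- list(file = "truth.json",
                               rows = nrow(truth@trueLabels),
                               columns = ncol(truth@trueLabels))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

# full-precision decimal rendering so TSV round-trips bit-exactly
fmtNum <- function(x) sprintf("%.17g", as.numeric(x))

#' Read a diallel fixture written by [writeFixture()]
#'
#' @param dir directory containing \code{values.tsv} and \code{design.tsv}
#'   (and optionally \code{truth.json}, \code{manifest.json}).
#' @return list with \code{experiment}, \code{design}
#'   (\linkS4class{DiallelDesign} reconstructed from the design sheet) and
#'   \code{truth} (NULL when no sidecar is present).
#' @export
readFixture <- function(dir) {
    vPath <- file.path(dir, "values.tsv")
    dPath <- file.path(dir, "design.tsv")
    if (!file.exists(vPath) || !file.exists(dPath))
        stop("fixture files missing under: ", dir)
    vdf <- read.delim(vPath, check.names = FALSE, stringsAsFactors = FALSE)
    ddf <- read.delim(dPath, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = c(mother = "character",
                                     father = "character"))
    stopifnot(identical(vdf$sample, ddf$sample))
    vals <- as.matrix(vdf[, -1L, drop = FALSE])
    rownames(vals) <- vdf$sample
    logScale <- TRUE
    mPath <- file.path(dir, "manifest.json")
    if (file.exists(mPath))
        logScale <- isTRUE(jsonlite::read_json(mPath)$logScale)
    exp <- DiallelExperiment(
        intensity = t(vals), genotype = ddf$genotype,
        mother = ifelse(ddf$mother == "", NA, ddf$mother),
        father = ifelse(ddf$father == "", NA, ddf$father),
        replicate = ddf$replicate, batch = ddf$batch,
        biomass = ddf$biomass, logScale = logScale)
    pid <- unique(ddf$genotype[ddf$mother == ""])
    rtab <- table(ddf$genotype)
    design <- makeDesign(pid, nReplicates = max(rtab),
                         nBatches = length(unique(ddf$batch)))
    truth <- NULL
    tPath <- file.path(dir, "truth.json")
    if (file.exists(tPath)) {
        tj <- jsonlite::read_json(tPath, simplifyVector = TRUE)
        asMat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
        lab <- asMat(tj$trueLabels$labels)
        storage.mode(lab) <- "integer"
        dimnames(lab) <- list(tj$trueLabels$hybrids,
                              tj$trueLabels$metabolites)
        be <- asMat(tj$batchEffects$values)
        storage.mode(be) <- "double"
        dimnames(be) <- list(tj$batchEffects$batches,
                             tj$batchEffects$metabolites)
        bw <- unlist(tj$biomassWeights)
        if (is.null(bw)) bw <- setNames(numeric(0), character(0))
        truth <- new("GroundTruth",
            driverFeatures = tj$driverFeatures,
            trueLabels = lab,
            biomassWeights = bw,
            noiseSd = tj$noiseSd,
            batchEffects = be,
            drivenMetabolites = as.character(tj$drivenMetabolites))
    }
    list(experiment = exp, design = design, truth = truth)
}
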