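#' Default pipeline configuration
#'
#' One nested list with every stage's tunables at its standard value:
#' outlier cutoff 4; CRL alpha 0.05 with BH adjustment; balance cut at
#' nine identical labels of twelve; 3-fold cross-validation with 25
#' repetitions over five classifier families; quartile decision rule;
#' 60/40 SVR splits with 500 repetitions and 5-feature subsets. The
#' simulate block reproduces the reference study dimensions: 4 parents,
#' 12 reciprocal hybrids, 6 replicates, 112 metabolites, 3 batches.
#'
#' @param seed master seed; per-stage seeds are derived from it and
#'   logged in the pipeline output.
#' @return named list of stage blocks.
#' @export
pipelineConfig <- function(seed = 1L) {
    list(
        simulate = list(parents = paste0("P", 1:4), nReplicates = 6L,
                        nBatches = 3L, m = 112L, nDrivers = 20L,
                        nDriven = 40L, effectSize = 2, noiseSd = 0.15,
                        batchSd = 0.1, maternalFraction = 0.75),
        normalization = list(outlierThreshold = 4),
        crl = list(alpha = 0.05, adjust = "BH", maxSame = NULL),
        screen = list(k = 3L, reps = 25L, methods = screenMethods(),
                      rule = "quartile", ntree = 500L, plsNcomp = 10L),
        ranking = list(rfe = FALSE),
        biomass = list(trainFrac = 0.6, reps = 500L,
                       schemes = defaultSchemes()),
        seed = as.integer(seed))
}

# per-stage substreams of the master seed (kept below 2^31)
stageSeed <- function(seed, stage) {
    offs <- c(simulate = 11L, xpp = 23L, screen = 37L, biomass = 53L,
              loo = 71L)
    (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Simulate a fixture directory from a pipeline config
#'
#' @param config a [pipelineConfig()] list (its \code{simulate} block and
#'   \code{seed} are used; the seed is required).
#' @param dir output directory.
#' @return the fixture manifest (invisibly), with the seed and stage
#'   parameters recorded.
#' @export
runSimulate <- function(config, dir) {
    if (is.null(config$seed))
        stop("config must carry a seed")
    sb <- config$simulate
    design <- makeDesign(sb$parents, sb$nReplicates, sb$nBatches)
    sim <- simulateDiallel(design, m = sb$m, nDrivers = sb$nDrivers,
                           nDriven = sb$nDriven,
                           effectSize = sb$effectSize,
                           noiseSd = sb$noiseSd, batchSd = sb$batchSd,
                           maternalFraction = sb$maternalFraction,
                           seed = stageSeed(config$seed, "simulate"))
    manifest <- writeFixture(sim$experiment, sim$truth, dir)
    manifest$seed <- config$seed
    manifest$parameters <- sb
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

#' Run CRL labeling, screening and ranking on one dataset
#'
#' The core analysis chain behind [runPipeline()] and [looStability()]:
#' CRL label assignment, balance filter, parental-pair matrix, classifier
#' screen, predictability decision, SVM feature ranks over the
#' predictable metabolites, rank aggregation.
#'
#' @param x a normalized \linkS4class{DiallelExperiment}.
#' @param design the \linkS4class{DiallelDesign}.
#' @param config a [pipelineConfig()] list.
#' @param hybridIds restrict to these hybrids (leave-one-out reruns).
#' @return list: \code{crl}, \code{xpp}, \code{screen}, \code{decision},
#'   \code{ranking} (NULL when nothing is predictable).
#' @export
rankingPipeline <- function(x, design, config = pipelineConfig(),
                            hybridIds = NULL) {
    crl <- assignLabels(x, design, alpha = config$crl$alpha,
                        adjust = config$crl$adjust,
                        hybridIds = hybridIds)
    crl <- balanceFilter(crl, maxSame = config$crl$maxSame)
    xpp <- buildXpp(x, design, seed = stageSeed(config$seed, "xpp"),
                    hybridIds = hybridIds)
    scr <- cvScreen(xpp, crl, methods = config$screen$methods,
                    k = config$screen$k, reps = config$screen$reps,
                    seed = stageSeed(config$seed, "screen"),
                    ntree = config$screen$ntree,
                    plsNcomp = config$screen$plsNcomp)
    dec <- decidePredictable(scr, rule = config$screen$rule)
    pred <- dec$metabolite[dec$predictable]
    ranking <- NULL
    if (length(pred)) {
        rks <- lapply(pred, function(met)
            svmFeatureRanks(xpp, metaboliteLabels(crl, met),
                            rfe = isTRUE(config$ranking$rfe)))
        names(rks) <- pred
        ranking <- aggregateRanks(rks)
    }
    list(crl = crl, xpp = xpp, screen = scr, decision = dec,
         ranking = ranking)
}

#' Run the full pipeline: normalize, CRL, screen, rank, biomass
#'
#' Executes the stages in their fixed order on an experiment (or a
#' fixture directory written by [runSimulate()]/[writeFixture()]) and,
#' when \code{outDir} is given, writes each stage's result as TSV/JSON.
#'
#' @param input a \linkS4class{DiallelExperiment} or a fixture directory.
#' @param design the \linkS4class{DiallelDesign} (inferred from the
#'   fixture when \code{input} is a directory).
#' @param config a [pipelineConfig()] list.
#' @param outDir optional output directory.
#' @return list: \code{normalization} (report), \code{crl}, \code{xpp},
#'   \code{screen}, \code{decision}, \code{ranking}, \code{biomass}
#'   (scheme evaluation, NULL when nothing is predictable), \code{seeds}
#'   (per-stage derived seeds).
#' @export
runPipeline <- function(input, design = NULL,
                        config = pipelineConfig(), outDir = NULL) {
    if (is.character(input)) {
        fx <- readFixture(input)
        x <- fx$experiment
        if (is.null(design)) design <- fx$design
    } else x <- input
    if (is.null(design))
        stop("a DiallelDesign is required when input is an experiment")
    norm <- normalizeDiallel(
        x, outlierThreshold = config$normalization$outlierThreshold)
    res <- rankingPipeline(norm$experiment, design, config)
    biomassEval <- NULL
    if (!is.null(res$ranking)) {
        bio <- alignBiomass(res$xpp, norm$experiment)
        schemes <- config$biomass$schemes
        nf <- nrow(rankSummary(res$ranking))
        schemes <- schemes[vapply(schemes, function(s) {
            n <- suppressWarnings(as.integer(
                sub("^.*?(top|bottom)([0-9]+).*$", "\\2", s)))
            is.na(n) || n <= nf
        }, logical(1L))]
        biomassEval <- evaluateSchemes(
            res$xpp, bio, res$ranking, schemes = schemes,
            trainFrac = config$biomass$trainFrac,
            reps = config$biomass$reps,
            seed = stageSeed(config$seed, "biomass"))
    }
    out <- list(normalization = norm$report, crl = res$crl,
                xpp = res$xpp, screen = res$screen,
                decision = res$decision, ranking = res$ranking,
                biomass = biomassEval,
                seeds = vapply(c("simulate", "xpp", "screen", "biomass"),
                               function(s) stageSeed(config$seed, s),
                               integer(1L)))
    if (!is.null(outDir)) writePipelineOutputs(out, outDir, config)
    out
}

writePipelineOutputs <- function(out, outDir, config) {
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    write.table(crlLabels(out$crl), file.path(outDir, "crl_labels.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    jsonlite::write_json(
        list(weights = as.list(crlWeights(out$crl)),
             genotypeDrops = genotypeDrops(out$crl)),
        file.path(outDir, "crl_meta.json"), auto_unbox = TRUE,
        digits = NA)
    write.table(as.data.frame(out$screen),
                file.path(outDir, "screen_errors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$decision, file.path(outDir, "screen_decision.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$ranking))
        write.table(rankSummary(out$ranking),
                    file.path(outDir, "feature_ranking.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    if (!is.null(out$biomass)) {
        write.table(out$biomass, file.path(outDir, "biomass_eval.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            apply(attr(out$biomass, "summary"), 1L, as.list),
            file.path(outDir, "biomass_summary.json"),
            auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(
        list(config = config, seeds = as.list(out$seeds)),
        file.path(outDir, "run_meta.json"), auto_unbox = TRUE,
        digits = NA)
    invisible(outDir)
}

#' Leave-one-hybrid-out stability of the feature ranking
#'
#' For every hybrid, reruns CRL labeling, screening and ranking with all
#' of that hybrid's replicates excluded, and compares each rank-ordering
#' to the full one by Spearman correlation of the median scaled ranks and
#' by the overlap of the top-20 feature sets.
#'
#' @param x a normalized \linkS4class{DiallelExperiment}.
#' @param design the \linkS4class{DiallelDesign}.
#' @param config a [pipelineConfig()] list.
#' @param full optional precomputed full-data [rankingPipeline()] result.
#' @return data.frame, one row per left-out hybrid: \code{hybrid},
#'   \code{spearman} (NA when the rerun has no predictable metabolites),
#'   \code{top20Overlap}, \code{nPredictable}.
#' @export
looStability <- function(x, design, config = pipelineConfig(),
                         full = NULL) {
    hb <- hybrids(design)
    if (nrow(hb) < 3L)
        stop("need at least 3 hybrids")
    if (is.null(full))
        full <- rankingPipeline(x, design, config)
    if (is.null(full$ranking))
        stop("full run has no predictable metabolites")
    fullMed <- setNames(rankSummary(full$ranking)$medianScaledRank,
                        rankSummary(full$ranking)$feature)
    fullTop <- topFeatures(full$ranking, 20L)
    out <- lapply(hb$id, function(h) {
        keepHyb <- setdiff(hb$id, h)
        keepCols <- !(x$genotype %in% h)
        res <- rankingPipeline(x[, keepCols], design, config,
                               hybridIds = keepHyb)
        if (is.null(res$ranking))
            return(data.frame(hybrid = h, spearman = NA_real_,
                              top20Overlap = NA_real_,
                              nPredictable = 0L))
        med <- setNames(rankSummary(res$ranking)$medianScaledRank,
                        rankSummary(res$ranking)$feature)
        common <- intersect(names(fullMed), names(med))
        data.frame(hybrid = h,
                   spearman = cor(fullMed[common], med[common],
                                  method = "spearman"),
                   top20Overlap =
                       length(intersect(fullTop,
                                        topFeatures(res$ranking, 20L))) /
                       min(20L, length(fullTop)),
                   nPredictable = ncol(rankMatrix(res$ranking)))
    })
    do.call(rbind, c(out, make.row.names = FALSE))
}
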