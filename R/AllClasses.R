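#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median sd var quantile cor rnorm runif setNames
#'   p.adjust pt pnorm lm model.matrix rstudent contr.sum digamma trigamma
#'   predict coef complete.cases
#' @importFrom utils head read.delim write.table
NULL

#' Diallel mating design
#'
#' Describes a full reciprocal diallel: every ordered pair of distinct
#' parents (mother x father, no selfs) is a hybrid genotype. With \eqn{p}
#' parents there are \eqn{p(p-1)} hybrids.
#'
#' @slot parents character vector of parent genotype identifiers.
#' @slot hybrids data.frame with columns \code{id}, \code{mother},
#'   \code{father}, one row per ordered hybrid.
#' @slot nReplicates integer, biological replicates per genotype.
#' @slot nBatches integer, number of measurement batches.
#'
#' @seealso [makeDesign()]
#' @exportClass DiallelDesign
setClass("DiallelDesign",
    representation(
        parents     = "character",
        hybrids     = "data.frame",
        nReplicates = "integer",
        nBatches    = "integer"
    )
)

setValidity("DiallelDesign", function(object) {
    msg <- character()
    p <- object@parents
    h <- object@hybrids
    if (anyDuplicated(p))
        msg <- c(msg, "duplicate parent identifiers")
    if (!all(c("id", "mother", "father") %in% names(h)))
        msg <- c(msg, "hybrids must have columns id, mother, father")
    else {
        if (!all(h$mother %in% p) || !all(h$father %in% p))
            msg <- c(msg, "hybrid parents must appear in 'parents'")
        if (any(h$mother == h$father))
            msg <- c(msg, "selfs are not allowed in a reciprocal diallel")
        want <- expand.grid(father = p, mother = p,
                            stringsAsFactors = FALSE)
        want <- want[want$mother != want$father, c("mother", "father")]
        if (nrow(h) != length(p) * (length(p) - 1L) ||
            anyDuplicated(paste(h$mother, h$father)))
            msg <- c(msg, sprintf(
                "expected all %d ordered parent pairs, got %d rows",
                length(p) * (length(p) - 1L), nrow(h)))
    }
    if (object@nReplicates < 2L)
        msg <- c(msg, "nReplicates must be >= 2 (variance estimation)")
    if (object@nBatches < 1L)
        msg <- c(msg, "nBatches must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Diallel metabolome experiment
#'
#' A \linkS4class{SummarizedExperiment} holding a metabolites x samples
#' log10-intensity assay with the per-sample annotations a diallel analysis
#' needs: \code{genotype}, \code{mother}, \code{father} (NA for inbreds),
#' \code{replicate}, \code{batch} and \code{biomass} (primary-root fresh
#' weight, mg). \code{metadata(x)$logScale} records whether the assay is on
#' the log10 scale.
#'
#' @seealso [DiallelExperiment()], [simulateDiallel()]
#' @exportClass DiallelExperiment
setClass("DiallelExperiment",
    contains = "SummarizedExperiment")

setValidity("DiallelExperiment", function(object) {
    msg <- character()
    need <- c("genotype", "mother", "father", "replicate", "batch", "biomass")
    miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
    if (length(miss))
        msg <- c(msg, paste("missing colData columns:",
                            paste(miss, collapse = ", ")))
    else {
        bm <- object$biomass
        if (any(!is.na(bm) & bm <= 0))
            msg <- c(msg, "biomass must be positive")
    }
    if (!length(SummarizedExperiment::assayNames(object)) ||
        SummarizedExperiment::assayNames(object)[1L] != "intensity")
        msg <- c(msg, "first assay must be named 'intensity'")
    if (length(msg)) msg else TRUE
})

#' Ground truth sidecar for a simulated diallel dataset
#'
#' Records what the generator planted so downstream stages can be scored:
#' which parental features drive hybrid outcomes, the true CRL label of
#' every (hybrid, metabolite) cell, the biomass effect of each driver, and
#' the nuisance parameters (replicate noise, batch offsets).
#'
#' @slot driverFeatures character, parental feature ids (metabolite id with
#'   \code{_m}/\code{_p} tag) that determine hybrid outcomes.
#' @slot trueLabels integer matrix, hybrids x metabolites, in {-2,...,2}.
#' @slot biomassWeights named numeric, per-driver effect on biomass (mg per
#'   standardized level unit).
#' @slot noiseSd numeric, replicate noise sd on the log10 scale.
#' @slot batchEffects numeric matrix, batches x metabolites, additive log10
#'   offsets.
#' @slot drivenMetabolites character, metabolites whose labels are driven.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(
        driverFeatures    = "character",
        trueLabels        = "matrix",
        biomassWeights    = "numeric",
        noiseSd           = "numeric",
        batchEffects      = "matrix",
        drivenMetabolites = "character"
    )
)

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (!length(object@driverFeatures))
        msg <- c(msg, "driverFeatures must be non-empty")
    if (!all(object@trueLabels %in% -2:2))
        msg <- c(msg, "trueLabels must be in {-2,-1,0,1,2}")
    if (length(msg)) msg else TRUE
})

#' Combined Relative Level (CRL) matrix
#'
#' Hybrids x metabolites class labels in {-2,-1,0,+1,+2}: +-2 positive /
#' negative overdominance (hybrid significantly outside the parental range),
#' +-1 positive/negative dominance (significantly beyond exactly one
#' parent), 0 additivity (indistinguishable from both parents, or
#' significantly between them). Carries the balance weights
#' \eqn{w_j \in \{0,1\}} and any per-metabolite genotype drops set by
#' [balanceFilter()].
#'
#' @slot labels integer matrix, hybrids x metabolites (NA = untestable).
#' @slot weights named numeric 0/1 per metabolite.
#' @slot genotypeDrops named list; per metabolite, hybrid ids whose rows are
#'   excluded for that metabolite only.
#' @slot classCounts integer matrix, 5 x metabolites, rows "-2".."2".
#' @slot alpha numeric, significance level used.
#'
#' @seealso [assignLabels()], [balanceFilter()]
#' @exportClass CRLMatrix
setClass("CRLMatrix",
    representation(
        labels        = "matrix",
        weights       = "numeric",
        genotypeDrops = "list",
        classCounts   = "matrix",
        alpha         = "numeric"
    )
)

setValidity("CRLMatrix", function(object) {
    msg <- character()
    if (!all(object@labels %in% c(-2:2, NA)))
        msg <- c(msg, "labels must be in {-2,-1,0,1,2} or NA")
    if (!all(object@weights %in% c(0, 1)))
        msg <- c(msg, "weights must be 0 or 1")
    if (length(object@weights) != ncol(object@labels))
        msg <- c(msg, "one weight per metabolite required")
    if (length(msg)) msg else TRUE
})

#' Concatenated parental-pair matrix
#'
#' One row per hybrid replicate: the maternal metabolite profile
#' concatenated with the paternal profile, so every metabolite appears
#' twice (tags \code{_m} and \code{_p}; 2m feature columns in total).
#' Maternal and paternal replicates are paired by a seeded random matching;
#' columns are mean-centered and scaled to unit variance.
#'
#' @slot values numeric matrix, (n_hybrids * r) x 2m.
#' @slot rowHybrid character, hybrid id per row.
#' @slot rowReplicate integer, hybrid replicate index per row.
#' @slot featureIds character, column ids (metabolite plus tag).
#' @slot featureTags character, "maternal" or "paternal" per column.
#' @slot pairingSeed integer seed used for the replicate matching.
#'
#' @seealso [buildXpp()]
#' @exportClass ParentalPairMatrix
setClass("ParentalPairMatrix",
    representation(
        values       = "matrix",
        rowHybrid    = "character",
        rowReplicate = "integer",
        featureIds   = "character",
        featureTags  = "character",
        pairingSeed  = "integer"
    )
)

setValidity("ParentalPairMatrix", function(object) {
    msg <- character()
    if (length(object@rowHybrid) != nrow(object@values))
        msg <- c(msg, "rowHybrid must have one entry per row")
    if (length(object@featureIds) != ncol(object@values))
        msg <- c(msg, "featureIds must have one entry per column")
    if (!all(object@featureTags %in% c("maternal", "paternal")))
        msg <- c(msg, "featureTags must be 'maternal' or 'paternal'")
    if (length(msg)) msg else TRUE
})

#' Global parental feature ranking
#'
#' Per parental feature, the scaled SVM feature-weight rank it received in
#' each predictable hybrid metabolite's classifier (rank 1 = most important,
#' scaled to (0, 1] by dividing by the number of features), and the median
#' of those scaled ranks, by which features are ordered.
#'
#' @slot ranks numeric matrix, features x predictable metabolites, scaled
#'   ranks in (0, 1].
#' @slot summary data.frame with columns \code{feature}, \code{tag},
#'   \code{medianScaledRank}, \code{nMetabolites}, sorted ascending by
#'   median scaled rank.
#'
#' @seealso [aggregateRanks()], [topFeatures()]
#' @exportClass FeatureRanking
setClass("FeatureRanking",
    representation(
        ranks   = "matrix",
        summary = "data.frame"
    )
)

setValidity("FeatureRanking", function(object) {
    msg <- character()
    r <- object@ranks
    if (length(r) && (any(r <= 0) || any(r > 1)))
        msg <- c(msg, "scaled ranks must lie in (0, 1]")
    if (!all(c("feature", "tag", "medianScaledRank") %in%
             names(object@summary)))
        msg <- c(msg, "summary needs feature, tag, medianScaledRank")
    if (length(msg)) msg else TRUE
})
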