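#' Simulate a full reciprocal diallel metabolome with known ground truth
#'
#' Generates a dataset with the structure the CRL analysis assumes: per
#' metabolite, parent means are drawn on the log10 scale (log-normal
#' intensities, as is typical of GC-MS peak heights); a small set of
#' parental \emph{driver features} (metabolite plus maternal/paternal tag,
#' 3:1 maternal by default) determines, through a deterministic threshold
#' function of the drivers' parental means, the true CRL label of each
#' \emph{driven} hybrid metabolite; hybrid replicate means follow the label
#' geometry (mid-parent for 0, at one parent for +-1, beyond the parental
#' range by \code{effectSize * noise units} for +-2); replicate noise and
#' per-(batch, metabolite) offsets are added; biomass is a baseline plus a
#' linear combination of the driver feature levels plus noise. All other
#' metabolites are additive (label 0, mid-parent hybrids).
#'
#' Driven labels are assigned by ranking the 12 (in general \eqn{p(p-1)})
#' per-hybrid driver scores and cutting at fixed proportions
#' (2:3:2:3:2 of hybrids into -2:-1:0:+1:+2), which keeps label sets
#' balanced by construction. With \code{effectSize = 0} no heterosis is
#' planted: all labels are 0 and all hybrid means are exactly mid-parent.
#'
#' The geometric unit for overdominant shifts is
#' \code{effectSize * max(noiseSd, 0.02)} so the planted geometry stays
#' strict (hybrid mean strictly outside the parental range) even in
#' noise-free fixtures.
#'
#' @param design a \linkS4class{DiallelDesign}.
#' @param m number of metabolites (default 112).
#' @param nDrivers number of planted driver parental features (distinct
#'   metabolites; default 20). Must satisfy \code{m >= 2 * nDrivers}.
#' @param nDriven number of driven hybrid metabolites (disjoint from the
#'   driver metabolites; default 40).
#' @param effectSize overdominant shift in units of \code{noiseSd}
#'   (default 2; 0 disables all heterosis).
#' @param noiseSd replicate noise sd, log10 scale (default 0.15).
#' @param batchSd sd of per-(batch, metabolite) offsets (default 0.1).
#' @param maternalFraction fraction of drivers tagged maternal (default
#'   0.75, i.e. 3:1).
#' @param parentTau sd of per-parent deviations around each metabolite's
#'   grand mean (default 0.5) for driver and driven metabolites.
#' @param backgroundTau parental spread of the remaining (background)
#'   metabolites (default \code{0.3 * parentTau}): background metabolites
#'   are only weakly genotype-structured, so their between-genotype
#'   variation is dominated by replicate noise, as is typical of the bulk
#'   of a GC-MS profile.
#' @param biomassBaseline,biomassBeta,biomassNoiseSd biomass model: baseline
#'   fresh weight (mg, default 60), total driver effect scale (default 8),
#'   residual sd (default 2).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list with elements \code{experiment}
#'   (\linkS4class{DiallelExperiment}, log10 scale) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' d <- makeDesign(paste0("P", 1:4), nReplicates = 6, nBatches = 3)
#' sim <- simulateDiallel(d, m = 30, nDrivers = 4, nDriven = 10, seed = 1)
#' dim(intensities(sim$experiment))  # 30 x 96
#' @export
simulateDiallel <- function(design, m = 112L, nDrivers = 20L,
                            nDriven = 40L, effectSize = 2,
                            noiseSd = 0.15, batchSd = 0.1,
                            maternalFraction = 0.75, parentTau = 0.5,
                            backgroundTau = 0.3 * parentTau,
                            biomassBaseline = 60, biomassBeta = 8,
                            biomassNoiseSd = 2, seed = 1L) {
    stopifnot(is(design, "DiallelDesign"))
    if (nDrivers > m)
        stop("nDrivers must not exceed m")
    if (m < 2L * nDrivers)
        stop("need m >= 2 * nDrivers so driven metabolites can be disjoint ",
             "from driver metabolites")
    if (noiseSd < 0 || batchSd < 0 || effectSize < 0)
        stop("effectSize, noiseSd and batchSd must be non-negative")
    set.seed(as.integer(seed))

    p <- parents(design)
    hb <- hybrids(design)
    r <- nReplicates(design)
    nb <- nBatches(design)
    mets <- sprintf("met%03d", seq_len(m))

    # parent means on log10 scale: metabolite grand mean ~ N(5, 1),
    # per-parent deviation ~ N(0, parentTau)
    mu <- rnorm(m, mean = 5, sd = 1)
    M <- matrix(rnorm(length(p) * m, sd = backgroundTau), length(p), m,
                dimnames = list(p, mets))
    M <- sweep(M, 2L, mu, "+")

    # planted drivers: distinct metabolites, tagged maternal/paternal
    noHeterosis <- effectSize == 0 || nDrivers == 0L || nDriven == 0L
    drvMet <- if (nDrivers > 0L) sample(mets, nDrivers) else character()
    # driven metabolites get well-separated parent means (a jittered
    # equispaced grid scaled by parentTau, randomly assigned to parents)
    # so the planted dominance geometry is detectable by construction
    gridSep <- function() {
        g <- (seq_along(p) - (length(p) + 1) / 2) * parentTau
        sample(g) + rnorm(length(p), sd = 0.05 * parentTau)
    }
    nMat <- round(maternalFraction * nDrivers)
    tags <- c(rep("maternal", nMat), rep("paternal", nDrivers - nMat))
    drvFeat <- paste0(drvMet, ifelse(tags == "maternal", "_m", "_p"))
    driven <- if (noHeterosis) character() else
        sample(setdiff(mets, drvMet), nDriven)
    for (j in c(drvMet, driven))
        M[, j] <- mu[match(j, mets)] + gridSep()

    # per-hybrid standardized driver levels (maternal tag reads the mother's
    # mean, paternal the father's)
    drvLevels <- function(mother, father) {
        lv <- mapply(function(met, tag) {
            src <- if (tag == "maternal") mother else father
            M[src, met]
        }, drvMet, tags)
        matrix(lv, nrow = length(mother))
    }
    Zh <- NULL
    if (nDrivers > 0L) {
        Zh <- drvLevels(hb$mother, hb$father)     # hybrids x drivers
        Zh <- scale(Zh)
        Zh[is.nan(Zh)] <- 0
    }

    # true labels: per driven metabolite, a random +-weighted combination of
    # 2-3 drivers, ranked over hybrids and cut at fixed 2:3:2:3:2 proportions
    nH <- nrow(hb)
    trueLab <- matrix(0L, nH, m, dimnames = list(hb$id, mets))
    cuts <- round(nH * cumsum(c(2, 3, 2, 3, 2)) / 12)
    cuts[5L] <- nH
    for (j in driven) {
        # every driver contributes, with fresh random signed weights per
        # metabolite: drivers are globally influential, as the rank
        # aggregation assumes
        w <- sample(c(-1, 1), nDrivers, replace = TRUE) *
            runif(nDrivers, 0.5, 1.5)
        sc <- as.vector(Zh %*% w)
        ord <- rank(sc, ties.method = "first")
        lab <- integer(nH)
        lab[ord <= cuts[1L]] <- -2L
        lab[ord > cuts[1L] & ord <= cuts[2L]] <- -1L
        lab[ord > cuts[2L] & ord <= cuts[3L]] <- 0L
        lab[ord > cuts[3L] & ord <= cuts[4L]] <- 1L
        lab[ord > cuts[4L]] <- 2L
        trueLab[, j] <- lab
    }

    # genotype means per metabolite following label geometry
    unit <- effectSize * max(noiseSd, 0.02)
    geno <- genotypeIds(design)
    G <- matrix(NA_real_, length(geno), m, dimnames = list(geno, mets))
    G[p, ] <- M
    for (i in seq_len(nH)) {
        mo <- M[hb$mother[i], ]
        fa <- M[hb$father[i], ]
        lo <- pmin(mo, fa); hi <- pmax(mo, fa)
        lab <- trueLab[i, ]
        G[hb$id[i], ] <- (mo + fa) / 2
        G[hb$id[i], lab == -2L] <- lo[lab == -2L] - unit
        G[hb$id[i], lab == -1L] <- lo[lab == -1L]
        G[hb$id[i], lab ==  1L] <- hi[lab ==  1L]
        G[hb$id[i], lab ==  2L] <- hi[lab ==  2L] + unit
    }

    # samples: r replicates per genotype; batches round-robin over a
    # randomized sample order (completely randomized measurement order)
    samGeno <- rep(geno, each = r)
    samRep <- rep(seq_len(r), times = length(geno))
    samId <- paste0(samGeno, "_r", samRep)
    n <- length(samId)
    batch <- integer(n)
    batch[sample.int(n)] <- rep(seq_len(nb), length.out = n)

    batchEff <- matrix(rnorm(nb * m, sd = batchSd), nb, m,
                       dimnames = list(paste0("batch", seq_len(nb)), mets))
    vals <- G[samGeno, , drop = FALSE] +
        matrix(rnorm(n * m, sd = noiseSd), n, m) +
        batchEff[batch, , drop = FALSE]
    rownames(vals) <- samId

    # biomass: baseline + linear combination of standardized driver levels
    # (a parent's own levels stand in for both tags) + noise
    bw <- setNames(numeric(0), character(0))
    biomassGeno <- setNames(rep(biomassBaseline, length(geno)), geno)
    if (nDrivers > 0L && !noHeterosis) {
        bw <- setNames(sample(c(-1, 1), nDrivers, replace = TRUE) *
                       runif(nDrivers, 0.5, 1.5) *
                       biomassBeta / sqrt(nDrivers), drvFeat)
        Zg <- rbind(drvLevels(p, p), drvLevels(hb$mother, hb$father))
        Zg <- scale(Zg)
        Zg[is.nan(Zg)] <- 0
        rownames(Zg) <- geno
        biomassGeno <- biomassGeno + as.vector(Zg %*% bw)
    }
    biomass <- biomassGeno[samGeno] + rnorm(n, sd = biomassNoiseSd)
    biomass <- pmax(biomass, 0.5)   # fresh weight cannot be negative

    hybLookup <- setNames(seq_len(nH), hb$id)
    isHyb <- samGeno %in% hb$id
    mother <- father <- rep(NA_character_, n)
    mother[isHyb] <- hb$mother[hybLookup[samGeno[isHyb]]]
    father[isHyb] <- hb$father[hybLookup[samGeno[isHyb]]]

    exp <- DiallelExperiment(
        intensity = t(vals), genotype = samGeno, mother = mother,
        father = father, replicate = samRep, batch = batch,
        biomass = biomass, logScale = TRUE)
    truth <- new("GroundTruth",
        driverFeatures = if (length(drvFeat)) drvFeat else "none",
        trueLabels = trueLab, biomassWeights = bw,
        noiseSd = noiseSd, batchEffects = batchEff,
        drivenMetabolites = driven)
    list(experiment = exp, truth = truth)
}

#' @rdname GroundTruth-class
#' @export
setMethod("driverFeatures", "GroundTruth",
    function(object) object@driverFeatures)

#' @rdname GroundTruth-class
#' @export
setMethod("trueLabels", "GroundTruth", function(object) object@trueLabels)

#' @rdname GroundTruth-class
#' @export
setMethod("drivenMetabolites", "GroundTruth",
    function(object) object@drivenMetabolites)

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth: ", length(object@driverFeatures), " driver features (",
        sum(grepl("_m$", object@driverFeatures)), " maternal), ",
        length(object@drivenMetabolites), " driven metabolites\n", sep = "")
    cat("  label matrix: ", nrow(object@trueLabels), " hybrids x ",
        ncol(object@trueLabels), " metabolites; noiseSd = ",
        object@noiseSd, "\n", sep = "")
})
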