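#' Build the concatenated parental-pair matrix
#'
#' Represents every hybrid replicate as the concatenation of one maternal
#' and one paternal replicate profile, giving an (n_hybrids * r) x 2m
#' matrix in which every metabolite appears twice (maternal tag \code{_m},
#' paternal \code{_p}). Within each hybrid, maternal and paternal
#' replicates are paired by a seeded random matching (each replicate used
#' once); columns are then mean-centered and scaled to unit variance.
#'
#' @param x a normalized \linkS4class{DiallelExperiment} (the parental
#'   samples are read from it).
#' @param design the \linkS4class{DiallelDesign}.
#' @param seed integer; same seed, same pairing, same matrix.
#' @param hybridIds restrict rows to these hybrids (default: all).
#' @return a \linkS4class{ParentalPairMatrix}.
#' @examples
#' d <- makeDesign(paste0("P", 1:4))
#' sim <- simulateDiallel(d, m = 112, nDrivers = 10, nDriven = 20, seed = 1)
#' xpp <- buildXpp(sim$experiment, d, seed = 7)
#' dim(xppValues(xpp))  # 72 x 224
#' @export
buildXpp <- function(x, design, seed = 1L, hybridIds = NULL) {
    stopifnot(is(design, "DiallelDesign"))
    set.seed(as.integer(seed))
    v <- intensities(x)
    # masked cells (outlier-removed replicates) cannot enter the
    # classifiers: impute from the same (genotype, metabolite) group's
    # unmasked replicates, falling back to the metabolite mean
    if (anyNA(v)) {
        for (g in unique(x$genotype)) {
            cols <- genotypeCols(x, g)
            blk <- v[, cols, drop = FALSE]
            if (!anyNA(blk)) next
            gm <- rowMeans(blk, na.rm = TRUE)
            gm[is.nan(gm)] <- rowMeans(v, na.rm = TRUE)[is.nan(gm)]
            for (jj in which(rowSums(is.na(blk)) > 0L))
                blk[jj, is.na(blk[jj, ])] <- gm[jj]
            v[, cols] <- blk
        }
    }
    mets <- rownames(v)
    hb <- hybrids(design)
    if (!is.null(hybridIds))
        hb <- hb[hb$id %in% hybridIds, , drop = FALSE]
    rows <- list(); rowHyb <- character(); rowRep <- integer()
    for (i in seq_len(nrow(hb))) {
        mo <- genotypeCols(x, hb$mother[i])
        fa <- genotypeCols(x, hb$father[i])
        r <- min(length(mo), length(fa))
        if (length(mo) != length(fa))
            warning("unequal replicate counts for ", hb$id[i],
                    "; pairing first ", r)
        pm <- sample(length(mo))[seq_len(r)]
        pf <- sample(length(fa))[seq_len(r)]
        blk <- cbind(t(v[, mo[pm], drop = FALSE]),
                     t(v[, fa[pf], drop = FALSE]))
        rows[[i]] <- blk
        rowHyb <- c(rowHyb, rep(hb$id[i], r))
        rowRep <- c(rowRep, seq_len(r))
    }
    mat <- do.call(rbind, rows)
    ids <- c(paste0(mets, "_m"), paste0(mets, "_p"))
    colnames(mat) <- ids
    rownames(mat) <- paste0(rowHyb, "_r", rowRep)
    sc <- autoscaleColumns(mat)
    new("ParentalPairMatrix",
        values = sc$matrix, rowHybrid = rowHyb,
        rowReplicate = rowRep, featureIds = ids,
        featureTags = rep(c("maternal", "paternal"), each = length(mets)),
        pairingSeed = as.integer(seed))
}

#' @rdname ParentalPairMatrix-class
#' @export
setMethod("xppValues", "ParentalPairMatrix", function(object) object@values)

#' @rdname ParentalPairMatrix-class
#' @export
setMethod("rowHybrid", "ParentalPairMatrix",
    function(object) object@rowHybrid)

#' @rdname ParentalPairMatrix-class
#' @export
setMethod("featureIds", "ParentalPairMatrix",
    function(object) object@featureIds)

#' @rdname ParentalPairMatrix-class
#' @export
setMethod("featureTags", "ParentalPairMatrix",
    function(object) object@featureTags)

setMethod("show", "ParentalPairMatrix", function(object) {
    cat("ParentalPairMatrix: ", nrow(object@values), " hybrid-replicate ",
        "rows x ", ncol(object@values), " parental features (",
        sum(object@featureTags == "maternal"), " maternal + ",
        sum(object@featureTags == "paternal"), " paternal)\n", sep = "")
    cat("  hybrids: ", length(unique(object@rowHybrid)),
        "; pairing seed: ", object@pairingSeed, "\n", sep = "")
})

#' Per-sample biomass aligned to the rows of a parental-pair matrix
#'
#' Each Xpp row stands for one hybrid replicate; this pulls the matching
#' hybrid replicate's biomass from the experiment.
#'
#' @param xpp a \linkS4class{ParentalPairMatrix}.
#' @param x the \linkS4class{DiallelExperiment} the matrix was built from.
#' @return numeric vector, one biomass value per Xpp row.
#' @export
alignBiomass <- function(xpp, x) {
    key <- paste0(x$genotype, "_r", x$replicate)
    want <- paste0(xpp@rowHybrid, "_r", xpp@rowReplicate)
    idx <- match(want, key)
    if (anyNA(idx))
        stop("missing hybrid replicate samples: ",
             paste(head(want[is.na(idx)]), collapse = ", "))
    setNames(x$biomass[idx], want)
}
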