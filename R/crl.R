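#' Assign Combined Relative Level labels to every hybrid metabolite
#'
#' For each hybrid, its replicate values are compared per metabolite to the
#' mother's and to the father's replicates with moderated t-statistics
#' (variances shrunk across the metabolite ensemble within each
#' hybrid-parent comparison). P-values are adjusted for multiplicity across
#' metabolites within each comparison family (Benjamini-Hochberg by
#' default) and converted to labels:
#' significantly above both parents +2, below both -2, beyond exactly one
#' parent +1/-1 (sign of that difference), indistinguishable from both or
#' significantly between the parents (above one, below the other) 0.
#'
#' @param x a normalized \linkS4class{DiallelExperiment}, log10 scale.
#' @param design the \linkS4class{DiallelDesign}.
#' @param alpha significance level (default 0.05).
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default "BH"; "none" disables it).
#' @param hybridIds restrict to these hybrids (default: all in the
#'   design; used e.g. by leave-one-hybrid-out reruns).
#' @return a \linkS4class{CRLMatrix} with all weights 1 (run
#'   [balanceFilter()] next). Untestable cells (fewer than 2 unmasked
#'   replicates in a group) are NA.
#' @export
assignLabels <- function(x, design, alpha = 0.05, adjust = "BH",
                         hybridIds = NULL) {
    stopifnot(is(design, "DiallelDesign"))
    v <- intensities(x)
    hb <- hybrids(design)
    if (!is.null(hybridIds))
        hb <- hb[hb$id %in% hybridIds, , drop = FALSE]
    for (pid in parents(design))
        if (length(genotypeCols(x, pid)) < 2L)
            stop("parent missing or unreplicated: ", pid)
    mets <- rownames(v)
    labels <- matrix(NA_integer_, nrow(hb), length(mets),
                     dimnames = list(hb$id, mets))
    for (i in seq_len(nrow(hb))) {
        hcols <- genotypeCols(x, hb$id[i])
        if (length(hcols) < 2L)
            stop("hybrid missing or unreplicated: ", hb$id[i])
        H <- v[, hcols, drop = FALSE]
        resM <- moderatedT(H, v[, genotypeCols(x, hb$mother[i]),
                                drop = FALSE])
        resF <- moderatedT(H, v[, genotypeCols(x, hb$father[i]),
                                drop = FALSE])
        pM <- p.adjust(resM$pValue, method = adjust)
        pF <- p.adjust(resF$pValue, method = adjust)
        labels[i, ] <- crlFromTests(resM$delta, pM, resF$delta, pF, alpha)
    }
    counts <- apply(labels, 2L, function(l)
        tabulate(factor(l, levels = -2:2), nbins = 5L))
    rownames(counts) <- as.character(-2:2)
    new("CRLMatrix", labels = labels,
        weights = setNames(rep(1, length(mets)), mets),
        genotypeDrops = setNames(vector("list", length(mets)), mets),
        classCounts = counts, alpha = alpha)
}

# signed significance pattern -> CRL label
crlFromTests <- function(deltaM, pM, deltaF, pF, alpha) {
    sigM <- !is.na(pM) & pM < alpha
    sigF <- !is.na(pF) & pF < alpha
    lab <- integer(length(pM))
    both <- sigM & sigF
    same <- both & sign(deltaM) == sign(deltaF)
    lab[same] <- 2L * sign(deltaM[same])
    # both significant, opposite sides (between the parents) stays 0
    oneM <- sigM & !sigF
    lab[oneM] <- sign(deltaM[oneM])
    oneF <- sigF & !sigM
    lab[oneF] <- sign(deltaF[oneF])
    lab[is.na(pM) | is.na(pF)] <- NA_integer_
    as.integer(lab)
}

#' @rdname CRLMatrix-class
#' @export
setMethod("crlLabels", "CRLMatrix", function(object) object@labels)

#' @rdname CRLMatrix-class
#' @export
setMethod("crlWeights", "CRLMatrix", function(object) object@weights)

#' @rdname CRLMatrix-class
#' @export
setMethod("genotypeDrops", "CRLMatrix",
    function(object) object@genotypeDrops)

#' @rdname CRLMatrix-class
#' @export
setMethod("classCounts", "CRLMatrix", function(object) object@classCounts)

setMethod("show", "CRLMatrix", function(object) {
    cat("CRLMatrix: ", nrow(object@labels), " hybrids x ",
        ncol(object@labels), " metabolites (alpha = ", object@alpha,
        ")\n", sep = "")
    cat("  label tally: ",
        paste(sprintf("%s:%d", rownames(object@classCounts),
                      rowSums(object@classCounts)), collapse = "  "),
        "\n", sep = "")
    cat("  balanced (w = 1): ", sum(object@weights == 1), " of ",
        length(object@weights), "; genotype drops: ",
        sum(lengths(object@genotypeDrops) > 0), "\n", sep = "")
})

#' Filter metabolites with unbalanced label sets
#'
#' Metabolites whose modal class label occurs more than \code{maxSame}
#' times across hybrids get weight 0 and are excluded from classification
#' (with 12 hybrids: at least nine identical labels of twelve). Among the
#' retained metabolites, a class represented by a single hybrid cannot be
#' stratified in cross-validation; instead of discarding such a
#' metabolite, the rows of the offending genotype are dropped for that
#' metabolite only (recorded in \code{genotypeDrops}) — equivalent to
#' brute-force enumeration of single-genotype removals that restore
#' stratifiability. If after drops fewer than 2 classes remain, or the
#' modal count exceeds the cut, the weight is zeroed after all.
#'
#' @param crl a \linkS4class{CRLMatrix}.
#' @param maxSame largest tolerated modal class count (default
#'   \code{ceiling(0.75 * n_hybrids) - 1}, i.e. 8 of 12).
#' @return the \linkS4class{CRLMatrix} with updated weights, genotype
#'   drops and class counts (rescued metabolites tallied without the
#'   dropped genotypes).
#' @export
balanceFilter <- function(crl, maxSame = NULL) {
    lab <- crl@labels
    nH <- nrow(lab)
    if (is.null(maxSame))
        maxSame <- as.integer(ceiling(0.75 * nH)) - 1L
    tallies <- function(l) table(factor(l[!is.na(l)], levels = -2:2))
    for (j in seq_len(ncol(lab))) {
        tab <- tallies(lab[, j])
        if (max(tab) > maxSame) { crl@weights[j] <- 0; next }
        keep <- !is.na(lab[, j])
        singleton <- names(tab)[tab == 1L]
        if (length(singleton)) {
            dropRows <- which(keep & lab[, j] %in% as.integer(singleton))
            crl@genotypeDrops[[j]] <- rownames(lab)[dropRows]
            keep[dropRows] <- FALSE
            tab <- tallies(lab[keep, j])
            crl@classCounts[, j] <-
                tabulate(factor(lab[keep, j], levels = -2:2), nbins = 5L)
        }
        if (sum(tab > 0L) < 2L || max(tab) > maxSame)
            crl@weights[j] <- 0
    }
    crl
}

#' Per-hybrid labels of one metabolite after genotype drops
#' @noRd
metaboliteLabels <- function(crl, metabolite) {
    l <- crl@labels[, metabolite]
    drop <- crl@genotypeDrops[[metabolite]]
    if (length(drop)) l <- l[!(names(l) %in% drop)]
    l[!is.na(l)]
}
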