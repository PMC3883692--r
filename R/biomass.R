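#' Select a parental feature subset from a ranking
#'
#' Scheme ids follow the pattern \code{top<N>} (the N best-ranked features
#' exactly), \code{rand<S>_of_top<N>} / \code{rand<S>_of_bottom<N>} (S
#' features sampled without replacement from the top-N or bottom-N pool),
#' \code{rand<S>} (S features sampled from all) and \code{all}.
#'
#' @param ranking a \linkS4class{FeatureRanking}.
#' @param scheme scheme id string.
#' @param seed integer seed (sampling is deterministic given the seed).
#' @return character vector of feature ids.
#' @examples
#' # selectSubset(rk, "rand5_of_top20", seed = 1)
#' @export
selectSubset <- function(ranking, scheme, seed = 1L) {
    sm <- rankSummary(ranking)
    feats <- sm$feature
    nf <- length(feats)
    pick <- function(pool, s) {
        if (s > length(pool))
            stop("subset size ", s, " exceeds pool of ", length(pool),
                 " in scheme ", scheme)
        set.seed(as.integer(seed))
        sample(pool, s)
    }
    if (scheme == "all")
        return(feats)
    m <- regmatches(scheme, regexec("^top([0-9]+)$", scheme))[[1L]]
    if (length(m)) {
        n <- as.integer(m[2L])
        if (n > nf) stop("subset size ", n, " exceeds pool of ", nf)
        return(head(feats, n))
    }
    m <- regmatches(scheme,
        regexec("^rand([0-9]+)_of_(top|bottom)([0-9]+)$", scheme))[[1L]]
    if (length(m)) {
        s <- as.integer(m[2L]); n <- as.integer(m[4L])
        if (n > nf) stop("pool size ", n, " exceeds ", nf, " features")
        pool <- if (m[3L] == "top") head(feats, n) else tail(feats, n)
        return(pick(pool, s))
    }
    m <- regmatches(scheme, regexec("^rand([0-9]+)$", scheme))[[1L]]
    if (length(m))
        return(pick(feats, as.integer(m[2L])))
    stop("unknown scheme: ", scheme)
}

#' Block-permute biomass over hybrid genotypes
#'
#' Permutes biomass at the hybrid level: all replicate values of one
#' hybrid move together to another hybrid's rows, preserving the multiset
#' of values and the within-hybrid replicate structure (the null for
#' "parental profiles predict biomass").
#'
#' @param biomass numeric, one value per Xpp row.
#' @param rowHybrid hybrid id per row.
#' @param seed integer seed.
#' @return permuted biomass vector, same length.
#' @export
blockPermuteBiomass <- function(biomass, rowHybrid, seed = 1L) {
    set.seed(as.integer(seed))
    permuteBlocks(biomass, rowHybrid)
}

# one draw of the hybrid-block permutation using the current RNG state
permuteBlocks <- function(biomass, rowHybrid) {
    hybs <- unique(rowHybrid)
    if (length(hybs) < 2L)
        stop("need at least 2 hybrids to permute")
    perm <- setNames(sample(hybs), hybs)
    out <- biomass
    for (h in hybs)
        out[rowHybrid == h] <- biomass[rowHybrid == perm[h]]
    out
}

#' Destroy the correlation structure of a parental-pair matrix
#'
#' Independently permutes every column across rows: column marginals
#' (means, sds) are preserved, row coherence -- and with it any real
#' association between profiles and biomass -- is destroyed.
#'
#' @param xpp a \linkS4class{ParentalPairMatrix}.
#' @param seed integer seed.
#' @return the matrix object with shuffled values.
#' @export
cellPermute <- function(xpp, seed = 1L) {
    set.seed(as.integer(seed))
    v <- xpp@values
    for (j in seq_len(ncol(v)))
        v[, j] <- v[sample.int(nrow(v)), j]
    xpp@values <- v
    xpp
}

# one SVR train/test repetition; genotype-coherent 60/40 split (a hybrid's
# replicate rows never straddle the split). Returns Pearson r, 0 with a
# flag when predictions are constant.
svrOnce <- function(X, biomass, rowHyb, trainFrac) {
    hybs <- unique(rowHyb)
    nTrain <- max(1L, round(trainFrac * length(hybs)))
    if (nTrain >= length(hybs)) nTrain <- length(hybs) - 1L
    trainHyb <- sample(hybs, nTrain)
    tr <- rowHyb %in% trainHyb
    pred <- tryCatch({
        fit <- e1071::svm(X[tr, , drop = FALSE], biomass[tr],
                          type = "eps-regression", kernel = "radial",
                          cost = 1, epsilon = 0.1)
        predict(fit, X[!tr, , drop = FALSE])
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(pred) || sd(pred) == 0 || sd(biomass[!tr]) == 0)
        return(c(r = 0, degenerate = 1))
    c(r = cor(pred, biomass[!tr]), degenerate = 0)
}

#' Evaluate biomass prediction from a fixed feature subset
#'
#' Repeatedly splits the hybrids 60/40 (replicate rows of one hybrid stay
#' on one side), fits an epsilon-SVR (radial kernel, cost 1, epsilon 0.1)
#' on the training rows restricted to the subset columns, and records the
#' Pearson correlation between predicted and observed test-set biomass.
#'
#' @param xpp a \linkS4class{ParentalPairMatrix}.
#' @param biomass numeric, one value per Xpp row (see [alignBiomass()]).
#' @param subset character vector of feature ids.
#' @param trainFrac training fraction of hybrids (default 0.6).
#' @param reps repetitions (default 500).
#' @param seed integer seed.
#' @return data.frame of class \code{"BiomassEvaluation"}: \code{rep},
#'   \code{r}, \code{degenerate}; quartile summary in
#'   \code{attr(, "summary")}.
#' @export
svrEvaluate <- function(xpp, biomass, subset, trainFrac = 0.6,
                        reps = 500L, seed = 1L) {
    if (!length(subset))
        stop("subset must be non-empty")
    stopifnot(length(biomass) == nrow(xpp@values))
    miss <- setdiff(subset, colnames(xpp@values))
    if (length(miss))
        stop("unknown features: ", paste(head(miss), collapse = ", "))
    set.seed(as.integer(seed))
    X <- xpp@values[, subset, drop = FALSE]
    res <- t(vapply(seq_len(reps), function(i)
        svrOnce(X, biomass, xpp@rowHybrid, trainFrac),
        c(r = 0, degenerate = 0)))
    out <- data.frame(rep = seq_len(reps), r = res[, "r"],
                      degenerate = res[, "degenerate"] == 1)
    class(out) <- c("BiomassEvaluation", "data.frame")
    attr(out, "summary") <- quantile(out$r, c(0.25, 0.5, 0.75))
    out
}

#' Default biomass evaluation scheme list
#'
#' Mirrors the standard comparison: the top-5 features, random fives from
#' growing top pools, random fives from growing bottom pools, all
#' features, and the nulls (block-permuted biomass for the top-5, a
#' random 5 and all features; cell-permuted profiles for the top-5 and a
#' random 5).
#' @return character vector of scheme ids.
#' @export
defaultSchemes <- function() c(
    "top5", "rand5_of_top10", "rand5_of_top20", "rand5_of_top50",
    "rand5_of_bottom10", "rand5_of_bottom20", "rand5_of_bottom50",
    "all",
    "top5_permbiomass", "rand5_permbiomass", "all_permbiomass",
    "top5_cellperm", "rand5_cellperm")

#' Evaluate a battery of feature-subset schemes against biomass
#'
#' Per scheme and repetition: a fresh feature subset is drawn (for
#' sampling schemes), the biomass vector is block-permuted (schemes
#' suffixed \code{_permbiomass}) or the profile matrix cell-permuted
#' (suffix \code{_cellperm}), the hybrids are split 60/40 and an SVR is
#' scored by test-set Pearson r.
#'
#' @param xpp a \linkS4class{ParentalPairMatrix}.
#' @param biomass numeric, one value per row.
#' @param ranking a \linkS4class{FeatureRanking}.
#' @param schemes scheme ids (default [defaultSchemes()]).
#' @param trainFrac,reps,seed as in [svrEvaluate()] (default 0.6, 500).
#' @return data.frame: \code{scheme}, \code{rep}, \code{r},
#'   \code{degenerate}; per-scheme quartiles in \code{attr(, "summary")}.
#' @export
evaluateSchemes <- function(xpp, biomass, ranking,
                            schemes = defaultSchemes(), trainFrac = 0.6,
                            reps = 500L, seed = 1L) {
    set.seed(as.integer(seed))
    sm <- rankSummary(ranking)
    out <- list()
    for (sc in schemes) {
        base <- sub("_(permbiomass|cellperm)$", "", sc)
        permBio <- grepl("_permbiomass$", sc)
        cellPerm <- grepl("_cellperm$", sc)
        rs <- numeric(reps); dg <- logical(reps)
        for (i in seq_len(reps)) {
            subset <- schemeSubsetDraw(sm$feature, base)
            X <- xpp@values[, subset, drop = FALSE]
            if (cellPerm)
                for (j in seq_len(ncol(X)))
                    X[, j] <- X[sample.int(nrow(X)), j]
            bio <- if (permBio)
                permuteBlocks(biomass, xpp@rowHybrid) else biomass
            v <- svrOnce(X, bio, xpp@rowHybrid, trainFrac)
            rs[i] <- v["r"]; dg[i] <- v["degenerate"] == 1
        }
        out[[sc]] <- data.frame(scheme = sc, rep = seq_len(reps), r = rs,
                                degenerate = dg,
                                stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, c(out, make.row.names = FALSE))
    smry <- do.call(rbind, lapply(split(res$r, res$scheme), quantile,
                                  probs = c(0.25, 0.5, 0.75)))
    attr(res, "summary") <- smry[schemes, , drop = FALSE]
    res
}

# subset draw using the current RNG state (fresh draw each repetition)
schemeSubsetDraw <- function(feats, scheme) {
    if (scheme == "all") return(feats)
    m <- regmatches(scheme, regexec("^top([0-9]+)$", scheme))[[1L]]
    if (length(m)) return(head(feats, as.integer(m[2L])))
    m <- regmatches(scheme,
        regexec("^rand([0-9]+)_of_(top|bottom)([0-9]+)$", scheme))[[1L]]
    if (length(m)) {
        pool <- if (m[3L] == "top") head(feats, as.integer(m[4L]))
            else tail(feats, as.integer(m[4L]))
        return(sample(pool, as.integer(m[2L])))
    }
    m <- regmatches(scheme, regexec("^rand([0-9]+)$", scheme))[[1L]]
    if (length(m)) return(sample(feats, as.integer(m[2L])))
    stop("unknown scheme: ", scheme)
}
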