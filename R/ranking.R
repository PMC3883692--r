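#' SVM feature-weight ranks for one hybrid metabolite
#'
#' Trains a linear SVM on all rows of the parental-pair matrix (no
#' cross-validation: features are ranked regardless of classifier
#' performance) and ranks features by importance, defined for multiclass
#' problems as the maximum absolute weight over the one-vs-one binary
#' machines. Rank 1 = most important; ties get averaged ranks; ranks are
#' scaled to (0, 1] by dividing by the feature count (2m). An optional
#' recursive-feature-elimination mode re-ranks by elimination order
#' (halving the feature set each round).
#'
#' @param xpp a \linkS4class{ParentalPairMatrix}.
#' @param hybLabels named vector of CRL labels, one per hybrid (as from
#'   the internal per-metabolite label accessor); at least 2 classes.
#' @param rfe use SVM-RFE instead of single-fit weights (default FALSE).
#' @param cost linear SVM cost (default 1).
#' @return numeric vector of scaled ranks, one per feature, named by
#'   feature id. \code{attr(, "degenerate")} is TRUE when all weights were
#'   zero (uniform ranks returned).
#' @export
svmFeatureRanks <- function(xpp, hybLabels, rfe = FALSE, cost = 1) {
    if (length(unique(hybLabels)) < 2L)
        stop("need at least 2 label classes")
    keep <- xpp@rowHybrid %in% names(hybLabels)
    X <- xpp@values[keep, , drop = FALSE]
    y <- factor(hybLabels[xpp@rowHybrid[keep]])
    nf <- ncol(X)
    if (!rfe) {
        imp <- svmImportance(X, y, cost)
    } else {
        # SVM-RFE: repeatedly drop the worse half; earlier-eliminated
        # features get worse (larger) importance-order positions
        alive <- seq_len(nf)
        elimOrder <- integer(0)
        while (length(alive) > 1L) {
            impA <- svmImportance(X[, alive, drop = FALSE], y, cost)
            nDrop <- max(1L, floor(length(alive) / 2))
            drop <- alive[order(impA)[seq_len(nDrop)]]
            elimOrder <- c(drop, elimOrder)
            alive <- setdiff(alive, drop)
        }
        elimOrder <- c(alive, elimOrder)
        imp <- numeric(nf)
        imp[elimOrder] <- seq(nf, 1L)    # survivor ranked best
    }
    degenerate <- all(abs(imp) < 1e-12)
    rk <- if (degenerate) rep((nf + 1) / 2, nf) else
        rank(-imp, ties.method = "average")
    out <- setNames(rk / nf, colnames(X))
    attr(out, "degenerate") <- degenerate
    out
}

# max |weight| over the one-vs-one machines of a linear e1071 SVM
svmImportance <- function(X, y, cost = 1) {
    fit <- e1071::svm(X, droplevels(y), kernel = "linear", cost = cost,
                      scale = FALSE)
    W <- ovoWeights(fit)
    apply(abs(W), 2L, max)
}

# per-machine primal weight vectors of a libsvm one-vs-one model.
# dual coefficients for the SVs of class c occupy the k-1 columns of
# $coefs in the order of the opposing classes; for the (i, j) machine the
# class-i SVs contribute column j-1 and the class-j SVs column i.
ovoWeights <- function(fit) {
    k <- fit$nclasses
    nsv <- fit$nSV
    start <- c(0L, cumsum(nsv))[seq_len(k)]
    W <- NULL
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
        ii <- start[i] + seq_len(nsv[i])
        jj <- start[j] + seq_len(nsv[j])
        w <- colSums(fit$SV[ii, , drop = FALSE] *
                     fit$coefs[ii, j - 1L]) +
             colSums(fit$SV[jj, , drop = FALSE] * fit$coefs[jj, i])
        W <- rbind(W, w)
    }
    W
}

#' Aggregate per-metabolite rank vectors into a global feature ranking
#'
#' The global importance of a parental feature is the median of its scaled
#' ranks over all predictable hybrid metabolites; features are ordered
#' ascending (low median rank = globally important).
#'
#' @param rankVectors numeric matrix features x metabolites (one column
#'   per predictable metabolite, as returned by [svmFeatureRanks()]), or a
#'   list of such vectors.
#' @param tags "maternal"/"paternal" per feature; inferred from the
#'   \code{_m}/\code{_p} suffix when NULL.
#' @return a \linkS4class{FeatureRanking}.
#' @export
aggregateRanks <- function(rankVectors, tags = NULL) {
    if (is.list(rankVectors))
        rankVectors <- do.call(cbind, rankVectors)
    if (is.null(dim(rankVectors)))
        rankVectors <- matrix(rankVectors,
                              dimnames = list(names(rankVectors), NULL))
    if (!ncol(rankVectors))
        stop("no predictable metabolites: nothing to aggregate")
    feats <- rownames(rankVectors)
    if (is.null(tags))
        tags <- ifelse(grepl("_m$", feats), "maternal", "paternal")
    med <- apply(rankVectors, 1L, median)
    sm <- data.frame(feature = feats, tag = tags,
                     medianScaledRank = med,
                     nMetabolites = ncol(rankVectors),
                     row.names = NULL, stringsAsFactors = FALSE)
    sm <- sm[order(sm$medianScaledRank, sm$feature), ]
    rownames(sm) <- NULL
    new("FeatureRanking", ranks = rankVectors, summary = sm)
}

#' @rdname FeatureRanking-class
#' @export
setMethod("rankMatrix", "FeatureRanking", function(object) object@ranks)

#' @rdname FeatureRanking-class
#' @export
setMethod("rankSummary", "FeatureRanking", function(object) object@summary)

setMethod("show", "FeatureRanking", function(object) {
    cat("FeatureRanking: ", nrow(object@summary), " parental features ",
        "over ", ncol(object@ranks), " predictable metabolites\n",
        sep = "")
    print(head(object@summary, 5L))
})

#' Best-ranked features
#' @param ranking a \linkS4class{FeatureRanking}.
#' @param k how many (default 20).
#' @return character vector of feature ids, best first.
#' @export
topFeatures <- function(ranking, k = 20L)
    head(rankSummary(ranking)$feature, k)

#' Maternal/paternal composition of the top of a ranking
#' @param ranking a \linkS4class{FeatureRanking}.
#' @param k rank cutoff (default 20).
#' @return named integer vector with counts of maternal and paternal
#'   features among the top k.
#' @export
parentalTagCounts <- function(ranking, k = 20L) {
    sm <- head(rankSummary(ranking), k)
    c(maternal = sum(sm$tag == "maternal"),
      paternal = sum(sm$tag == "paternal"))
}
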