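#' @importFrom e1071 svm
#' @importFrom randomForest randomForest
NULL

# classifier registry: each entry trains on (x, y) and predicts classes for
# newx. Hyperparameters: linear SVM cost 1 (linear weights are reused for
# ranking); LDA with a PCA fallback when the pooled covariance is singular;
# RF with ntree trees; PLS variants reduce to min(plsNcomp, rank) components
# first.
screenMethods <- function() c("svm", "lda", "plslda", "plsrf", "rf")

classDummy <- function(y) {
    out <- model.matrix(~ 0 + y)
    colnames(out) <- levels(y)
    out
}

ldaSafe <- function(x, y) {
    fit <- if (ncol(x) >= nrow(x)) NULL else
        tryCatch(suppressWarnings(MASS::lda(x, grouping = y)),
                 error = function(e) NULL)
    if (!is.null(fit))
        return(list(predict = function(newx)
            predict(fit, newx)$class))
    # singular pooled covariance: project on leading principal components
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    keep <- which(pc$sdev > 1e-8)
    keep <- head(keep, max(1L, min(nrow(x) - nlevels(y), length(keep))))
    sc <- pc$x[, keep, drop = FALSE]
    fit2 <- suppressWarnings(MASS::lda(sc, grouping = y))
    list(predict = function(newx) {
        nsc <- scale(newx, center = pc$center, scale = FALSE) %*%
            pc$rotation[, keep, drop = FALSE]
        predict(fit2, nsc)$class
    })
}

# PLS2 dimension reduction (regression mode): per component the X-weight
# is the leading left singular vector of X'Y; X is deflated by the score's
# loading. Train and test rows are projected with the same weight/loading
# sequence. Scores agree with mixOmics::pls(mode = "regression",
# scale = FALSE) up to sign (cross-checked in the test suite).
plsScores <- function(xtr, ytr, xte, plsNcomp) {
    Y <- classDummy(ytr)
    ncomp <- min(plsNcomp, ncol(xtr), nrow(xtr) - 1L)
    xm <- colMeans(xtr)
    ym <- colMeans(Y)
    Xd <- sweep(xtr, 2L, xm); Yd <- sweep(Y, 2L, ym)
    Xnew <- sweep(xte, 2L, xm)
    Ttr <- matrix(0, nrow(xtr), ncomp)
    Tte <- matrix(0, nrow(xte), ncomp)
    for (h in seq_len(ncomp)) {
        w <- svd(crossprod(Xd, Yd), nu = 1L, nv = 0L)$u[, 1L]
        t_ <- Xd %*% w
        tt <- sum(t_^2)
        if (tt < 1e-12) { Ttr <- Ttr[, seq_len(h - 1L), drop = FALSE]
                          Tte <- Tte[, seq_len(h - 1L), drop = FALSE]
                          break }
        p_ <- crossprod(Xd, t_) / tt
        Ttr[, h] <- t_
        Tte[, h] <- Xnew %*% w
        Xd <- Xd - tcrossprod(t_, p_)
        Xnew <- Xnew - tcrossprod(Tte[, h], p_)
        Yd <- Yd - tcrossprod(t_, crossprod(Yd, t_) / tt)
    }
    colnames(Ttr) <- colnames(Tte) <- paste0("comp", seq_len(ncol(Ttr)))
    rownames(Tte) <- rownames(xte)
    list(train = Ttr, test = Tte)
}

trainAndPredict <- function(method, xtr, ytr, xte,
                            ntree = 500L, plsNcomp = 10L) {
    ytr <- droplevels(ytr)
    switch(method,
        svm = {
            fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = 1,
                              scale = FALSE)
            predict(fit, xte)
        },
        lda = ldaSafe(xtr, ytr)$predict(xte),
        rf = {
            fit <- randomForest::randomForest(xtr, ytr, ntree = ntree)
            predict(fit, xte)
        },
        plslda = {
            sc <- plsScores(xtr, ytr, xte, plsNcomp)
            fit <- ldaSafe(sc$train, ytr)
            fit$predict(sc$test)
        },
        plsrf = {
            sc <- plsScores(xtr, ytr, xte, plsNcomp)
            fit <- randomForest::randomForest(sc$train, ytr, ntree = ntree)
            predict(fit, sc$test)
        },
        stop("unknown method: ", method))
}

# stratified genotype-level fold assignment: hybrids of each class dealt
# round-robin to k folds so replicate rows never straddle train/test;
# redraws until every fold's training set covers all classes
foldHybrids <- function(hybLabels, k, maxTries = 20L) {
    hybs <- names(hybLabels)
    for (try in seq_len(maxTries)) {
        fold <- setNames(integer(length(hybs)), hybs)
        for (cl in unique(hybLabels)) {
            members <- sample(hybs[hybLabels == cl])
            fold[members] <- (sample.int(k, 1L) +
                              seq_along(members)) %% k + 1L
        }
        ok <- all(vapply(seq_len(k), function(f) {
            length(unique(hybLabels[fold != f])) ==
                length(unique(hybLabels)) && any(fold == f)
        }, logical(1L)))
        if (ok) return(fold)
    }
    NULL
}

#' Screen hybrid metabolites for parental-profile predictability
#'
#' Per balanced hybrid metabolite, decides whether the parental-pair
#' matrix predicts its CRL labels better than chance by repeated
#' cross-validation: each repetition builds one genotype-block permuted
#' label vector (replicate rows of a hybrid keep a common label), draws a
#' stratified 3-fold split at the hybrid level (independent splits for the
#' original and permuted runs), trains every classifier on each fold
#' complement, and records the median misclassification rate over folds.
#'
#' @param xpp a \linkS4class{ParentalPairMatrix}.
#' @param crl a balance-filtered \linkS4class{CRLMatrix}.
#' @param metabolites metabolite ids to screen (default: all with weight
#'   1 and at least 2 label classes).
#' @param methods classifier subset (default all five:
#'   \code{c("svm","lda","plslda","plsrf","rf")}).
#' @param k folds (default 3).
#' @param reps repetitions (default 25).
#' @param seed integer seed; full run is reproducible.
#' @param ntree random-forest trees (default 500).
#' @param plsNcomp PLS components before LDA/RF (default 10, capped at the
#'   matrix rank).
#' @return data.frame of class \code{"ScreenResult"}: columns
#'   \code{metabolite}, \code{method}, \code{rep}, \code{split}
#'   ("original"/"permuted"), \code{error}. Metabolites that could not be
#'   screened are in \code{attr(, "flagged")}.
#' @seealso [decidePredictable()]
#' @export
cvScreen <- function(xpp, crl, metabolites = NULL,
                     methods = screenMethods(), k = 3L, reps = 25L,
                     seed = 1L, ntree = 500L, plsNcomp = 10L) {
    stopifnot(all(methods %in% screenMethods()))
    set.seed(as.integer(seed))
    X <- xpp@values
    if (is.null(metabolites))
        metabolites <- names(crl@weights)[crl@weights == 1]
    out <- list(); flagged <- character()
    for (met in metabolites) {
        hybLab <- metaboliteLabels(crl, met)
        if (length(unique(hybLab)) < 2L) {
            if (length(unique(hybLab)) == 1L && length(metabolites) == 1L)
                stop("single-class labels for ", met)
            flagged <- c(flagged, met); next
        }
        res <- screenOne(X, xpp@rowHybrid, hybLab, methods, k, reps,
                         ntree, plsNcomp)
        if (is.null(res)) { flagged <- c(flagged, met); next }
        res$metabolite <- met
        out[[met]] <- res
    }
    if (!length(out) && length(metabolites) == 1L &&
        length(flagged) == 1L)
        stop("metabolite not screenable (single class or unsplittable): ",
             flagged)
    res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
        else data.frame(method = character(), rep = integer(),
                        split = character(), error = numeric(),
                        metabolite = character())
    res <- res[, c("metabolite", "method", "rep", "split", "error")]
    class(res) <- c("ScreenResult", "data.frame")
    attr(res, "flagged") <- flagged
    attr(res, "reps") <- reps
    res
}

screenOne <- function(X, rowHyb, hybLab, methods, k, reps, ntree,
                      plsNcomp) {
    keep <- rowHyb %in% names(hybLab)
    Xs <- X[keep, , drop = FALSE]
    rh <- rowHyb[keep]
    rec <- expand.grid(method = methods, rep = seq_len(reps),
                       split = c("original", "permuted"),
                       stringsAsFactors = FALSE)
    rec$error <- NA_real_
    for (rep_ in seq_len(reps)) {
        permLab <- setNames(sample(unname(hybLab)), names(hybLab))
        for (split in c("original", "permuted")) {
            lab <- if (split == "original") hybLab else permLab
            fold <- foldHybrids(lab, k)
            if (is.null(fold)) return(NULL)
            y <- factor(lab[rh])
            foldErr <- matrix(NA_real_, k, length(methods),
                              dimnames = list(NULL, methods))
            for (f in seq_len(k)) {
                te <- fold[rh] == f
                for (mth in methods) {
                    pred <- trainAndPredict(
                        mth, Xs[!te, , drop = FALSE], y[!te],
                        Xs[te, , drop = FALSE],
                        ntree = ntree, plsNcomp = plsNcomp)
                    foldErr[f, mth] <-
                        mean(as.character(pred) !=
                             as.character(y[te]))
                }
            }
            sel <- rec$rep == rep_ & rec$split == split
            rec$error[sel] <- apply(foldErr, 2L, median)[rec$method[sel]]
        }
    }
    rec
}

#' Decide which metabolites are predictable from parental profiles
#'
#' Per metabolite, the two classifier families with the lowest median
#' misclassification under both the original and the permuted runs are
#' selected (rank-sum over the two lists; ties broken by mean error, then
#' by fixed method order). Under the primary quartile rule the metabolite
#' is predictable iff, for both selected methods, the third quartile of
#' the original median errors lies below the first quartile of the
#' permuted median errors (Delta = Q1(permuted) - Q3(original) > 0) --
#' stricter than comparing medians. The alternative minimum-median rule
#' (predictable iff the minimum original median error over all methods is
#' lower than the minimum permuted median error) is also evaluated; both
#' verdicts are reported and \code{rule} picks which fills
#' \code{predictable}.
#'
#' @param result a \code{"ScreenResult"} from [cvScreen()].
#' @param rule \code{"quartile"} (primary) or \code{"min-median"}.
#' @return data.frame, one row per screened metabolite: selected methods,
#'   their Delta values, \code{predictableQuartile},
#'   \code{predictableMinMedian} and \code{predictable}.
#' @export
decidePredictable <- function(result, rule = c("quartile", "min-median")) {
    rule <- match.arg(rule)
    stopifnot(inherits(result, "ScreenResult"))
    methodOrder <- screenMethods()
    out <- lapply(split(as.data.frame(result), result$metabolite),
                  function(d) {
        stat <- do.call(rbind, lapply(split(d, d$method), function(m) {
            orig <- m$error[m$split == "original"]
            perm <- m$error[m$split == "permuted"]
            data.frame(method = m$method[1L],
                       medOrig = median(orig), medPerm = median(perm),
                       meanOrig = mean(orig),
                       q3Orig = quantile(orig, 0.75, names = FALSE),
                       q1Perm = quantile(perm, 0.25, names = FALSE),
                       stringsAsFactors = FALSE)
        }))
        if (nrow(stat) < 2L)
            return(data.frame(metabolite = d$metabolite[1L],
                              method1 = stat$method[1L], method2 = NA,
                              delta1 = NA_real_, delta2 = NA_real_,
                              predictableQuartile = FALSE,
                              predictableMinMedian =
                                  min(stat$medOrig) < min(stat$medPerm),
                              stringsAsFactors = FALSE))
        sel <- order(rank(stat$medOrig, ties.method = "min") +
                     rank(stat$medPerm, ties.method = "min"),
                     stat$meanOrig,
                     match(stat$method, methodOrder))[1:2]
        delta <- stat$q1Perm[sel] - stat$q3Orig[sel]
        data.frame(metabolite = d$metabolite[1L],
                   method1 = stat$method[sel[1L]],
                   method2 = stat$method[sel[2L]],
                   delta1 = delta[1L], delta2 = delta[2L],
                   predictableQuartile = all(delta > 0),
                   predictableMinMedian =
                       min(stat$medOrig) < min(stat$medPerm),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(out, make.row.names = FALSE))
    out$predictable <- if (rule == "quartile") out$predictableQuartile
        else out$predictableMinMedian
    out
}

#' Analytic chance misclassification rate of a label vector
#'
#' One minus the modal class frequency: the error of always predicting the
#' majority class, the best a label-independent classifier can do.
#'
#' @param labels vector of class labels (one per row or per hybrid).
#' @return numeric in [0, 1).
#' @export
chanceRate <- function(labels) {
    labels <- labels[!is.na(labels)]
    1 - max(table(labels)) / length(labels)
}
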