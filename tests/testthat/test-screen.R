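test_that("the parental-pair matrix has 2m autoscaled paired columns", {
    d <- fourParentDesign()
    sim <- simulateDiallel(d, m = 112, nDrivers = 10, nDriven = 20,
                           seed = 4)
    norm <- normalizeDiallel(sim$experiment)
    xpp <- buildXpp(norm$experiment, d, seed = 9)
    expect_equal(dim(xppValues(xpp)), c(72L, 224L))    # 12*6 x 2*112
    expect_equal(sum(featureTags(xpp) == "maternal"), 112L)
    expect_lt(max(abs(colMeans(xppValues(xpp)))), 1e-10)
    expect_lt(max(abs(apply(xppValues(xpp), 2, sd) - 1)), 1e-10)
    expect_true(all(table(rowHybrid(xpp)) == 6L))

    # replicate pairing is seeded: same seed, same matrix
    again <- buildXpp(norm$experiment, d, seed = 9)
    expect_identical(xppValues(xpp), xppValues(again))
    other <- buildXpp(norm$experiment, d, seed = 10)
    expect_false(identical(xppValues(xpp), xppValues(other)))
})

test_that("internal PLS scores match mixOmics regression-mode PLS", {
    skip_if_not_installed("mixOmics")
    set.seed(12)
    X <- matrix(rnorm(60 * 25), 60, 25)
    colnames(X) <- paste0("f", 1:25)
    y <- factor(sample(c("a", "b", "c"), 60, TRUE))
    Xte <- matrix(rnorm(30 * 25), 30, 25)
    colnames(Xte) <- colnames(X)
    got <- diallelCRL:::plsScores(X, y, Xte, 8)
    fit <- mixOmics::pls(X, diallelCRL:::classDummy(y), ncomp = 8,
                         mode = "regression", scale = FALSE)
    pr <- predict(fit, newdata = Xte)
    sgn <- sign(colSums(got$train * unclass(fit$variates$X)))
    expect_equal(sweep(got$train, 2, sgn, "*"),
                 unname(unclass(fit$variates$X)),
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(sweep(got$test, 2, sgn, "*"),
                 unname(unclass(pr$variates)),
                 ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("fold assignment keeps replicate rows together and classes covered", {
    lab <- twoClassLabels(12L)
    set.seed(5)
    for (i in 1:20) {
        fold <- diallelCRL:::foldHybrids(lab, 3L)
        expect_equal(sort(unique(fold)), 1:3)
        for (f in 1:3)
            expect_setequal(unique(lab[fold != f]), unique(lab))
    }
})

test_that("separable labels screen at zero error, permuted near chance", {
    lab <- twoClassLabels(12L)
    xpp <- syntheticXpp(nf = 10, informative = 1L, hybLabels = lab,
                        seed = 31)
    crl <- singleMetaboliteCrl(lab)
    scr <- cvScreen(xpp, crl, methods = c("svm", "lda"), reps = 10,
                    seed = 7)
    orig <- scr$error[scr$split == "original" & scr$method == "svm"]
    perm <- scr$error[scr$split == "permuted"]
    expect_equal(median(orig), 0)
    # analytic chance rate for balanced 6/6 labels is 0.5
    expect_lt(abs(mean(perm) - 0.5), 0.1)
    dec <- decidePredictable(scr, rule = "quartile")
    expect_true(dec$predictableQuartile)
    expect_true(dec$predictableMinMedian)
})

test_that("label-independent features are not declared predictable", {
    # 20 genotype blocks: enough that chance feature-label alignment in
    # the small genotype pool does not mimic real signal
    verdicts <- vapply(1:10, function(s) {
        lab <- twoClassLabels(20L)
        xpp <- syntheticXpp(nHyb = 20L, nf = 10, seed = 100 + s)
        crl <- singleMetaboliteCrl(lab)
        scr <- cvScreen(xpp, crl, methods = c("svm", "lda"), reps = 10,
                        seed = s)
        decidePredictable(scr, rule = "quartile")$predictableQuartile
    }, logical(1))
    expect_gte(mean(!verdicts), 0.9)
})

test_that("screen results are reproducible under a fixed seed", {
    lab <- twoClassLabels(12L)
    xpp <- syntheticXpp(nf = 8, informative = 1L, hybLabels = lab,
                        seed = 3)
    crl <- singleMetaboliteCrl(lab)
    a <- cvScreen(xpp, crl, methods = c("svm", "plslda"), reps = 5,
                  seed = 42)
    b <- cvScreen(xpp, crl, methods = c("svm", "plslda"), reps = 5,
                  seed = 42)
    expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("single-class labels are rejected", {
    lab <- setNames(rep(0L, 12), paste0("h", 1:12))
    xpp <- syntheticXpp(nf = 6, seed = 2)
    crl <- singleMetaboliteCrl(lab)
    expect_error(cvScreen(xpp, crl, methods = "svm", reps = 2, seed = 1),
                 "single")
})

test_that("the quartile rule is stricter than the minimum-median rule", {
    # overlapping error distributions: medians differ but Q3(orig) >
    # Q1(perm) -> only the minimum-median rule calls it predictable
    orig <- c(rep(0.2, 13), rep(0.5, 12))     # median 0.2, Q3 0.5
    perm <- c(rep(0.3, 13), rep(0.6, 12))     # median 0.3, Q1 0.3
    rec <- rbind(
        data.frame(metabolite = "m1", method = "svm",
                   rep = 1:25, split = "original", error = orig),
        data.frame(metabolite = "m1", method = "svm",
                   rep = 1:25, split = "permuted", error = perm),
        data.frame(metabolite = "m1", method = "lda",
                   rep = 1:25, split = "original", error = orig),
        data.frame(metabolite = "m1", method = "lda",
                   rep = 1:25, split = "permuted", error = perm))
    class(rec) <- c("ScreenResult", "data.frame")
    dec <- decidePredictable(rec)
    expect_false(dec$predictableQuartile)
    expect_true(dec$predictableMinMedian)
    # sanity: quartiles behave as constructed
    expect_gt(quantile(orig, 0.75), quantile(perm, 0.25))
    expect_lt(min(median(orig)), min(median(perm)))
})

test_that("chance rate is one minus the modal class frequency", {
    expect_equal(chanceRate(c(0, 0, 0, 1)), 0.25)
    expect_equal(chanceRate(rep(c(-1, 0, 1), c(2, 6, 4))), 0.5)
})
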