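rawExperiment <- function(vals, ...) {
    x <- tinyExperiment(...)
    S4Vectors::metadata(x)$logScale <- FALSE
    if (!missing(vals)) SummarizedExperiment::assay(x, "intensity") <- vals
    x
}

test_that("log transform is log10 and rejects non-positive cells", {
    x <- tinyExperiment(list(g1 = 0, g2 = 0), r = 2L, m = 3L, sd = 0)
    v <- matrix(c(1, 10, 100, 1000, 10, 1), 3, 4)
    dimnames(v) <- dimnames(intensities(x))
    x <- rawExperiment(v, genoMeans = list(g1 = 0, g2 = 0), r = 2L,
                       m = 3L, sd = 0)
    out <- logTransform(x)
    expect_equal(unname(intensities(out)[, 1]), c(0, 1, 2))
    expect_true(isLogScale(out))
    expect_error(logTransform(out), "already")

    v[2, 2] <- -5
    bad <- rawExperiment(v, genoMeans = list(g1 = 0, g2 = 0), r = 2L,
                         m = 3L, sd = 0)
    expect_error(logTransform(bad), "met002")
})

test_that("planted batch offsets are recovered and removed exactly", {
    # zero replicate noise, +0.5 on batch 2: correction must restore the
    # pre-injection table to numerical precision
    clean <- tinyExperiment(list(g1 = 1, g2 = 2, g3 = 0.5), r = 4L,
                            m = 6L, sd = 0, nBatches = 2L, seed = 4)
    injected <- clean
    v <- intensities(injected)
    v[, injected$batch == 2L] <- v[, injected$batch == 2L] + 0.5
    SummarizedExperiment::assay(injected, "intensity") <- v
    out <- removeBatchEffects(injected)
    eff <- out$report$batchEffectsRemoved
    # sum-to-zero parametrization splits the offset across batches
    expect_equal(unname(eff[, 2] - eff[, 1]), rep(0.5, 6),
                 tolerance = 1e-9)
    # sum-to-zero correction restores the clean table up to the overall
    # +0.25 grand-mean shift the injection introduced
    expect_equal(intensities(out$experiment),
                 intensities(clean) + 0.25, tolerance = 1e-9)
})

test_that("single-batch and zero-offset tables pass through unchanged", {
    x <- tinyExperiment(list(g1 = 1, g2 = 2), r = 3L, m = 4L, sd = 0.1,
                        nBatches = 1L)
    out <- removeBatchEffects(x)
    expect_identical(intensities(out$experiment), intensities(x))

    x2 <- tinyExperiment(list(g1 = 1, g2 = 2), r = 6L, m = 4L, sd = 0,
                         nBatches = 2L)
    out2 <- removeBatchEffects(x2)
    expect_equal(intensities(out2$experiment), intensities(x2),
                 tolerance = 1e-12)
})

test_that("a planted spike is the only masked cell", {
    x <- tinyExperiment(list(g1 = 1, g2 = 2, g3 = 3), r = 6L, m = 5L,
                        sd = 0.05, nBatches = 2L, seed = 8)
    v <- intensities(x)
    v["met003", 4L] <- v["met003", 4L] + 10 * 0.05 * 10
    SummarizedExperiment::assay(x, "intensity") <- v
    out <- removeOutliers(x, threshold = 4)
    rep <- out$report$outliersRemoved
    expect_equal(nrow(rep), 1L)
    expect_equal(rep$metabolite, "met003")
    expect_equal(rep$sample, colnames(v)[4L])
    expect_true(is.na(intensities(out$experiment)["met003", 4L]))

    # infinite threshold: nothing masked
    none <- removeOutliers(x, threshold = Inf)
    expect_equal(nrow(none$report$outliersRemoved), 0L)
})

test_that("outlier detection matches brute-force studentized residuals", {
    # identical replicates plus one spike: compute the externally
    # studentized residual by direct leave-one-out arithmetic
    x <- tinyExperiment(list(g1 = 1, g2 = 2), r = 5L, m = 1L, sd = 0.01,
                        nBatches = 1L, seed = 2)
    v <- intensities(x)
    v[1, 3] <- v[1, 3] + 1
    SummarizedExperiment::assay(x, "intensity") <- v
    # brute-force external studentization: residual of the spiked cell
    # against the fit refitted without it
    grp <- factor(x$genotype)
    fitLoo <- lm(v[1, -3] ~ grp[-3])
    predLoo <- mean(v[1, -3][grp[-3] == grp[3]])
    s <- summary(fitLoo)$sigma
    h <- 1 / sum(grp == grp[3])          # leverage of a group-mean fit
    tExt <- (v[1, 3] - predLoo) / (s * sqrt(1 + h))
    expect_gt(abs(tExt), 4)
    out <- removeOutliers(x, threshold = 4)
    expect_equal(out$report$outliersRemoved$sample, colnames(v)[3])
    expect_equal(nrow(out$report$outliersRemoved), 1L)
})

test_that("sample scaling removes per-sample level shifts exactly", {
    x <- tinyExperiment(list(g1 = 1, g2 = 2), r = 6L, m = 11L, sd = 0.1,
                        seed = 5)
    v0 <- intensities(x)
    v <- v0; v[, 3] <- v[, 3] + 0.7      # one sample shifted by c
    SummarizedExperiment::assay(x, "intensity") <- v
    out <- scaleSamples(x)
    f <- out$report$scaleFactors
    base <- scaleSamples({
        y <- x; SummarizedExperiment::assay(y, "intensity") <- v0; y
    })$report$scaleFactors
    # the injected sample also moves its genotype-group median a little,
    # so removal of c is exact only up to that shift
    expect_lt(abs(unname(f[3] - base[3]) - 0.7), 0.1)
    expect_lt(max(abs(f[-3] - base[-3])), 0.1)

    # identical replicates scale to identical rows
    y <- tinyExperiment(list(g1 = 1), r = 2L, m = 5L, sd = 0, seed = 1)
    vy <- intensities(y); vy[, 2] <- vy[, 2] + 1
    SummarizedExperiment::assay(y, "intensity") <- vy
    sy <- scaleSamples(y)
    expect_equal(intensities(sy$experiment)[, 1],
                 intensities(sy$experiment)[, 2], tolerance = 1e-12)
})

test_that("column autoscaling yields zero mean, unit sd, idempotently", {
    set.seed(9)
    m <- matrix(rnorm(20 * 5, mean = 3, sd = 2), 20, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    out <- autoscaleColumns(m)
    expect_lt(max(abs(colMeans(out$matrix))), 1e-10)
    expect_lt(max(abs(apply(out$matrix, 2, sd) - 1)), 1e-10)
    twice <- autoscaleColumns(out$matrix)
    expect_equal(twice$matrix, out$matrix, tolerance = 1e-10)

    m[, 2] <- 1
    expect_error(autoscaleColumns(m), "f2")
    dropped <- autoscaleColumns(m, dropConstant = TRUE)
    expect_equal(dropped$report$dropped, "f2")
    expect_equal(ncol(dropped$matrix), 4L)
})

test_that("clean Gaussian fixtures rarely lose cells at threshold 4", {
    hits <- vapply(1:20, function(s) {
        x <- tinyExperiment(list(g1 = 1, g2 = 2, g3 = 3), r = 6L,
                            m = 10L, sd = 0.1, nBatches = 3L, seed = s)
        nrow(removeOutliers(x)$report$outliersRemoved)
    }, numeric(1))
    # 180 cells/fixture, per-cell tail prob 2*P(t_12 > 4) ~ 1.8e-3:
    # expected ~6.5 false positives over the 3600 cells; assert a
    # generous upper bound on the total (well under 1 per 100 cells)
    expect_lt(sum(hits), 20)
    expect_lt(sum(hits) / 3600, 0.01)
})
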