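test_that("forced geometry yields the expected labels", {
    # hybrid 10 sigma above both parents -> +2; crossing pattern -> 0
    d <- makeDesign(c("A", "B"), 6L, 1L)
    set.seed(21)
    m <- 20L; r <- 6L
    geno <- rep(c("A", "B", "AxB", "BxA"), each = r)
    sd0 <- 0.1
    vals <- matrix(rnorm(m * length(geno), sd = sd0), m, length(geno))
    aCols <- geno == "A"; bCols <- geno == "B"
    h1 <- geno == "AxB"; h2 <- geno == "BxA"
    vals[, bCols] <- vals[, bCols] + 1          # B one unit above A
    vals[, h1] <- vals[, h1] + 2                # above both (10 sigma)
    vals[, h2] <- vals[, h2] + 0.5              # between the parents
    colnames(vals) <- paste0(geno, "_r", rep(seq_len(r), 4))
    rownames(vals) <- sprintf("met%03d", seq_len(m))
    x <- DiallelExperiment(vals, genotype = geno,
                           mother = c(A = NA, B = NA, AxB = "A",
                                      BxA = "B")[geno],
                           father = c(A = NA, B = NA, AxB = "B",
                                      BxA = "A")[geno],
                           replicate = rep(seq_len(r), 4),
                           batch = rep(1L, length(geno)),
                           biomass = rep(50, length(geno)),
                           logScale = TRUE)
    crl <- assignLabels(x, d)
    expect_true(all(crlLabels(crl)["AxB", ] == 2L))
    # significantly above one parent, below the other: additivity (0)
    expect_true(all(crlLabels(crl)["BxA", ] == 0L))
})

test_that("labels on zero-noise planted fixtures equal the ground truth", {
    d <- fourParentDesign()
    sim <- simulateDiallel(d, m = 24, nDrivers = 5, nDriven = 10,
                           effectSize = 5, noiseSd = 0, batchSd = 0,
                           seed = 31)
    crl <- assignLabels(sim$experiment, d)
    expect_identical(unname(crlLabels(crl)),
                     unname(trueLabels(sim$truth)))
})

test_that("negating all values flips every label's sign", {
    d <- fourParentDesign()
    sim <- simulateDiallel(d, m = 12, nDrivers = 3, nDriven = 6,
                           effectSize = 4, noiseSd = 0.05, seed = 17)
    x <- sim$experiment
    crl1 <- assignLabels(x, d)
    neg <- x
    SummarizedExperiment::assay(neg, "intensity") <- -intensities(x)
    crl2 <- assignLabels(neg, d)
    expect_identical(crlLabels(crl2), -crlLabels(crl1))
})

test_that("under the global null nonzero labels stay near the alpha level", {
    d <- fourParentDesign()
    fracs <- vapply(1:10, function(s) {
        x <- nullDiallelExperiment(d, m = 40, sd = 0.2, seed = s)
        crl <- assignLabels(x, d, alpha = 0.05)
        mean(crlLabels(crl) != 0L)
    }, numeric(1))
    expect_lt(mean(fracs), 2 * 0.05 + 0.02)
})

test_that("balance filter drops overdominant-modal columns at 9 of 12", {
    lab <- matrix(0L, 12, 4,
                  dimnames = list(paste0("h", 1:12),
                                  paste0("met", 1:4)))
    lab[1:9, 1] <- 0L;  lab[10:12, 1] <- 1L     # modal 9 -> removed
    lab[1:8, 2] <- 0L;  lab[9:12, 2] <- 1L      # modal 8 -> kept
    lab[, 3] <- rep(c(0L, 1L), 6)               # balanced -> kept
    lab[1:6, 4] <- 0L; lab[7:12, 4] <- 1L       # balanced -> kept
    crl <- balanceFilter(crlFromLabels(lab))
    expect_equal(unname(crlWeights(crl)), c(0, 1, 1, 1))
})

test_that("singleton classes are cured by dropping that genotype's rows", {
    # retained metabolite (modal 7 of 12) with one single-member class:
    # stratified 3-fold CV cannot place a 1-member class on both sides,
    # so the genotype is dropped for this metabolite instead
    lab <- matrix(0L, 12, 1, dimnames = list(paste0("h", 1:12), "metX"))
    lab[1:7, 1] <- 0L; lab[8:11, 1] <- 1L; lab[12, 1] <- 2L
    crl <- balanceFilter(crlFromLabels(lab))
    # brute force over single-genotype removals: the only removal that
    # leaves every remaining class with >= 2 members is h12
    cure <- vapply(1:12, function(i) {
        tab <- table(lab[-i, 1])
        all(tab[tab > 0] >= 2) && length(tab[tab > 0]) >= 2
    }, logical(1))
    expect_equal(rownames(lab)[which(cure)], "h12")
    expect_equal(unname(crlWeights(crl)), 1)
    expect_equal(genotypeDrops(crl)[["metX"]], "h12")
    # tally excludes the dropped genotype
    expect_equal(sum(classCounts(crl)[, 1]), 11L)

    # a singleton whose removal leaves a single class is not rescuable
    lab2 <- matrix(0L, 8, 1, dimnames = list(paste0("h", 1:8), "metY"))
    lab2[8, 1] <- 1L   # modal 7 of 8 > ceiling(6)-1 = 5 -> removed anyway
    crl2 <- balanceFilter(crlFromLabels(lab2))
    expect_equal(unname(crlWeights(crl2)), 0)
})
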