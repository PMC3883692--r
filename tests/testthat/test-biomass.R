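rankingOfFeatures <- function(feats) {
    rv <- matrix(seq_along(feats) / length(feats),
                 dimnames = list(feats, NULL))
    aggregateRanks(rv)
}

test_that("subset schemes draw from the documented pools", {
    feats <- paste0("f", sprintf("%02d", 1:30),
                    rep(c("_m", "_p"), 15))
    rk <- rankingOfFeatures(feats)
    expect_equal(selectSubset(rk, "top5"), feats[1:5])
    expect_equal(selectSubset(rk, "all"), feats)
    s1 <- selectSubset(rk, "rand5_of_top10", seed = 1)
    s2 <- selectSubset(rk, "rand5_of_top10", seed = 2)
    expect_length(s1, 5L)
    expect_true(all(s1 %in% feats[1:10]))
    expect_true(all(s2 %in% feats[1:10]))
    expect_identical(s1, selectSubset(rk, "rand5_of_top10", seed = 1))
    sb <- selectSubset(rk, "rand5_of_bottom10", seed = 3)
    expect_true(all(sb %in% feats[21:30]))
    # coupon-collector union: repeated draws cover the whole pool
    un <- unique(unlist(lapply(1:60, function(s)
        selectSubset(rk, "rand5_of_top20", seed = s))))
    expect_setequal(un, feats[1:20])
    expect_error(selectSubset(rk, "top40"), "exceeds")
    expect_error(selectSubset(rk, "nonsense"), "unknown scheme")
})

test_that("block permutation moves replicate blocks intact", {
    rowHyb <- rep(paste0("h", 1:6), each = 4)
    bio <- rep(1:6 * 10, each = 4) + rep(c(0, 1, 2, 3), 6)
    perm <- blockPermuteBiomass(bio, rowHyb, seed = 5)
    expect_setequal(perm, bio)
    # within-block variance profile preserved
    pv <- vapply(split(perm, rowHyb), var, numeric(1))
    ov <- vapply(split(bio, rowHyb), var, numeric(1))
    expect_setequal(unname(round(pv, 12)), unname(round(ov, 12)))

    # two hybrids: identity or full swap only
    rh2 <- rep(c("a", "b"), each = 3)
    b2 <- c(1, 2, 3, 10, 20, 30)
    seen <- vapply(1:20, function(s)
        paste(blockPermuteBiomass(b2, rh2, seed = s), collapse = ","),
        character(1))
    expect_true(all(seen %in% c("1,2,3,10,20,30", "10,20,30,1,2,3")))
    expect_error(blockPermuteBiomass(1:3, rep("a", 3), seed = 1),
                 "at least 2")
})

test_that("cell permutation preserves column marginals, destroys rows", {
    xpp <- syntheticXpp(nf = 8, seed = 4)
    shuf <- cellPermute(xpp, seed = 9)
    expect_equal(colMeans(xppValues(shuf)), colMeans(xppValues(xpp)))
    expect_equal(apply(xppValues(shuf), 2, sd),
                 apply(xppValues(xpp), 2, sd))
    expect_false(identical(xppValues(shuf), xppValues(xpp)))
    expect_identical(xppValues(cellPermute(xpp, seed = 9)),
                     xppValues(shuf))
})

test_that("SVR recovers a noiseless single-feature biomass signal", {
    xpp <- syntheticXpp(nHyb = 12, r = 4, nf = 6, seed = 14)
    bio <- 50 + 10 * xppValues(xpp)[, 2]
    ev <- svrEvaluate(xpp, bio, subset = colnames(xppValues(xpp))[2],
                      reps = 50, seed = 3)
    expect_equal(nrow(ev), 50L)
    expect_gt(median(ev$r), 0.99)
})

test_that("feature-independent biomass centers near zero correlation", {
    xpp <- syntheticXpp(nHyb = 12, r = 4, nf = 6, seed = 15)
    set.seed(8)
    bio <- 50 + rnorm(nrow(xppValues(xpp)), sd = 5)
    ev <- svrEvaluate(xpp, bio, subset = colnames(xppValues(xpp))[1:3],
                      reps = 200, seed = 4)
    expect_lt(abs(median(ev$r)), 0.15)
})

test_that("degenerate fits are recorded as r = 0 with a flag", {
    xpp <- syntheticXpp(nHyb = 6, r = 2, nf = 4, seed = 16)
    bio <- rep(42, nrow(xppValues(xpp)))      # constant outcome
    ev <- svrEvaluate(xpp, bio, subset = colnames(xppValues(xpp))[1],
                      reps = 5, seed = 1)
    expect_true(all(ev$degenerate))
    expect_true(all(ev$r == 0))
})

test_that("scheme evaluation orders planted signal above nulls", {
    xpp <- syntheticXpp(nHyb = 12, r = 4, nf = 12, seed = 17)
    feats <- colnames(xppValues(xpp))
    bio <- 50 + 8 * xppValues(xpp)[, 1] + 5 * xppValues(xpp)[, 2] +
        rnorm(nrow(xppValues(xpp)), sd = 1)
    rk <- rankingOfFeatures(feats)       # features 1,2 best-ranked
    ev <- evaluateSchemes(xpp, bio, rk,
                          schemes = c("top5", "rand5_of_bottom5",
                                      "top5_permbiomass"),
                          reps = 60, seed = 21)
    sm <- attr(ev, "summary")
    expect_gt(sm["top5", "50%"], sm["rand5_of_bottom5", "50%"])
    expect_gt(sm["top5", "50%"], sm["top5_permbiomass", "50%"] + 0.3)
    expect_equal(unname(table(ev$scheme)), rep(60L, 3L),
                 ignore_attr = TRUE)
})
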