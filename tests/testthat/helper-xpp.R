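# directly constructed parental-pair matrices for screen/ranking/biomass
# tests: nHyb hybrids x r replicate rows, nf feature columns of pure
# noise, with optional informative columns carrying the labels at a given
# separation
syntheticXpp <- function(nHyb = 12L, r = 4L, nf = 10L,
                         informative = integer(0), hybLabels = NULL,
                         sep = 4, seed = 1L) {
    set.seed(seed)
    hybs <- paste0("h", seq_len(nHyb))
    rowHyb <- rep(hybs, each = r)
    X <- matrix(rnorm(nHyb * r * nf), nHyb * r, nf)
    if (length(informative)) {
        stopifnot(!is.null(hybLabels))
        sig <- as.numeric(factor(hybLabels[rowHyb]))
        for (j in informative)
            X[, j] <- sig * sep + rnorm(length(sig), sd = 0.1)
    }
    colnames(X) <- paste0("met", sprintf("%02d", seq_len(nf)),
                          rep(c("_m", "_p"), length.out = nf))
    X <- scale(X)
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    new("ParentalPairMatrix", values = X, rowHybrid = rowHyb,
        rowReplicate = rep(seq_len(r), nHyb),
        featureIds = colnames(X),
        featureTags = ifelse(grepl("_m$", colnames(X)), "maternal",
                             "paternal"),
        pairingSeed = as.integer(seed))
}

# CRLMatrix with one metabolite whose per-hybrid labels are given
singleMetaboliteCrl <- function(hybLabels, metabolite = "metX") {
    lab <- matrix(as.integer(hybLabels), ncol = 1,
                  dimnames = list(names(hybLabels), metabolite))
    crlFromLabels(lab)
}

# balanced two-class labels over nHyb hybrids
twoClassLabels <- function(nHyb = 12L) {
    setNames(rep(c(0L, 1L), length.out = nHyb),
             paste0("h", seq_len(nHyb)))
}
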