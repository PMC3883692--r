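# Small fixtures built in code; all randomness is explicitly seeded.

fourParentDesign <- function(r = 6L, b = 3L)
    makeDesign(c("UH002", "UH005", "UH250", "UH301"), r, b)

# hand-built experiment: g genotypes (first two inbred-like), r replicates,
# values N(mean, sd) per genotype, optional per-batch offsets
tinyExperiment <- function(genoMeans, r = 4L, m = 5L, sd = 0.1,
                           batchOffsets = NULL, nBatches = 2L,
                           seed = 1L) {
    set.seed(seed)
    g <- length(genoMeans)
    geno <- rep(names(genoMeans), each = r)
    n <- g * r
    batch <- rep(seq_len(nBatches), length.out = n)
    vals <- matrix(rnorm(m * n, sd = sd), m, n)
    vals <- vals + matrix(rep(unlist(genoMeans), each = r), m, n,
                          byrow = TRUE)
    if (!is.null(batchOffsets))
        vals <- vals + matrix(batchOffsets[batch], m, n, byrow = TRUE)
    colnames(vals) <- paste0(geno, "_r", rep(seq_len(r), g))
    rownames(vals) <- sprintf("met%03d", seq_len(m))
    DiallelExperiment(vals, genotype = geno,
                      mother = rep(NA_character_, n),
                      father = rep(NA_character_, n),
                      replicate = rep(seq_len(r), g), batch = batch,
                      biomass = rep(50, n), logScale = TRUE)
}

# all genotypes of a full diallel identically distributed (global null)
nullDiallelExperiment <- function(design, m = 30L, sd = 0.2, seed = 1L) {
    set.seed(seed)
    geno <- genotypeIds(design)
    r <- nReplicates(design)
    n <- length(geno) * r
    vals <- matrix(rnorm(m * n, mean = 5, sd = sd), m, n)
    colnames(vals) <- paste0(rep(geno, each = r), "_r",
                             rep(seq_len(r), length(geno)))
    rownames(vals) <- sprintf("met%03d", seq_len(m))
    hb <- hybrids(design)
    gvec <- rep(geno, each = r)
    idx <- match(gvec, hb$id)
    DiallelExperiment(vals, genotype = gvec,
                      mother = hb$mother[idx], father = hb$father[idx],
                      replicate = rep(seq_len(r), length(geno)),
                      batch = rep(seq_len(nBatches(design)),
                                  length.out = n),
                      biomass = rep(50, n), logScale = TRUE)
}

# a CRLMatrix built directly from a label matrix (for filter tests)
crlFromLabels <- function(lab) {
    counts <- apply(lab, 2L, function(l)
        tabulate(factor(l, levels = -2:2), nbins = 5L))
    rownames(counts) <- as.character(-2:2)
    new("CRLMatrix", labels = lab,
        weights = setNames(rep(1, ncol(lab)), colnames(lab)),
        genotypeDrops = setNames(vector("list", ncol(lab)),
                                 colnames(lab)),
        classCounts = counts, alpha = 0.05)
}

# standard strong-effect simulated dataset used across screen/ranking
# tests: 14 parents keep the parental feature space well-conditioned so
# planted drivers are identifiable (see the methods vignette)
strongEffectSim <- function(seed, p = 14L, m = 24L, r = 4L,
                            nDrivers = 6L, nDriven = 10L,
                            effectSize = 5, noiseSd = 0.1) {
    d <- makeDesign(paste0("P", seq_len(p)), r, 3L)
    sim <- simulateDiallel(d, m = m, nDrivers = nDrivers,
                           nDriven = nDriven, effectSize = effectSize,
                           noiseSd = noiseSd, batchSd = 0.1, seed = seed)
    sim$design <- d
    sim
}
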