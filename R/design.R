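#' Construct a full reciprocal diallel design
#'
#' Enumerates every ordered pair of distinct parents (mother x father, no
#' selfs). With \eqn{p} parents this gives \eqn{p(p-1)} hybrid genotypes;
#' 4 parents give 12 hybrids and, together with the inbreds, 16 genotypes.
#' Hybrid ordering is deterministic: mothers in parent order, then fathers.
#'
#' @param parentIds character vector (>= 2) of distinct parent identifiers.
#' @param nReplicates biological replicates per genotype (>= 2; replicate
#'   variance must be estimable).
#' @param nBatches number of measurement batches (>= 1).
#' @return A \linkS4class{DiallelDesign}.
#' @examples
#' d <- makeDesign(c("UH002", "UH005", "UH250", "UH301"))
#' nrow(hybrids(d))  # 12
#' @export
makeDesign <- function(parentIds, nReplicates = 6L, nBatches = 3L) {
    parentIds <- as.character(parentIds)
    if (length(parentIds) < 2L)
        stop("need at least two parents")
    if (anyDuplicated(parentIds))
        stop("duplicate parent ids: ",
             paste(unique(parentIds[duplicated(parentIds)]), collapse = ", "))
    if (nReplicates < 2L)
        stop("nReplicates must be >= 2: replicate variance is inestimable ",
             "with a single replicate")
    pairs <- do.call(rbind, lapply(parentIds, function(mo) {
        fa <- setdiff(parentIds, mo)
        data.frame(mother = mo, father = fa, stringsAsFactors = FALSE)
    }))
    pairs$id <- hybridId(pairs$mother, pairs$father)
    new("DiallelDesign",
        parents = parentIds,
        hybrids = pairs[, c("id", "mother", "father")],
        nReplicates = as.integer(nReplicates),
        nBatches = as.integer(nBatches))
}

#' @return character id of an ordered cross, mother first.
#' @noRd
hybridId <- function(mother, father) paste0(mother, "x", father)

#' @rdname DiallelDesign-class
#' @export
setMethod("parents", "DiallelDesign", function(object) object@parents)

#' @rdname DiallelDesign-class
#' @export
setMethod("hybrids", "DiallelDesign", function(object) object@hybrids)

#' @rdname DiallelDesign-class
#' @export
setMethod("nReplicates", "DiallelDesign",
    function(object) object@nReplicates)

#' @rdname DiallelDesign-class
#' @export
setMethod("nBatches", "DiallelDesign", function(object) object@nBatches)

#' All genotype ids of a design: parents, then hybrids
#' @param design a \linkS4class{DiallelDesign}.
#' @return character vector of genotype ids.
#' @export
genotypeIds <- function(design) c(parents(design), hybrids(design)$id)

setMethod("show", "DiallelDesign", function(object) {
    p <- length(object@parents)
    cat("DiallelDesign: full reciprocal diallel\n")
    cat("  parents (", p, "): ",
        paste(object@parents, collapse = ", "), "\n", sep = "")
    cat("  hybrids: ", nrow(object@hybrids), " ordered crosses (p(p-1))\n",
        sep = "")
    cat("  replicates per genotype: ", object@nReplicates,
        "; batches: ", object@nBatches, "\n", sep = "")
})
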