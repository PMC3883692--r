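#' Build a DiallelExperiment
#'
#' Thin constructor around \linkS4class{SummarizedExperiment}: assay
#' \code{intensity} is metabolites x samples; sample annotations carry the
#' diallel structure and the biomass phenotype.
#'
#' @param intensity numeric matrix, metabolites x samples, with rownames
#'   (metabolite ids) and colnames (sample ids).
#' @param genotype,mother,father,replicate,batch,biomass per-sample vectors;
#'   \code{mother}/\code{father} are NA for inbred samples.
#' @param logScale logical, whether \code{intensity} is already log10.
#' @return A \linkS4class{DiallelExperiment}.
#' @export
DiallelExperiment <- function(intensity, genotype, mother, father,
                              replicate, batch, biomass,
                              logScale = FALSE) {
    cd <- S4Vectors::DataFrame(
        genotype = as.character(genotype),
        mother = as.character(mother),
        father = as.character(father),
        replicate = as.integer(replicate),
        batch = as.integer(batch),
        biomass = as.numeric(biomass),
        row.names = colnames(intensity))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensity), colData = cd)
    S4Vectors::metadata(se)$logScale <- isTRUE(logScale)
    new("DiallelExperiment", se)
}

#' Assay accessor for a DiallelExperiment
#' @param x a \linkS4class{DiallelExperiment}.
#' @return metabolites x samples numeric matrix.
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

`intensities<-` <- function(x, value) {
    SummarizedExperiment::assay(x, "intensity") <- value
    x
}

#' Is the assay on the log10 scale?
#' @param x a \linkS4class{DiallelExperiment}.
#' @export
isLogScale <- function(x) isTRUE(S4Vectors::metadata(x)$logScale)

#' Column indices of a genotype's samples
#' @noRd
genotypeCols <- function(x, genotype) which(x$genotype == genotype)

setMethod("show", "DiallelExperiment", function(object) {
    callNextMethod()
    gt <- table(object$genotype)
    cat("genotypes: ", length(gt), " (replicates ",
        paste(range(gt), collapse = "-"), "); batches: ",
        length(unique(object$batch)),
        "; scale: ", if (isLogScale(object)) "log10" else "raw",
        "\n", sep = "")
})
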