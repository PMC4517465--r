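#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' RipCountSet: 3'UTR read counts with sample metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one integer `counts` assay (genes x samples) and the sample annotation
#' the RIP-seq design needs: `sample_id`, `assay` (one of `"rip"`, `"sham"`,
#' `"mrna"`), `condition` (free-text arm label, e.g. `"control-sponge"` or
#' `"miR-124-sponge"`) and `replicate` (positive integer). Row names are
#' gene identifiers and must be unique.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [RipCountSet()] for construction, [readCountTable()] for file
#'   input.
#' @export
setClass("RipCountSet", contains = "SummarizedExperiment")

setValidity("RipCountSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(m))
            msg <- c(msg, "counts must be numeric")
        else {
            if (any(!is.finite(m)))
                msg <- c(msg, "counts must be finite")
            else {
                if (any(m < 0))
                    msg <- c(msg, "counts must be non-negative")
                if (any(m != round(m)))
                    msg <- c(msg, "counts must be integers")
            }
        }
    }
    if (is.null(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) are required")
    else if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "assay", "condition", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
    else {
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "duplicate sample_id")
        if (!all(cd$assay %in% c("rip", "sham", "mrna")))
            msg <- c(msg, "assay must be one of 'rip', 'sham', 'mrna'")
        if (any(!is.finite(cd$replicate)) || any(cd$replicate < 1) ||
            any(cd$replicate != round(cd$replicate)))
            msg <- c(msg, "replicate must be a positive integer")
    }
    if (length(msg)) msg else TRUE
})

#' EnrichmentResult: per-gene relative AGO2 enrichment
#'
#' Result of [relativeEnrichment()]. Holds, for every gene retained by the
#' minimum-read filter in all replicates, the raw RIP/sham ratio and the
#' window-normalized enrichment per replicate, their across-replicate mean
#' E_g, and the bound/unbound call at the stored cutoff. `passedMinReads`
#' covers every gene of the input table so the filter outcome is auditable.
#'
#' @slot repEnrichment numeric matrix, genes x replicates, normalized
#'   enrichment per replicate.
#' @slot enrichment named numeric, mean enrichment E_g across replicates.
#' @slot rawRatio numeric matrix of raw RIP/sham count ratios.
#' @slot normFactors numeric matrix (2 x replicates, rows `rip`/`sham`) of
#'   anchor-window normalization factors.
#' @slot bound named logical, E_g strictly above `cutoff`.
#' @slot passedMinReads named logical over all input genes.
#' @slot cutoff numeric, fold-enrichment cutoff of the bound call.
#' @slot anchorGene character, window anchor gene.
#' @slot halfWindow integer, genes on each side of the anchor.
#' @slot minReads integer, minimum read filter threshold.
#' @export
setClass("EnrichmentResult", representation(
    repEnrichment = "matrix",
    enrichment = "numeric",
    rawRatio = "matrix",
    normFactors = "matrix",
    bound = "logical",
    passedMinReads = "logical",
    cutoff = "numeric",
    anchorGene = "character",
    halfWindow = "integer",
    minReads = "integer"
))

setValidity("EnrichmentResult", function(object) {
    msg <- character()
    g <- names(object@enrichment)
    if (!identical(rownames(object@repEnrichment), g))
        msg <- c(msg, "repEnrichment rows must match enrichment names")
    if (!identical(names(object@bound), g))
        msg <- c(msg, "bound names must match enrichment names")
    if (length(g) && any(object@enrichment <= 0))
        msg <- c(msg, "retained genes must have positive enrichment")
    if (length(g) &&
        max(abs(object@enrichment - rowMeans(object@repEnrichment))) > 1e-8)
        msg <- c(msg, "enrichment must be the mean of repEnrichment")
    if (any(object@bound & !(object@enrichment > object@cutoff)))
        msg <- c(msg, "bound flag inconsistent with cutoff")
    if (object@cutoff <= 0)
        msg <- c(msg, "cutoff must be positive")
    if (length(msg)) msg else TRUE
})

#' SiteCurve: cumulative predicted-site curve along the enrichment ranking
#'
#' For one miRNA family, `y[x]` is the fraction of its predicted-site genes
#' found at enrichment rank <= x (rank 1 = lowest AGO2 enrichment). A family
#' active in the profiled cells concentrates its targets at high ranks, so
#' the curve runs below the diagonal and `aucDev = mean(y - x/N)` is
#' negative; `dMax` is the largest absolute deviation from the diagonal.
#'
#' @slot mirna character, miRNA family name.
#' @slot x integer rank thresholds 1..N.
#' @slot y numeric cumulative fraction of site-bearing genes.
#' @slot aucDev numeric, mean deviation of the curve from the diagonal.
#' @slot dMax numeric, maximum absolute deviation from the diagonal.
#' @slot nSiteGenes integer, number of site-bearing genes in the universe.
#' @export
setClass("SiteCurve", representation(
    mirna = "character",
    x = "integer",
    y = "numeric",
    aucDev = "numeric",
    dMax = "numeric",
    nSiteGenes = "integer"
))

setValidity("SiteCurve", function(object) {
    msg <- character()
    if (length(object@x) != length(object@y))
        msg <- c(msg, "x and y lengths differ")
    if (length(object@y)) {
        if (any(diff(object@y) < 0))
            msg <- c(msg, "y must be non-decreasing")
        if (abs(object@y[length(object@y)] - 1) > 1e-12)
            msg <- c(msg, "y must end at 1")
    }
    if (abs(object@aucDev) > 0.5 + 1e-12)
        msg <- c(msg, "aucDev must lie in [-0.5, 0.5]")
    if (length(msg)) msg else TRUE
})
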