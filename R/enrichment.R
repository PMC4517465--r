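#' Minimum-read filter
#'
#' Removes genes with fewer than `threshold` reads in any sample of the
#' table. Applied per pairwise comparison (the samples actually present in
#' the table), with "lower than threshold" excluded, so a gene with
#' exactly `threshold` reads everywhere is retained.
#'
#' @param x a [RipCountSet-class] (or count matrix).
#' @param threshold minimum read count, default 10.
#' @return the table restricted to genes with `count >= threshold` in
#'   every sample.
#' @export
filterMinReads <- function(x, threshold = 10L) {
    if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
        .stopf("threshold must be a single non-negative number")
    m <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    keep <- rowSums(m < threshold) == 0L
    x[keep, , drop = FALSE]
}

#' Anchor-window normalization factors
#'
#' Per-sample normalization factors for the relative-enrichment statistic:
#' genes are sorted in ascending order of a preliminary per-gene RIP/sham
#' ratio, the window of `halfWindow` genes on each side of the anchor gene
#' (plus the anchor itself, 2*halfWindow + 1 genes; 101 at the default)
#' is selected, and each sample's factor is the arithmetic mean of the
#' window genes' counts in that sample. Anchoring on a highly expressed
#' gene without conserved miRNA sites (GAPDH) centers the window on the
#' unenriched background.
#'
#' @param object a [RipCountSet-class] or count matrix restricted to the
#'   genes passing the minimum-read filter.
#' @param prelimRatio named numeric, preliminary RIP/sham ratio per gene
#'   (raw counts; per-sample scaling cannot reorder genes, so window
#'   membership is well defined before normalization).
#' @param anchorGene anchor gene identifier, default `"Gapdh"`.
#' @param halfWindow genes on each side of the anchor, default 50.
#' @param ... unused.
#' @return named numeric vector of per-sample factors.
#' @export
setMethod("windowFactors", "ANY",
    function(object, prelimRatio, anchorGene = "Gapdh", halfWindow = 50L,
             ...) {
    m <- if (is(object, "SummarizedExperiment"))
        SummarizedExperiment::assay(object, "counts") else as.matrix(object)
    halfWindow <- as.integer(halfWindow)
    if (halfWindow < 0) .stopf("halfWindow must be non-negative")
    genes <- rownames(m)
    if (is.null(genes) || !all(genes %in% names(prelimRatio)))
        .stopf("prelimRatio must name every gene of the table")
    r <- prelimRatio[genes]
    ord <- .orderBy(r, genes)
    pos <- match(anchorGene, genes[ord])
    if (is.na(pos))
        .stopf("anchor gene '%s' filtered out of the table", anchorGene)
    if (pos - 1L < halfWindow || length(genes) - pos < halfWindow)
        .stopf(paste0("anchor '%s' at position %d of %d: fewer than %d ",
                      "genes on one side"),
               anchorGene, pos, length(genes), halfWindow)
    window <- genes[ord][(pos - halfWindow):(pos + halfWindow)]
    f <- colMeans(m[window, , drop = FALSE])
    if (any(f <= 0)) .stopf("non-positive normalization factor")
    f
})

#' Sham-normalized relative AGO2 enrichment
#'
#' The core RIP-seq statistic: for each replicate, 3'UTR read counts of
#' the AGO2 RIP sample are divided by those of the paired sham
#' (mock-injected) sample, after (1) excluding genes with fewer than
#' `minReads` reads in either sample of that replicate and (2) scaling
#' each sample by its anchor-window factor (see [windowFactors()]).
#' Per-replicate enrichment is
#' `E_rep = (c_rip / f_rip) / (c_sham / f_sham)`, and the reported
#' enrichment `E_g` is the unweighted mean across replicates, defined on
#' the genes passing the filter in every replicate. Genes with `E_g`
#' strictly above `cutoff` (default 4-fold) are called AGO2-bound, i.e.
#' putative miRNA targets.
#'
#' @param x a [RipCountSet-class] containing the RIP and sham samples.
#' @param ripSamples,shamSamples character vectors of sample identifiers;
#'   position `i` of each forms replicate `i`'s RIP/sham pair.
#' @param anchorGene,halfWindow see [windowFactors()].
#' @param minReads per-replicate minimum-read threshold (default 10;
#'   at least 1 so sham denominators are positive).
#' @param cutoff fold-enrichment cutoff for the bound call, default 4.
#' @return an [EnrichmentResult-class].
#' @seealso [classifyBound()], [assignRanks()]
#' @export
relativeEnrichment <- function(x, ripSamples, shamSamples,
                               anchorGene = "Gapdh", halfWindow = 50L,
                               minReads = 10L, cutoff = 4) {
    stopifnot(is(x, "RipCountSet"))
    if (length(ripSamples) != length(shamSamples) || !length(ripSamples))
        .stopf("need one sham sample per RIP sample (>= 1 replicate)")
    minReads <- max(1L, as.integer(minReads))
    if (cutoff <= 0) .stopf("cutoff must be positive")
    m <- counts(x)
    missing <- setdiff(c(ripSamples, shamSamples), colnames(m))
    if (length(missing))
        .stopf("sample(s) not in table: %s", paste(missing, collapse = ", "))
    nRep <- length(ripSamples)
    genes <- rownames(m)

    perRep <- vector("list", nRep)
    passed <- matrix(FALSE, nrow = length(genes), ncol = nRep,
                     dimnames = list(genes, NULL))
    normF <- matrix(NA_real_, nrow = 2, ncol = nRep,
                    dimnames = list(c("rip", "sham"),
                                    paste0("rep", seq_len(nRep))))
    for (i in seq_len(nRep)) {
        sub <- m[, c(ripSamples[i], shamSamples[i]), drop = FALSE]
        keep <- rowSums(sub < minReads) == 0L
        sub <- sub[keep, , drop = FALSE]
        passed[rownames(sub), i] <- TRUE
        r <- sub[, 1] / sub[, 2]
        f <- windowFactors(sub, r, anchorGene = anchorGene,
                           halfWindow = halfWindow)
        normF[, i] <- f
        eRep <- (sub[, 1] / f[1]) / (sub[, 2] / f[2])
        perRep[[i]] <- list(raw = r, e = eRep)
    }
    shared <- genes[rowSums(passed) == nRep]
    repE <- vapply(perRep, function(p) p$e[shared], numeric(length(shared)))
    repE <- matrix(repE, nrow = length(shared),
                   dimnames = list(shared, paste0("rep", seq_len(nRep))))
    rawR <- vapply(perRep, function(p) p$raw[shared],
                   numeric(length(shared)))
    rawR <- matrix(rawR, nrow = length(shared),
                   dimnames = list(shared, paste0("rep", seq_len(nRep))))
    eMean <- rowMeans(repE)
    new("EnrichmentResult",
        repEnrichment = repE,
        enrichment = eMean,
        rawRatio = rawR,
        normFactors = normF,
        bound = eMean > cutoff,
        passedMinReads = stats::setNames(rowSums(passed) == nRep, genes),
        cutoff = cutoff,
        anchorGene = anchorGene,
        halfWindow = as.integer(halfWindow),
        minReads = minReads)
}

#' Mean relative enrichment per gene
#'
#' Accessors for [EnrichmentResult-class]: `enrichment()` returns the
#' named vector of mean enrichments E_g, `repEnrichment()` the
#' genes x replicates matrix, `windowFactors()` (on an
#' `EnrichmentResult`) the stored normalization factors.
#'
#' @param object an `EnrichmentResult`.
#' @param ... unused.
#' @name enrichment
#' @export
setMethod("enrichment", "EnrichmentResult", function(object, ...)
    object@enrichment)

#' @rdname enrichment
#' @export
setMethod("repEnrichment", "EnrichmentResult", function(object, ...)
    object@repEnrichment)

#' @rdname enrichment
#' @export
setMethod("windowFactors", "EnrichmentResult", function(object, ...)
    object@normFactors)

#' Classify AGO2-bound genes
#'
#' `classifyBound()` returns the genes whose mean relative enrichment is
#' strictly above `cutoff` (a gene at exactly the cutoff is not called
#' bound). `boundGenes()` returns the call stored at construction time.
#'
#' @param object an [EnrichmentResult-class] or a named numeric vector of
#'   enrichments.
#' @param cutoff fold-enrichment cutoff, default 4.
#' @param ... unused.
#' @return character vector of bound gene identifiers.
#' @name classifyBound
#' @export
setMethod("classifyBound", "EnrichmentResult",
    function(object, cutoff = 4, ...) {
    if (cutoff <= 0) .stopf("cutoff must be positive")
    e <- object@enrichment
    names(e)[e > cutoff]
})

#' @rdname classifyBound
#' @export
setMethod("classifyBound", "numeric", function(object, cutoff = 4, ...) {
    if (cutoff <= 0) .stopf("cutoff must be positive")
    if (is.null(names(object))) .stopf("enrichment vector must be named")
    names(object)[object > cutoff]
})

#' @rdname classifyBound
#' @export
setMethod("boundGenes", "EnrichmentResult", function(object, ...)
    names(object@bound)[object@bound])

#' @describeIn enrichment Tabular view. With `all = TRUE`, every input
#'   gene appears with its `passed_min_reads` flag and `NA` enrichment
#'   where the filter removed it.
#' @param x an `EnrichmentResult`.
#' @param all logical, include filtered-out genes.
#' @export
enrichmentTable <- function(x, all = FALSE) {
    stopifnot(is(x, "EnrichmentResult"))
    genes <- if (all) names(x@passedMinReads) else names(x@enrichment)
    repE <- x@repEnrichment[match(genes, rownames(x@repEnrichment)), ,
                            drop = FALSE]
    df <- data.frame(gene_id = genes, repE,
                     E_mean = x@enrichment[match(genes,
                                                 names(x@enrichment))],
                     passed_min_reads = x@passedMinReads[genes],
                     is_bound = x@bound[match(genes, names(x@bound))],
                     row.names = NULL, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[2:(1 + ncol(repE))] <- paste0("E_", colnames(x@repEnrichment))
    df$is_bound[is.na(df$is_bound)] <- FALSE
    df
}

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult:", length(object@enrichment),
        "genes across", ncol(object@repEnrichment), "replicate(s)\n")
    cat(sprintf("  bound (E > %g): %d genes; anchor '%s', window +/-%d, min reads %d\n",
                object@cutoff, sum(object@bound), object@anchorGene,
                object@halfWindow, object@minReads))
})
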