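#' Count reads overlapping 3'UTR intervals
#'
#' Assigns aligned read intervals to genes by overlap with their annotated
#' 3'UTR intervals. Multiple UTR records of one gene are unioned first, so
#' a read is counted at most once per gene. A read overlapping the UTRs of
#' several distinct genes increments all of them (`multiPolicy = "all"`,
#' matching per-3'UTR quantification) or none (`multiPolicy = "none"`).
#'
#' @param reads `GRanges` of read intervals (e.g. from
#'   [readBedIntervals()]).
#' @param utrs `GRanges` of 3'UTR intervals with metadata column `name`
#'   holding the gene identifier.
#' @param stranded logical; when `TRUE` (default, appropriate for a
#'   poly(A)-selected stranded library) a read only counts on the UTR's
#'   strand, and unknown strands are an error.
#' @param multiPolicy `"all"` or `"none"`; handling of reads overlapping
#'   UTRs of more than one gene.
#' @param minOverlap minimum overlap in bp (default 1).
#' @return named integer vector: one count per gene, genes in order of
#'   first appearance in `utrs` (a single count-table column).
#' @examples
#' utr <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(101, 200), "+", name = "Snca")
#' rd <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(151, 160), "+", name = "r1")
#' countReadsInUtrs(rd, utr)
#' @export
countReadsInUtrs <- function(reads, utrs, stranded = TRUE,
                             multiPolicy = c("all", "none"),
                             minOverlap = 1L) {
    if (!is.character(multiPolicy) ||
        !all(multiPolicy %in% c("all", "none")))
        .stopf("unknown multiPolicy: %s",
               paste(multiPolicy[1], collapse = ","))
    multiPolicy <- match.arg(multiPolicy)
    if (!length(reads)) .stopf("no read intervals supplied")
    if (!length(utrs)) .stopf("no UTR intervals supplied")
    if (!"name" %in% colnames(S4Vectors::mcols(utrs)))
        .stopf("utrs must carry gene identifiers in the 'name' column")
    if (stranded) {
        if (any(BiocGenerics::strand(reads) == "*") ||
            any(BiocGenerics::strand(utrs) == "*"))
            .stopf("stranded counting requested but strand is missing")
    }
    genes <- S4Vectors::mcols(utrs)$name
    geneOrder <- unique(genes)
    # union per gene: one read can hit one gene at most once
    grl <- GenomicRanges::reduce(
        GenomicRanges::split(utrs, factor(genes, levels = geneOrder)))
    hits <- GenomicRanges::findOverlaps(
        reads, grl, minoverlap = minOverlap, ignore.strand = !stranded)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    if (multiPolicy == "none") {
        nGenesPerRead <- tabulate(q, nbins = length(reads))
        keep <- nGenesPerRead[q] == 1L
        q <- q[keep]; s <- s[keep]
    }
    res <- tabulate(s, nbins = length(grl))
    names(res) <- geneOrder
    res
}
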