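#' Construct a RipCountSet
#'
#' Bundles an integer count matrix (genes x samples) with the sample
#' annotation of the RIP-seq design. This is the container every analysis
#' step consumes; it validates that counts are non-negative integers, gene
#' identifiers are unique and the metadata is complete.
#'
#' @param counts numeric matrix of non-negative integer read counts with
#'   gene identifiers as rownames; column order defines sample order.
#' @param sampleData data.frame with one row per sample and columns
#'   `sample_id`, `assay` (`"rip"`, `"sham"` or `"mrna"`), `condition`
#'   and `replicate`. Rows are matched to `counts` columns positionally
#'   (or by `colnames(counts)` when present).
#' @return A [RipCountSet-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 7L, 3L), nrow = 2,
#'             dimnames = list(c("Snca", "Itgb1"), NULL))
#' meta <- data.frame(sample_id = c("rip_1", "sham_1"),
#'                    assay = c("rip", "sham"),
#'                    condition = "control-sponge", replicate = 1L)
#' rcs <- RipCountSet(m, meta)
#' counts(rcs)
#' @export
RipCountSet <- function(counts, sampleData) {
    counts <- as.matrix(counts)
    sampleData <- as.data.frame(sampleData, stringsAsFactors = FALSE)
    if (ncol(counts) != nrow(sampleData))
        .stopf("counts has %d samples but sampleData has %d rows",
               ncol(counts), nrow(sampleData))
    if (!is.null(colnames(counts)) &&
        !identical(colnames(counts), as.character(sampleData$sample_id))) {
        idx <- match(colnames(counts), sampleData$sample_id)
        if (anyNA(idx))
            .stopf("counts columns and sampleData$sample_id disagree")
        sampleData <- sampleData[idx, , drop = FALSE]
    }
    colnames(counts) <- as.character(sampleData$sample_id)
    storage.mode(counts) <- "integer"
    cd <- S4Vectors::DataFrame(sampleData,
                               row.names = as.character(sampleData$sample_id))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("RipCountSet", se)
}

#' @describeIn RipCountSet The integer count matrix.
#' @param object,x a `RipCountSet`.
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "RipCountSet", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' Sample annotation of a RipCountSet
#'
#' @param x a [RipCountSet-class].
#' @return data.frame with columns `sample_id`, `assay`, `condition`,
#'   `replicate`.
#' @export
sampleInfo <- function(x) {
    as.data.frame(SummarizedExperiment::colData(x))[
        , c("sample_id", "assay", "condition", "replicate"), drop = FALSE]
}

setMethod("show", "RipCountSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("RipCountSet with", nrow(object), "genes and",
        ncol(object), "samples\n")
    if (ncol(object)) {
        tab <- table(paste(cd$assay, cd$condition, sep = "/"))
        cat("  samples:",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
            "\n")
    }
})
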