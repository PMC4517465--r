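#' Read and write count tables
#'
#' Count tables are plain TSV: a header row `gene_id` followed by sample
#' identifiers, then one row of non-negative integer counts per gene.
#' Sample metadata (`sample_id`, `assay`, `condition`, `replicate`) travels
#' either in a companion TSV (`metaPath`) or embedded as `#meta` lines
#' before the header, one per sample:
#' \preformatted{#meta<TAB>rip_1<TAB>rip<TAB>control-sponge<TAB>1}
#' [writeCountTable()] emits a canonical form (embedded `#meta` lines
#' unless `metaPath` is given) so that write-read-write round-trips are
#' byte identical.
#'
#' @param path count table TSV.
#' @param metaPath optional companion metadata TSV with header
#'   `sample_id assay condition replicate`.
#' @return [readCountTable()] returns a [RipCountSet-class];
#'   [writeCountTable()] returns `path` invisibly.
#' @export
readCountTable <- function(path, metaPath = NULL) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    lines <- readLines(path)
    metaLines <- grep("^#meta\t", lines, value = TRUE)
    body <- lines[!startsWith(lines, "#")]
    body <- body[nzchar(body)]
    if (!length(body)) .stopf("%s: no header row", path)
    header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
    if (header[1] != "gene_id")
        .stopf("%s: first header column must be 'gene_id'", path)
    sampleIds <- header[-1]
    if (!length(sampleIds)) .stopf("%s: no sample columns", path)

    if (!is.null(metaPath)) {
        if (!file.exists(metaPath)) .stopf("file not found: %s", metaPath)
        meta <- .readTsv(metaPath)
    } else if (length(metaLines)) {
        parts <- strsplit(metaLines, "\t", fixed = TRUE)
        bad <- lengths(parts) != 5L
        if (any(bad)) .stopf("%s: malformed #meta line", path)
        meta <- data.frame(
            sample_id = vapply(parts, `[`, "", 2L),
            assay = vapply(parts, `[`, "", 3L),
            condition = vapply(parts, `[`, "", 4L),
            replicate = as.integer(vapply(parts, `[`, "", 5L)),
            stringsAsFactors = FALSE)
    } else {
        .stopf("%s: no sample metadata (#meta lines or metaPath required)",
               path)
    }
    need <- c("sample_id", "assay", "condition", "replicate")
    if (!all(need %in% colnames(meta)))
        .stopf("metadata lacks columns: %s",
               paste(setdiff(need, colnames(meta)), collapse = ", "))
    idx <- match(sampleIds, meta$sample_id)
    if (anyNA(idx))
        .stopf("metadata missing for sample(s): %s",
               paste(sampleIds[is.na(idx)], collapse = ", "))
    meta <- meta[idx, need, drop = FALSE]

    rows <- strsplit(body[-1], "\t", fixed = TRUE)
    if (any(lengths(rows) != length(header)))
        .stopf("%s: row %d has wrong number of fields", path,
               which(lengths(rows) != length(header))[1] + 1L)
    geneIds <- vapply(rows, `[`, "", 1L)
    dup <- geneIds[duplicated(geneIds)]
    if (length(dup))
        .stopf("%s: duplicate gene_id: %s", path, dup[1])
    cells <- vapply(rows, function(r) r[-1L], character(length(sampleIds)))
    cells <- matrix(cells, nrow = length(sampleIds))  # samples x genes
    ok <- matrix(grepl("^[0-9]+$", cells), nrow = nrow(cells))
    if (!all(ok)) {
        bad <- which(!ok, arr.ind = TRUE)[1, ]
        .stopf("%s: non-integer count '%s' at gene '%s', sample '%s'",
               path, cells[bad[1], bad[2]], geneIds[bad[2]],
               sampleIds[bad[1]])
    }
    m <- matrix(as.integer(t(cells)), nrow = length(geneIds),
                dimnames = list(geneIds, sampleIds))
    RipCountSet(m, meta)
}

#' @rdname readCountTable
#' @param x a [RipCountSet-class] to write.
#' @export
writeCountTable <- function(x, path, metaPath = NULL) {
    stopifnot(is(x, "RipCountSet"))
    info <- sampleInfo(x)
    m <- counts(x)
    lines <- character(0)
    if (is.null(metaPath)) {
        lines <- sprintf("#meta\t%s\t%s\t%s\t%d", info$sample_id,
                         info$assay, info$condition, info$replicate)
    } else {
        utils::write.table(info, metaPath, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
    }
    lines <- c(lines,
               paste(c("gene_id", colnames(m)), collapse = "\t"),
               paste(rownames(m),
                     apply(m, 1, paste, collapse = "\t"), sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Read and write BED6 intervals
#'
#' BED6 (chrom, start, end, name, score, strand), 0-based half-open.
#' The name column carries the gene identifier for 3'UTR annotation, or a
#' read identifier for read intervals. Coordinates are validated
#' (`end > start`, `start >= 0`); a `.` strand is read as unknown (`*`)
#' and rejected later if strand-aware counting is requested.
#'
#' @param path BED file. Whitespace- or tab-delimited, at least 6 columns.
#' @return [readBedIntervals()] returns a
#'   [GenomicRanges::GRanges] with metadata columns `name` and `score`
#'   (internally 1-based; [writeBedIntervals()] restores BED coordinates
#'   exactly).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tSnca\t0\t+", bed)
#' readBedIntervals(bed)
#' @export
readBedIntervals <- function(path) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(#|track|browser)", lines)]
    if (!length(lines))
        return(GenomicRanges::GRanges(name = character(0),
                                      score = numeric(0)))
    parts <- strsplit(lines, "[ \t]+")
    if (any(lengths(parts) < 6L))
        .stopf("%s: line %d has fewer than 6 BED fields", path,
               which(lengths(parts) < 6L)[1])
    f <- function(i) vapply(parts, `[`, "", i)
    start <- suppressWarnings(as.numeric(f(2)))
    end <- suppressWarnings(as.numeric(f(3)))
    if (anyNA(start) || anyNA(end))
        .stopf("%s: non-numeric coordinate", path)
    if (any(start < 0)) .stopf("%s: negative start coordinate", path)
    bad <- which(end <= start)
    if (length(bad))
        .stopf("%s: line %d: end (%d) <= start (%d)", path, bad[1],
               end[bad[1]], start[bad[1]])
    strand <- f(6)
    if (!all(strand %in% c("+", "-", ".")))
        .stopf("%s: invalid strand field", path)
    strand[strand == "."] <- "*"
    name <- f(4)
    if (any(!nzchar(name))) .stopf("%s: empty name field", path)
    GenomicRanges::GRanges(
        seqnames = f(1),
        ranges = IRanges::IRanges(start = start + 1, end = end),
        strand = strand,
        name = name,
        score = suppressWarnings(as.numeric(f(5))))
}

#' @rdname readBedIntervals
#' @param gr a `GRanges` with metadata column `name` (and optionally
#'   `score`) as returned by [readBedIntervals()].
#' @export
writeBedIntervals <- function(gr, path) {
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "."
    score <- if ("score" %in% colnames(S4Vectors::mcols(gr)))
        S4Vectors::mcols(gr)$score else rep(0, length(gr))
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     as.character(GenomicRanges::seqnames(gr)),
                     BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                     S4Vectors::mcols(gr)$name, score, strand)
    writeLines(lines, path)
    invisible(path)
}

#' Read and write gene -> miRNA-family site annotation
#'
#' Two-column TSV `gene_id<TAB>miRNA_family`, one row per predicted
#' conserved site family (TargetScan-style). Returned as a named
#' [IRanges::CharacterList]: one character vector of family names per
#' gene, duplicates collapsed (set semantics).
#'
#' @param path annotation TSV (with or without a header row).
#' @return named `CharacterList`, genes as names.
#' @export
readSiteAnnotation <- function(path) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) && identical(lines[1], "gene_id\tmiRNA_family"))
        lines <- lines[-1]
    if (!length(lines))
        return(IRanges::CharacterList(structure(list(), names = character(0))))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
        .stopf("%s: line %d does not have 2 tab-separated fields", path,
               which(lengths(parts) != 2L)[1])
    gene <- vapply(parts, `[`, "", 1L)
    fam <- vapply(parts, `[`, "", 2L)
    if (any(!nzchar(fam))) .stopf("%s: empty miRNA family name", path)
    sets <- lapply(split(fam, gene), function(v) sort(unique(v), method = "radix"))
    sets <- sets[sort(names(sets), method = "radix")]
    IRanges::CharacterList(sets)
}

#' @rdname readSiteAnnotation
#' @param sites named list / `CharacterList` mapping gene to families.
#' @export
writeSiteAnnotation <- function(sites, path) {
    gene <- rep(names(sites), lengths(sites))
    fam <- unlist(sites, use.names = FALSE)
    lines <- c("gene_id\tmiRNA_family",
               if (length(gene)) paste(gene, fam, sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}
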