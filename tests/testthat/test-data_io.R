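test_that("count tables read, validate and round-trip byte-identically", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("#meta\ts1\trip\tcontrol-sponge\t1",
                 "#meta\ts2\tsham\tsham\t1",
                 "gene_id\ts1\ts2",
                 "Snca\t5\t7",
                 "Itgb1\t0\t3"), p)
    x <- readCountTable(p)
    expect_s4_class(x, "RipCountSet")
    expect_identical(unname(counts(x)),
                     matrix(c(5L, 0L, 7L, 3L), nrow = 2))
    expect_identical(rownames(x), c("Snca", "Itgb1"))
    expect_identical(sampleInfo(x)$assay, c("rip", "sham"))

    # write(read(p)) is byte-identical to a canonical write
    p2 <- withr::local_tempfile(fileext = ".tsv")
    p3 <- withr::local_tempfile(fileext = ".tsv")
    writeCountTable(x, p2)
    writeCountTable(readCountTable(p2), p3)
    expect_identical(readBin(p2, "raw", file.size(p2)),
                     readBin(p3, "raw", file.size(p3)))

    # companion-metadata variant
    pm <- withr::local_tempfile(fileext = ".tsv")
    pc <- withr::local_tempfile(fileext = ".tsv")
    writeCountTable(x, pc, metaPath = pm)
    y <- readCountTable(pc, metaPath = pm)
    expect_identical(counts(y), counts(x))
})

test_that("malformed count tables are rejected with located errors", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("#meta\ts1\trip\tc\t1", "gene_id\ts1",
                 "Snca\t3.5"), p)
    expect_error(readCountTable(p), "3\\.5.*Snca")
    writeLines(c("#meta\ts1\trip\tc\t1", "gene_id\ts1",
                 "Snca\t-2"), p)
    expect_error(readCountTable(p), "Snca")
    writeLines(c("#meta\ts1\trip\tc\t1", "gene_id\ts1",
                 "Snca\t5", "Snca\t7"), p)
    expect_error(readCountTable(p), "duplicate gene_id")
    writeLines(c("gene_id\ts1", "Snca\t5"), p)
    expect_error(readCountTable(p), "metadata")
})

test_that("BED6 intervals parse, validate and round-trip coordinates", {
    p <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr1\t100\t200\tSnca\t0\t+", p)
    gr <- readBedIntervals(p)
    expect_equal(length(gr), 1L)
    expect_equal(GenomicRanges::start(gr), 101L)  # 1-based internal
    expect_equal(GenomicRanges::end(gr), 200L)
    expect_equal(S4Vectors::mcols(gr)$name, "Snca")
    expect_equal(as.character(BiocGenerics::strand(gr)), "+")

    writeLines(character(0), p)
    expect_length(readBedIntervals(p), 0L)

    writeLines("chr1\t200\t100\tX\t0\t+", p)
    expect_error(readBedIntervals(p), "end.*<=.*start|end \\(100\\)")

    # round trip preserves BED coordinates exactly
    set.seed(42)
    n <- 40
    start <- sample(0:5000, n)
    lines <- sprintf("chr%d\t%d\t%d\tg%02d\t%d\t%s",
                     sample(1:3, n, TRUE), start,
                     start + sample(1:200, n), seq_len(n),
                     sample(0:10, n, TRUE), sample(c("+", "-"), n, TRUE))
    writeLines(lines, p)
    gr <- readBedIntervals(p)
    p2 <- withr::local_tempfile(fileext = ".bed")
    writeBedIntervals(gr, p2)
    expect_identical(readLines(p2), lines)
})

test_that("site annotation TSV gives set semantics and round-trips", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tmiRNA_family",
                 "Snca\tmiR-124", "Snca\tmiR-124", "Snca\tlet-7",
                 "Itgb1\tmiR-125"), p)
    s <- readSiteAnnotation(p)
    expect_identical(as.list(s),
                     list(Itgb1 = "miR-125",
                          Snca = c("let-7", "miR-124")))
    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeSiteAnnotation(s, p2)
    expect_identical(as.list(readSiteAnnotation(p2)), as.list(s))
})

test_that("UTR counting matches a brute-force overlap oracle", {
    set.seed(7)
    nReads <- 50; nUtrs <- 5
    utrStart <- sample(1:900, nUtrs)
    utrs <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(utrStart, utrStart + sample(50:150, nUtrs)),
        strand = sample(c("+", "-"), nUtrs, TRUE),
        name = c("A", "B", "C", "D", "A"))  # gene A has two UTR records
    rdStart <- sample(1:1000, nReads)
    reads <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(rdStart,
                                 rdStart + sample(10:50, nReads, TRUE)),
        strand = sample(c("+", "-"), nReads, TRUE),
        name = paste0("r", seq_len(nReads)))

    bruteForce <- function(policy) {
        genes <- unique(S4Vectors::mcols(utrs)$name)
        counts <- setNames(integer(length(genes)), genes)
        for (i in seq_along(reads)) {
            hit <- character(0)
            for (j in seq_along(utrs)) {
                sameStrand <- as.character(BiocGenerics::strand(reads[i])) ==
                    as.character(BiocGenerics::strand(utrs[j]))
                ovl <- min(GenomicRanges::end(reads[i]),
                           GenomicRanges::end(utrs[j])) -
                       max(GenomicRanges::start(reads[i]),
                           GenomicRanges::start(utrs[j])) + 1
                if (sameStrand && ovl >= 1)
                    hit <- union(hit, S4Vectors::mcols(utrs[j])$name)
            }
            if (policy == "none" && length(hit) > 1) next
            for (g in hit) counts[g] <- counts[g] + 1L
        }
        counts
    }
    for (policy in c("all", "none"))
        expect_identical(countReadsInUtrs(reads, utrs, multiPolicy = policy),
                         bruteForce(policy))

    # total under 'all' equals the sum of distinct genes per read
    cAll <- countReadsInUtrs(reads, utrs)
    expect_identical(sum(cAll), sum(bruteForce("all")))

    # permutation invariance in read and UTR order
    set.seed(8)
    pr <- sample(length(reads)); pu <- sample(length(utrs))
    shuffled <- countReadsInUtrs(reads[pr], utrs[pu])
    expect_identical(shuffled[names(cAll)], cAll)
})

test_that("counting edge cases behave as specified", {
    utr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+",
                                  name = "Snca")
    inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160),
                                     "+", name = "r1")
    outside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 350),
                                      "+", name = "r2")
    expect_identical(countReadsInUtrs(inside, utr), c(Snca = 1L))
    expect_identical(countReadsInUtrs(outside, utr), c(Snca = 0L))
    # antisense read does not count when stranded
    anti <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160), "-",
                                   name = "r3")
    expect_identical(countReadsInUtrs(anti, utr), c(Snca = 0L))
    expect_identical(countReadsInUtrs(anti, utr, stranded = FALSE),
                     c(Snca = 1L))
    # unknown strand is an error only under stranded counting
    star <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160), "*",
                                   name = "r4")
    expect_error(countReadsInUtrs(star, utr), "strand is missing")
    expect_error(countReadsInUtrs(inside, utr, multiPolicy = "both"),
                 "multiPolicy")
})
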