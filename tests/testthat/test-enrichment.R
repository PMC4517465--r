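test_that("minimum-read filter keeps exactly the genes at or above threshold", {
    m <- rbind(a = c(9L, 50L), b = c(10L, 10L), c = c(100L, 9L),
               d = c(11L, 12L))
    x <- makeRipSet(m, assay = c("rip", "sham"),
                    condition = c("control-sponge", "sham"),
                    replicate = c(1L, 1L))
    kept <- rownames(filterMinReads(x, 10))
    expect_identical(kept, c("b", "d"))  # 9 < 10 excluded, 10 retained
    expect_identical(rownames(filterMinReads(x, 0)), rownames(m))
    expect_error(filterMinReads(x, -1), "non-negative")
})

test_that("window normalization factors are window means and scale with samples", {
    m <- rbind(g1 = c(10L, 40L), g2 = c(20L, 60L), g3 = c(30L, 20L),
               g4 = c(50L, 10L), g5 = c(80L, 16L))
    r <- m[, 1] / m[, 2]   # ascending order: g1, g2, g3, g4, g5
    f <- windowFactors(m, r, anchorGene = "g3", halfWindow = 1)
    expect_equal(unname(f), c(mean(c(20, 30, 50)), mean(c(60, 20, 10))))

    # scaling one sample's counts doubles only that sample's factor
    m2 <- m; m2[, 2] <- m2[, 2] * 2L
    f2 <- windowFactors(m2, r, anchorGene = "g3", halfWindow = 1)
    expect_equal(unname(f2), unname(f) * c(1, 2))

    expect_error(windowFactors(m, r, anchorGene = "g1", halfWindow = 1),
                 "fewer than 1 genes on one side")
    expect_error(windowFactors(m, r, anchorGene = "absent", halfWindow = 1),
                 "filtered out")
    bigr <- setNames(seq_len(200), sprintf("h%03d", 1:200))
    bigm <- matrix(10L, 200, 2, dimnames = list(names(bigr), NULL))
    expect_error(windowFactors(bigm, bigr, anchorGene = "h010",
                               halfWindow = 50),
                 "position 10 of 200")
})

test_that("relative enrichment reproduces hand-computed values and replicate means", {
    # replicate 1: window {g2,g3,g4}; f_rip = 160/3, f_sham = 16;
    # E = r * f_sham / f_rip = r * 0.3
    m <- rbind(g1 = c(5L, 15L), g2 = c(40L, 20L), g3 = c(30L, 10L),
               g4 = c(90L, 18L), g5 = c(400L, 30L), g6 = c(2000L, 10L))
    x <- makeRipSet(m, assay = c("rip", "sham"),
                    condition = c("control-sponge", "sham"),
                    replicate = c(1L, 1L), ids = c("rip_1", "sham_1"))
    enr <- relativeEnrichment(x, "rip_1", "sham_1", anchorGene = "g3",
                              halfWindow = 1, minReads = 10)
    E <- enrichment(enr)
    expect_identical(names(E), c("g2", "g3", "g4", "g5", "g6"))
    expect_equal(unname(E), c(2, 3, 5, 400 / 30, 200) * 0.3)
    expect_false("g1" %in% names(E))  # rip count 5 < 10

    # two replicates: E_g is the unweighted mean; duplicated columns give
    # identical per-replicate values, so the mean equals each replicate
    x2 <- makeRipSet(cbind(m, m), assay = c("rip", "sham", "rip", "sham"),
                     condition = c("control-sponge", "sham")[c(1, 2, 1, 2)],
                     replicate = c(1L, 1L, 2L, 2L),
                     ids = c("rip_1", "sham_1", "rip_2", "sham_2"))
    enr2 <- relativeEnrichment(x2, c("rip_1", "rip_2"),
                               c("sham_1", "sham_2"), anchorGene = "g3",
                               halfWindow = 1)
    expect_equal(enrichment(enr2), E)
    expect_equal(rowMeans(repEnrichment(enr2)), enrichment(enr2))
})

test_that("within-replicate enrichment order equals raw-ratio order", {
    tab <- randPairTable(300, seed = 3)
    enr <- relativeEnrichment(tab$set, "rip_1", "sham_1",
                              anchorGene = tab$anchor, halfWindow = 20)
    e <- repEnrichment(enr)[, 1]
    r <- enr@rawRatio[, 1]
    # E is a positive rescaling of r; compare orders after rounding to 12
    # significant digits so exact ratio ties are not split by float noise
    expect_identical(order(signif(e, 12), names(e), method = "radix"),
                     order(signif(r, 12), names(r), method = "radix"))
})

test_that("per-sample scaling leaves enrichment invariant", {
    tab <- randPairTable(400, seed = 9)
    enr <- relativeEnrichment(tab$set, "rip_1", "sham_1",
                              anchorGene = tab$anchor, halfWindow = 20)
    m <- counts(tab$set)
    m[, "sham_1"] <- m[, "sham_1"] * 7L
    scaled <- makeRipSet(m, assay = c("rip", "sham"),
                         condition = c("control-sponge", "sham"),
                         replicate = c(1L, 1L), ids = colnames(m))
    enr2 <- relativeEnrichment(scaled, "rip_1", "sham_1",
                               anchorGene = tab$anchor, halfWindow = 20)
    expect_lt(max(abs(enrichment(enr2) - enrichment(enr))), 1e-9)
})

test_that("bound classification is strict and monotone in the cutoff", {
    e <- setNames(c(4.0, 4.01, 3.99, 60), c("a", "b", "c", "d"))
    expect_identical(classifyBound(e, 4), c("b", "d"))  # 4.0 is not bound

    set.seed(5)
    e20 <- setNames(runif(20, 0, 10), sprintf("g%02d", 1:20))
    oracle <- names(e20)[vapply(seq_along(e20),
                                function(i) e20[i] > 4, logical(1))]
    expect_identical(classifyBound(e20, 4), oracle)

    cuts <- sort(runif(10, 0.5, 9))
    sizes <- vapply(cuts, function(ct) length(classifyBound(e20, ct)),
                    integer(1))
    expect_true(all(diff(sizes) <= 0))
    expect_error(classifyBound(e20, 0), "positive")
})
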