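test_that("median-of-ratios size factors match the defining formula", {
    m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    expect_equal(unname(medianRatioSizeFactors(m)), c(1, 1))

    m2 <- cbind(s1 = c(10L, 20L, 30L), s2 = c(30L, 60L, 90L))
    rownames(m2) <- c("a", "b", "c")
    f <- medianRatioSizeFactors(m2)
    expect_equal(unname(f[2] / f[1]), 3)

    # 5-gene, 3-sample random table vs direct formula evaluation
    set.seed(12)
    m3 <- matrix(rpois(15, 60) + 1L, nrow = 5,
                 dimnames = list(letters[1:5], paste0("s", 1:3)))
    f3 <- medianRatioSizeFactors(m3)
    geo <- apply(m3, 1, function(r) prod(r)^(1 / length(r)))
    oracle <- apply(m3, 2, function(col) median(col / geo))
    expect_equal(unname(f3), unname(oracle), tolerance = 1e-12)

    zeros <- matrix(c(0L, 5L, 3L, 0L), 2)
    rownames(zeros) <- c("a", "b")
    expect_error(medianRatioSizeFactors(zeros), "no reference gene")
})

test_that("size factors agree with the DESeq2 implementation", {
    set.seed(19)
    m <- matrix(rnbinom(600, mu = 150, size = 10), ncol = 4,
                dimnames = list(sprintf("g%03d", 1:150), paste0("s", 1:4)))
    mine <- medianRatioSizeFactors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("size factors are scale-equivariant and fold changes invariant", {
    set.seed(23)
    m <- matrix(rpois(400, 120) + 1L, ncol = 4,
                dimnames = list(sprintf("g%03d", 1:100),
                                c("c1", "c2", "t1", "t2")))
    f <- medianRatioSizeFactors(m)
    m2 <- m; m2[, "t1"] <- m2[, "t1"] * 5L
    f2 <- medianRatioSizeFactors(m2)
    # equivariant up to the common geometric-mean renormalization
    ratio <- unname(f2 / f)
    expect_equal(ratio / ratio[1], c(1, 1, 5, 1), tolerance = 1e-12)
    fc1 <- foldChanges(m, c("c1", "c2"), c("t1", "t2"))
    fc2 <- foldChanges(m2, c("c1", "c2"), c("t1", "t2"))
    expect_equal(fc2$fc, fc1$fc, tolerance = 1e-12)
})

test_that("fold changes report per-gene shifts and respect the floor", {
    # all genes identical across samples except g01, doubled in the
    # sponge group: size factors stay 1, fc is exactly 2 for g01
    m <- matrix(100L, nrow = 11, ncol = 4,
                dimnames = list(sprintf("g%02d", 1:11),
                                c("c1", "c2", "t1", "t2")))
    m["g01", c("t1", "t2")] <- 200L
    fc <- foldChanges(m, c("c1", "c2"), c("t1", "t2"))
    expect_equal(fc$fc[fc$gene_id == "g01"], 2, tolerance = 1e-9)
    expect_equal(fc$log2fc[fc$gene_id == "g01"], 1, tolerance = 1e-9)
    expect_true(all(abs(fc$fc[fc$gene_id != "g01"] - 1) < 1e-9))

    # zero in the control group: undefined, never infinite
    m["g02", c("c1", "c2")] <- 0L
    fc2 <- foldChanges(m, c("c1", "c2"), c("t1", "t2"))
    expect_true(is.na(fc2$fc[fc2$gene_id == "g02"]))
    expect_error(foldChanges(m, c("c1", "t1"), c("t1", "t2")), "overlap")
})

test_that("KS test matches trivial cases and enumeration on small samples", {
    same <- ksTwoSample(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$statistic, 0)
    expect_equal(same$p_value, 1)
    sep <- ksTwoSample(c(1, 2, 3), c(101, 102, 103))
    expect_equal(sep$statistic, 1)

    ksStat <- function(x, y) {
        z <- sort(unique(c(x, y)))
        max(abs(ecdf(x)(z) - ecdf(y)(z)))
    }
    # exact p equals enumeration over all C(10,5) group assignments
    set.seed(2)
    for (i in 1:5) {
        x <- runif(5); y <- runif(5, 0.2, 1.2)
        obs <- ksTwoSample(x, y, mode = "exact")
        pooled <- c(x, y)
        splits <- combn(10, 5)
        ds <- apply(splits, 2, function(ix)
            ksStat(pooled[ix], pooled[-ix]))
        pEnum <- mean(ds >= obs$statistic - 1e-12)
        expect_equal(obs$p_value, pEnum, tolerance = 1e-12)
    }
    expect_error(ksTwoSample(numeric(0), 1:3), "empty sample")
    expect_error(ksTwoSample(runif(2000), runif(2000), mode = "exact"),
                 "infeasible")
})

test_that("asymptotic KS p tracks the exact p at moderate sample size", {
    set.seed(31)
    diffs <- replicate(30, {
        x <- rnorm(50); y <- rnorm(50, 0.2)
        abs(ksTwoSample(x, y, mode = "exact")$p_value -
            ksTwoSample(x, y, mode = "asymptotic")$p_value)
    })
    expect_lt(max(diffs), 0.02)
})

test_that("mean/SEM and t-test match textbook formulas", {
    expect_equal(meanSem(c(2, 2, 2)), c(mean = 2, sem = 0))
    ms <- meanSem(c(1, 2, 3, 4))
    expect_equal(unname(ms["sem"]), sd(1:4) / 2)

    same <- tTestUnpaired(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$statistic, 0)
    expect_equal(same$p_value, 1)

    set.seed(41)
    a <- rnorm(10, 1); b <- rnorm(10, 0.4, 2)
    got <- tTestUnpaired(a, b)
    # Welch formula oracle
    se <- sqrt(var(a) / 10 + var(b) / 10)
    tt <- (mean(a) - mean(b)) / se
    df <- se^4 / ((var(a) / 10)^2 / 9 + (var(b) / 10)^2 / 9)
    expect_equal(got$statistic, tt, tolerance = 1e-10)
    expect_equal(got$p_value, 2 * pt(-abs(tt), df), tolerance = 1e-10)
    # pooled form
    gotP <- tTestUnpaired(a, b, pooled = TRUE)
    sp <- sqrt((9 * var(a) + 9 * var(b)) / 18)
    tp <- (mean(a) - mean(b)) / (sp * sqrt(2 / 10))
    expect_equal(gotP$statistic, tp, tolerance = 1e-10)
    expect_error(tTestUnpaired(1, c(1, 2)), "at least 2")
})

test_that("delta-delta-Ct arithmetic", {
    expect_equal(ddct(20, 20, 20, 20), 1)
    expect_equal(ddct(19, 20, 20, 20), 2)   # ddCt = -1
    expect_equal(ddct(20, 18, 23, 18), 8)   # ddCt = -3
    expect_error(ddct(NA, 1, 1, 1), "finite")
    expect_error(ddct(Inf, 1, 1, 1), "finite")
})

test_that("derepression report structure and degenerate partitions", {
    set.seed(51)
    fc <- data.frame(gene_id = sprintf("g%03d", 1:100),
                     mean_control = 100, mean_sponge = 100,
                     fc = exp(rnorm(100, 0, 0.1)))
    fc$log2fc <- log2(fc$fc)
    shift <- fc$gene_id[1:20]
    rep <- derepressionAnalysis(shift, fc)
    expect_equal(rep$shift$n, 20)
    expect_equal(rep$other$n, 80)
    expect_equal(rep$n_expressed, 100)
    expect_true(rep$ks$p_value >= 0 && rep$ks$p_value <= 1)
    expect_equal(rep$shift$mean_fc, mean(fc$fc[1:20]))

    expect_error(derepressionAnalysis(fc$gene_id, fc), "nothing to compare")
    expect_error(derepressionAnalysis("g001", fc), "fewer than 2")

    # predicted-site subset reporting
    sites <- setNames(rep(list("miR-124"), 10), fc$gene_id[1:10])
    rep2 <- derepressionAnalysis(shift, fc, sites, "miR-124")
    expect_equal(rep2$predicted$n, 10)
    expect_equal(rep2$predicted$mirna, "miR-124")
})
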