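#' Median-of-ratios size factors
#'
#' Per-sample scaling constants for count normalization: each sample's
#' factor is the median, over reference genes, of that sample's count
#' divided by the gene's geometric mean across samples. Reference genes
#' are those with no zero count (their geometric mean is positive).
#'
#' @param x count matrix or [RipCountSet-class], genes x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
medianRatioSizeFactors <- function(x) {
    m <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    if (ncol(m) < 2L) .stopf("need at least 2 samples")
    ref <- rowSums(m == 0) == 0L
    if (!any(ref)) .stopf("no reference gene with nonzero counts in all samples")
    lg <- log(m[ref, , drop = FALSE])
    logGeo <- rowMeans(lg)
    apply(lg, 2, function(col) exp(stats::median(col - logGeo)))
}

#' Fold changes between two mRNA-seq groups
#'
#' Counts are normalized by [medianRatioSizeFactors()] (computed on the
#' union of the two groups), per-gene group means taken, and the linear
#' fold change `fc = mean_sponge / mean_control` reported for genes whose
#' normalized mean reaches `floor` in both groups; below the floor the
#' fold change is undefined (`NA`), never infinite.
#'
#' @param x [RipCountSet-class] or count matrix of mRNA-seq samples.
#' @param controlSamples,spongeSamples disjoint character vectors of
#'   sample identifiers.
#' @param floor minimum normalized group mean, default 1.
#' @return data.frame with `gene_id`, `mean_control`, `mean_sponge`,
#'   `fc`, `log2fc`.
#' @export
foldChanges <- function(x, controlSamples, spongeSamples, floor = 1) {
    m <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    if (!length(controlSamples) || !length(spongeSamples))
        .stopf("both groups must be non-empty")
    if (length(intersect(controlSamples, spongeSamples)))
        .stopf("sample groups overlap: %s",
               paste(intersect(controlSamples, spongeSamples),
                     collapse = ", "))
    missing <- setdiff(c(controlSamples, spongeSamples), colnames(m))
    if (length(missing))
        .stopf("sample(s) not in table: %s", paste(missing, collapse = ", "))
    sub <- m[, c(controlSamples, spongeSamples), drop = FALSE]
    sf <- medianRatioSizeFactors(sub)
    norm <- sweep(sub, 2, sf, "/")
    meanC <- rowMeans(norm[, controlSamples, drop = FALSE])
    meanS <- rowMeans(norm[, spongeSamples, drop = FALSE])
    ok <- meanC >= floor & meanS >= floor
    fc <- ifelse(ok, meanS / meanC, NA_real_)
    data.frame(gene_id = rownames(m), mean_control = meanC,
               mean_sponge = meanS, fc = fc, log2fc = log2(fc),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two empirical distributions via the supremum distance
#' `D = sup |ECDF_x - ECDF_y|`. Mode `"exact"` evaluates the exact
#' conditional null distribution of D (equivalent to enumerating all
#' group assignments of the pooled sample; only feasible for small
#' samples), `"asymptotic"` uses the Kolmogorov limit distribution with
#' effective size `|x||y|/(|x|+|y|)`, and `"auto"` picks exact when
#' `|x|*|y| < 10000`.
#'
#' @param x,y numeric samples (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @return list with `statistic` (D), `p_value`, `method` and `n`
#'   (the two group sizes).
#' @export
ksTwoSample <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
    mode <- match.arg(mode)
    if (!length(x) || !length(y)) .stopf("empty sample")
    if (mode == "exact" && length(x) * length(y) > 1e6)
        .stopf("exact mode infeasible for |x|*|y| = %g", length(x) * length(y))
    exact <- switch(mode, auto = NULL, exact = TRUE, asymptotic = FALSE)
    ht <- suppressWarnings(stats::ks.test(x, y, exact = exact))
    list(statistic = unname(ht$statistic),
         p_value = min(1, unname(ht$p.value)),
         method = "two-sample Kolmogorov-Smirnov",
         mode = if (is.null(exact)) "auto" else mode,
         n = c(length(x), length(y)))
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector.
#' @return named numeric `c(mean, sem)`, with `sem = sd / sqrt(n)` using
#'   the n-1 denominator standard deviation.
#' @export
meanSem <- function(values) {
    if (!length(values)) .stopf("empty sample")
    c(mean = mean(values),
      sem = if (length(values) > 1) stats::sd(values) / sqrt(length(values))
            else NA_real_)
}

#' Unpaired two-sample t-test
#'
#' Welch's unequal-variance form by default; `pooled = TRUE` gives the
#' classical pooled-variance Student form.
#'
#' @param a,b numeric samples, each of size at least 2.
#' @param pooled logical, default `FALSE` (Welch).
#' @return list with `statistic` (t), `p_value`, `method`, `n`.
#' @export
tTestUnpaired <- function(a, b, pooled = FALSE) {
    if (length(a) < 2 || length(b) < 2)
        .stopf("each group needs at least 2 values")
    ht <- stats::t.test(a, b, var.equal = pooled)
    list(statistic = unname(ht$statistic),
         p_value = unname(ht$p.value),
         method = if (pooled) "pooled-variance t-test" else "Welch t-test",
         n = c(length(a), length(b)))
}

#' Derepression analysis of rank-shifted genes
#'
#' Integrates the RIP rank-shift result with mRNA-seq fold changes:
#' expressed genes (defined fold change) are partitioned into the shifted
#' set and all others, the two log2 fold-change ECDFs are compared with
#' the KS test, each set's mean linear fold change +/- SEM is reported,
#' and the shifted set's fold changes are t-tested against those of all
#' expressed genes. When a site annotation and miRNA family are supplied,
#' the same report is produced for the shifted genes that also carry a
#' predicted site for that family (the directly predicted targets).
#'
#' @param shiftGenes character vector of rank-shifted gene identifiers
#'   (e.g. [topShifted()] output).
#' @param fc fold-change table from [foldChanges()].
#' @param sites optional gene -> family annotation.
#' @param mirna optional miRNA family for the predicted-site subset.
#' @param ksMode mode passed to [ksTwoSample()], default `"asymptotic"`
#'   (gene-set sizes make enumeration infeasible).
#' @return list with elements `n_expressed`, `shift` and `other` set
#'   summaries (sizes, `mean_fc`, `sem_fc`, `log2fc` vectors), `ks`,
#'   `t_vs_all`, and optionally `predicted` (same structure for the
#'   predicted-site subset, `NULL` if fewer than 2 usable genes).
#' @export
derepressionAnalysis <- function(shiftGenes, fc, sites = NULL,
                                 mirna = NULL, ksMode = "asymptotic") {
    expressed <- fc[!is.na(fc$fc), , drop = FALSE]
    inShift <- expressed$gene_id %in% shiftGenes
    if (sum(inShift) < 2)
        .stopf("fewer than 2 shifted genes with defined fold change")
    if (!any(!inShift))
        .stopf("shifted set covers all expressed genes; nothing to compare")
    sh <- expressed[inShift, , drop = FALSE]
    ot <- expressed[!inShift, , drop = FALSE]
    msSh <- meanSem(sh$fc)
    msOt <- meanSem(ot$fc)
    res <- list(
        n_expressed = nrow(expressed),
        shift = list(n = nrow(sh), mean_fc = unname(msSh["mean"]),
                     sem_fc = unname(msSh["sem"]), log2fc = sh$log2fc),
        other = list(n = nrow(ot), mean_fc = unname(msOt["mean"]),
                     sem_fc = unname(msOt["sem"]), log2fc = ot$log2fc),
        ks = ksTwoSample(sh$log2fc, ot$log2fc, mode = ksMode),
        t_vs_all = tTestUnpaired(sh$fc, expressed$fc))
    if (!is.null(sites) && !is.null(mirna)) {
        predGenes <- intersectPredicted(sh$gene_id, sites, mirna)
        if (length(predGenes) >= 2) {
            pr <- sh[sh$gene_id %in% predGenes, , drop = FALSE]
            rest <- expressed[!expressed$gene_id %in% predGenes, ,
                              drop = FALSE]
            msPr <- meanSem(pr$fc)
            res$predicted <- list(
                n = nrow(pr), mirna = mirna,
                mean_fc = unname(msPr["mean"]),
                sem_fc = unname(msPr["sem"]),
                ks = ksTwoSample(pr$log2fc, rest$log2fc, mode = ksMode),
                t_vs_all = tTestUnpaired(pr$fc, expressed$fc))
        } else {
            res$predicted <- NULL
        }
    }
    res
}

#' Delta-delta-Ct qPCR quantification
#'
#' Fold change between an experimental and a control condition from qPCR
#' cycle thresholds of a target and a reference transcript:
#' `fold = 2^-((Ct_target_exp - Ct_ref_exp) - (Ct_target_ctrl - Ct_ref_ctrl))`.
#'
#' @param ctTargetExp,ctRefExp,ctTargetCtrl,ctRefCtrl finite Ct values
#'   (scalars or equal-length vectors).
#' @return numeric fold change(s).
#' @examples
#' ddct(20, 18, 23, 18)  # ddCt = -3, fold = 8
#' @export
ddct <- function(ctTargetExp, ctRefExp, ctTargetCtrl, ctRefCtrl) {
    vals <- c(ctTargetExp, ctRefExp, ctTargetCtrl, ctRefCtrl)
    if (!is.numeric(vals) || any(!is.finite(vals)))
        .stopf("all Ct values must be finite numbers")
    2^(-((ctTargetExp - ctRefExp) - (ctTargetCtrl - ctRefCtrl)))
}
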