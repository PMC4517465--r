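#' Default miRNA family panel for the generator
#'
#' Families with activity 1 are active in the emulated neurons (their
#' functional sites recruit transcripts into the RISC); miR-21
#' (glia-enriched) and miR-292 (non-neural) are present in the site
#' annotation but inactive. `siteProb` is the probability that a gene
#' carries a predicted conserved site for the family; `functionalProb`
#' the fraction of predicted sites that are functional in this cell type
#' (most predicted sites are not); `affinity` the occupancy boost per
#' functional site.
#'
#' @return data.frame with columns `family`, `activity`, `siteProb`,
#'   `functionalProb`, `affinity`.
#' @export
defaultMirnaFamilies <- function() {
    fams <- c("miR-124", "miR-125", "let-7", "miR-9", "miR-26", "miR-29",
              "miR-30", "miR-128", "miR-137", "miR-138", "miR-218",
              "miR-21", "miR-292")
    data.frame(
        family = fams,
        activity = c(rep(1, 11), 0, 0),
        siteProb = c(0.125, 0.10, 0.12, rep(0.10, 8), 0.08, 0.05),
        functionalProb = rep(1 / 3, 13),
        affinity = rep(6, 13),
        stringsAsFactors = FALSE)
}

#' Generator configuration for a synthetic sponge RIP-seq experiment
#'
#' Fixes the conditions of the emulated study: ~8000 quantified genes,
#' two RIP replicates per arm against shared sham controls, three
#' mRNA-seq replicates per group, log-normal expression, occupancy-driven
#' AGO2 enrichment, sponge inhibition of one family with efficiency
#' `inhibitionEfficiency`, and a modest (mean `meanDerepression`, i.e.
#' fold change 1.06) mRNA derepression of the released targets. A
#' fraction of genes emulate glia-expressed transcripts: present in sham
#' and mRNA libraries but invisible to the neuron-specific RIP.
#'
#' @param nGenes number of genes, default 8000.
#' @param families family panel, see [defaultMirnaFamilies()].
#' @param inhibitedFamily family inhibited by the sponge, default
#'   `"miR-124"`.
#' @param inhibitionEfficiency eta in `[0, 1]`, default 0.9; the sponge
#'   arm multiplies the inhibited family's activity by `1 - eta`.
#' @param baselineOccupancy mean baseline RISC occupancy b0 > 0 of a gene
#'   without functional sites, default 1.
#' @param baselineSdLog log-sd of the per-gene baseline occupancy
#'   (lognormal around `baselineOccupancy`), default 0.6. This spread
#'   reproduces the progressively increasing enrichment profile of real
#'   AGO2 RIP data (background pulldown varies from gene to gene) and
#'   places the site-free anchor gene, whose baseline is pinned at
#'   exactly `baselineOccupancy`, stably in the middle of the unbound
#'   part of the ranking. 0 gives a homogeneous background.
#' @param shamBackground relative background pulldown in sham libraries,
#'   default 1.
#' @param exprMeanLog,exprSdLog log-normal expression parameters,
#'   defaults 6.5 and 1.5 (deep poly(A) libraries, median ~650 reads).
#' @param dispersionRip,dispersionMrna negative-binomial dispersions
#'   (variance `mu + alpha mu^2`), defaults 0.05 and 0.02; 0 gives
#'   Poisson counts.
#' @param nRepRip,nRepMrna replicates per RIP arm / mRNA group,
#'   defaults 2 and 3.
#' @param meanDerepression mean of the Gamma-distributed per-gene
#'   derepression delta (fold change `1 + delta` for responsive genes in
#'   the sponge mRNA arm, applied only when `inhibitionEfficiency > 0`),
#'   default 0.06.
#' @param derepressionShape Gamma shape of delta, default 2.
#' @param gliaFraction fraction of glia-emulating genes, default 0.1.
#' @param libFactorsSham,libFactorsRip,libFactorsRipSponge library-size
#'   multipliers per RIP-arm replicate.
#' @param libFactorsMrnaControl,libFactorsMrnaSponge library-size
#'   multipliers per mRNA-seq replicate.
#' @param anchorGene identifier given to the planted highly expressed,
#'   site-free anchor gene, default `"Gapdh"`.
#' @param seed integer seed; the same configuration yields bit-identical
#'   data.
#' @return validated configuration (class `SpongeSimConfig`).
#' @export
spongeSimConfig <- function(nGenes = 8000L,
                            families = defaultMirnaFamilies(),
                            inhibitedFamily = "miR-124",
                            inhibitionEfficiency = 0.9,
                            baselineOccupancy = 1,
                            baselineSdLog = 0.6,
                            shamBackground = 1,
                            exprMeanLog = 6.5,
                            exprSdLog = 1.5,
                            dispersionRip = 0.05,
                            dispersionMrna = 0.02,
                            nRepRip = 2L,
                            nRepMrna = 3L,
                            meanDerepression = 0.06,
                            derepressionShape = 2,
                            gliaFraction = 0.1,
                            libFactorsSham = c(1, 1.1),
                            libFactorsRip = c(1, 0.9),
                            libFactorsRipSponge = c(1.05, 0.95),
                            libFactorsMrnaControl = c(1, 0.95, 1.05),
                            libFactorsMrnaSponge = c(1.02, 0.98, 1),
                            anchorGene = "Gapdh",
                            seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes), families = families,
                inhibitedFamily = inhibitedFamily,
                inhibitionEfficiency = inhibitionEfficiency,
                baselineOccupancy = baselineOccupancy,
                baselineSdLog = baselineSdLog,
                shamBackground = shamBackground,
                exprMeanLog = exprMeanLog, exprSdLog = exprSdLog,
                dispersionRip = dispersionRip,
                dispersionMrna = dispersionMrna,
                nRepRip = as.integer(nRepRip),
                nRepMrna = as.integer(nRepMrna),
                meanDerepression = meanDerepression,
                derepressionShape = derepressionShape,
                gliaFraction = gliaFraction,
                libFactorsSham = libFactorsSham,
                libFactorsRip = libFactorsRip,
                libFactorsRipSponge = libFactorsRipSponge,
                libFactorsMrnaControl = libFactorsMrnaControl,
                libFactorsMrnaSponge = libFactorsMrnaSponge,
                anchorGene = anchorGene, seed = as.integer(seed))
    .validateSimConfig(cfg)
    class(cfg) <- "SpongeSimConfig"
    cfg
}

.validateSimConfig <- function(cfg) {
    bad <- function(field, why)
        .stopf("invalid generator config field '%s': %s", field, why)
    if (is.na(cfg$nGenes) || cfg$nGenes < 10L)
        bad("nGenes", "need at least 10 genes")
    fam <- cfg$families
    need <- c("family", "activity", "siteProb", "functionalProb",
              "affinity")
    if (!is.data.frame(fam) || !all(need %in% colnames(fam)))
        bad("families", paste("data.frame with columns",
                              paste(need, collapse = ", "), "required"))
    if (anyDuplicated(fam$family)) bad("families", "duplicate family name")
    if (any(fam$activity < 0)) bad("families", "activity must be >= 0")
    if (any(fam$siteProb < 0 | fam$siteProb > 1))
        bad("families", "siteProb must lie in [0, 1]")
    if (any(fam$functionalProb < 0 | fam$functionalProb > 1))
        bad("families", "functionalProb must lie in [0, 1]")
    if (any(fam$affinity < 0)) bad("families", "affinity must be >= 0")
    if (!cfg$inhibitedFamily %in% fam$family)
        bad("inhibitedFamily", "not in the family panel")
    if (cfg$inhibitionEfficiency < 0 || cfg$inhibitionEfficiency > 1)
        bad("inhibitionEfficiency", "must lie in [0, 1]")
    for (f in c("baselineOccupancy", "shamBackground", "exprSdLog",
                "meanDerepression", "derepressionShape"))
        if (cfg[[f]] < 0 || (f %in% c("baselineOccupancy",
                                      "shamBackground",
                                      "derepressionShape") &&
                             cfg[[f]] <= 0))
            bad(f, "must be positive")
    if (cfg$baselineSdLog < 0) bad("baselineSdLog", "must be >= 0")
    if (cfg$dispersionRip < 0) bad("dispersionRip", "must be >= 0")
    if (cfg$dispersionMrna < 0) bad("dispersionMrna", "must be >= 0")
    if (cfg$gliaFraction < 0 || cfg$gliaFraction >= 1)
        bad("gliaFraction", "must lie in [0, 1)")
    if (cfg$nRepRip < 1L) bad("nRepRip", "need at least 1 replicate")
    if (cfg$nRepMrna < 2L) bad("nRepMrna", "need at least 2 replicates")
    for (f in c("libFactorsSham", "libFactorsRip", "libFactorsRipSponge")) {
        if (length(cfg[[f]]) != cfg$nRepRip)
            bad(f, sprintf("length must equal nRepRip (%d)", cfg$nRepRip))
        if (any(cfg[[f]] <= 0)) bad(f, "must be positive")
    }
    for (f in c("libFactorsMrnaControl", "libFactorsMrnaSponge")) {
        if (length(cfg[[f]]) != cfg$nRepMrna)
            bad(f, sprintf("length must equal nRepMrna (%d)", cfg$nRepMrna))
        if (any(cfg[[f]] <= 0)) bad(f, "must be positive")
    }
    invisible(TRUE)
}

#' @export
print.SpongeSimConfig <- function(x, ...) {
    cat(sprintf(paste0("SpongeSimConfig: %d genes, %d families, sponge on",
                       " %s (eta = %g), seed %d\n"),
                x$nGenes, nrow(x$families), x$inhibitedFamily,
                x$inhibitionEfficiency, x$seed))
    invisible(x)
}

.nbDraw <- function(mu, dispersion) {
    if (dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a sponge RIP-seq / mRNA-seq experiment with ground truth
#'
#' Generative model: expression `lambda_g` is log-normal; each gene's
#' RISC occupancy is `O_g = b_g + sum_m functional(g, m) a_m x_m` over
#' the family panel, with a lognormal per-gene baseline `b_g` (mean
#' `b0`; zero occupancy for glia-emulating genes, which the
#' neuron-specific RIP cannot see). Expected sham counts are
#' proportional to `lambda_g`, expected RIP counts to
#' `lambda_g O_g / b0`, so a site-free gene has expected relative
#' enrichment `b_g / b0` (mean 1) and a gene with one functional site of
#' affinity `a` has on average `(b0 + a x) / b0`. The sponge arm replaces
#' the inhibited family's activity `x` by `x (1 - eta)`, releasing its
#' targets from the RISC; its mRNA group additionally derepresses
#' responsive genes by `1 + delta_g` (Gamma-distributed, mean
#' `meanDerepression`) when `eta > 0`. Counts are negative binomial
#' (Poisson at dispersion 0). The same configuration (including its
#' `seed`) yields bit-identical output; the RIP and mRNA arms use
#' independent derived streams so either can be generated alone.
#'
#' @param config a [spongeSimConfig()].
#' @param arms which arms to draw counts for, subset of
#'   `c("rip", "mrna")`.
#' @return list with `rip` ([RipCountSet-class]: sham + control-sponge +
#'   target-sponge RIP samples, or `NULL`), `mrna` (`RipCountSet` of the
#'   two mRNA-seq groups, or `NULL`), `sites` (predicted-site
#'   `CharacterList`), `truth` (per-gene data.frame: expression, site
#'   memberships, functional sites, occupancy, expected enrichment,
#'   planted target / sponge-responsive flags, derepression delta) and
#'   `config`.
#' @export
simulateExperiment <- function(config, arms = c("rip", "mrna")) {
    stopifnot(inherits(config, "SpongeSimConfig"))
    arms <- match.arg(arms, c("rip", "mrna"), several.ok = TRUE)
    n <- config$nGenes
    fam <- config$families
    nf <- nrow(fam)
    eta <- config$inhibitionEfficiency
    b0 <- config$baselineOccupancy

    # --- planted structure (stream 0) ---
    set.seed(.deriveSeed(config$seed, 0L))
    ids <- c(config$anchorGene,
             sprintf("g%0*d", max(4L, nchar(n)), seq_len(n - 1L)))
    lambda <- stats::rlnorm(n, config$exprMeanLog, config$exprSdLog)
    lambda[1] <- exp(config$exprMeanLog + config$exprSdLog)  # anchor: high
    nGlia <- round(config$gliaFraction * n)
    isGlia <- rep(FALSE, n)
    if (nGlia > 0)
        isGlia[sample(2:n, nGlia)] <- TRUE
    predicted <- matrix(stats::rbinom(n * nf, 1,
                                      rep(fam$siteProb, each = n)) == 1L,
                        nrow = n, dimnames = list(ids, fam$family))
    predicted[1, ] <- FALSE  # anchor carries no conserved sites
    functional <- predicted &
        matrix(stats::rbinom(n * nf, 1,
                             rep(fam$functionalProb, each = n)) == 1L,
               nrow = n)
    functional[isGlia, ] <- FALSE  # no neuronal RISC loading for glia genes
    inhIdx <- match(config$inhibitedFamily, fam$family)
    responsive <- functional[, inhIdx]
    delta <- numeric(n)
    if (any(responsive))
        delta[responsive] <- stats::rgamma(
            sum(responsive), shape = config$derepressionShape,
            rate = config$derepressionShape / config$meanDerepression)

    # per-gene baseline occupancy: lognormal with mean b0, the anchor
    # pinned at exactly b0 (site-free, mid-background by construction)
    bg <- b0 * exp(stats::rnorm(n, 0, config$baselineSdLog) -
                   config$baselineSdLog^2 / 2)
    bg[1] <- b0
    actCtrl <- fam$activity
    actSp <- fam$activity
    actSp[inhIdx] <- actSp[inhIdx] * (1 - eta)
    occCtrl <- bg + as.numeric(functional %*% (fam$affinity * actCtrl))
    occSp <- bg + as.numeric(functional %*% (fam$affinity * actSp))
    occCtrl[isGlia] <- 0
    occSp[isGlia] <- 0

    truth <- data.frame(
        gene_id = ids,
        lambda = lambda,
        is_glia = isGlia,
        predicted_sites = apply(predicted, 1, function(r)
            paste(fam$family[r], collapse = ",")),
        functional_sites = apply(functional, 1, function(r)
            paste(fam$family[r], collapse = ",")),
        occupancy = occCtrl,
        expected_enrichment = occCtrl / b0,
        is_planted_target =
            as.logical(functional %*% (fam$affinity * fam$activity) > 0),
        is_sponge_responsive = responsive,
        derepression = delta,
        row.names = NULL, stringsAsFactors = FALSE)

    keep <- rowSums(predicted) > 0
    sites <- IRanges::CharacterList(lapply(
        which(keep), function(i) fam$family[predicted[i, ]]))
    names(sites) <- ids[keep]

    out <- list(rip = NULL, mrna = NULL, sites = sites, truth = truth,
                config = config)

    spLabel <- paste0(config$inhibitedFamily, "-sponge")

    if ("rip" %in% arms) {
        set.seed(.deriveSeed(config$seed, 1L))
        nr <- config$nRepRip
        cols <- list()
        meta <- list()
        for (j in seq_len(nr)) {
            mu <- config$libFactorsSham[j] * lambda * config$shamBackground
            cols[[paste0("sham_", j)]] <-
                .nbDraw(mu, config$dispersionRip)
            meta[[length(meta) + 1L]] <-
                c(paste0("sham_", j), "sham", "sham", j)
        }
        for (j in seq_len(nr)) {
            mu <- config$libFactorsRip[j] * lambda * occCtrl / b0
            cols[[paste0("rip_ctrl_", j)]] <-
                .nbDraw(mu, config$dispersionRip)
            meta[[length(meta) + 1L]] <-
                c(paste0("rip_ctrl_", j), "rip", "control-sponge", j)
        }
        for (j in seq_len(nr)) {
            mu <- config$libFactorsRipSponge[j] * lambda * occSp / b0
            cols[[paste0("rip_sp_", j)]] <-
                .nbDraw(mu, config$dispersionRip)
            meta[[length(meta) + 1L]] <-
                c(paste0("rip_sp_", j), "rip", spLabel, j)
        }
        m <- do.call(cbind, cols)
        rownames(m) <- ids
        metaDf <- as.data.frame(do.call(rbind, meta),
                                stringsAsFactors = FALSE)
        names(metaDf) <- c("sample_id", "assay", "condition", "replicate")
        metaDf$replicate <- as.integer(metaDf$replicate)
        out$rip <- RipCountSet(m, metaDf)
    }

    if ("mrna" %in% arms) {
        set.seed(.deriveSeed(config$seed, 2L))
        nm <- config$nRepMrna
        derep <- 1 + if (eta > 0) delta else 0
        cols <- list()
        meta <- list()
        for (j in seq_len(nm)) {
            mu <- config$libFactorsMrnaControl[j] * lambda
            cols[[paste0("mrna_ctrl_", j)]] <-
                .nbDraw(mu, config$dispersionMrna)
            meta[[length(meta) + 1L]] <-
                c(paste0("mrna_ctrl_", j), "mrna", "control", j)
        }
        for (j in seq_len(nm)) {
            mu <- config$libFactorsMrnaSponge[j] * lambda * derep
            cols[[paste0("mrna_sp_", j)]] <-
                .nbDraw(mu, config$dispersionMrna)
            meta[[length(meta) + 1L]] <-
                c(paste0("mrna_sp_", j), "mrna", spLabel, j)
        }
        m <- do.call(cbind, cols)
        rownames(m) <- ids
        metaDf <- as.data.frame(do.call(rbind, meta),
                                stringsAsFactors = FALSE)
        names(metaDf) <- c("sample_id", "assay", "condition", "replicate")
        metaDf$replicate <- as.integer(metaDf$replicate)
        out$mrna <- RipCountSet(m, metaDf)
    }
    out
}

#' Write / read the planted ground truth
#'
#' Lossless TSV round-trip of the `truth` table produced by
#' [simulateExperiment()] (doubles serialized at full precision).
#'
#' @param truth truth data.frame.
#' @param path TSV path.
#' @return [readTruth()] returns the data.frame; [writeTruth()] the path,
#'   invisibly.
#' @export
writeTruth <- function(truth, path) {
    .writeTsv(truth, path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    df <- .readTsv(path, colClasses = c(
        gene_id = "character", lambda = "numeric", is_glia = "logical",
        predicted_sites = "character", functional_sites = "character",
        occupancy = "numeric", expected_enrichment = "numeric",
        is_planted_target = "logical", is_sponge_responsive = "logical",
        derepression = "numeric"))
    need <- c("gene_id", "lambda", "is_glia", "predicted_sites",
              "functional_sites", "occupancy", "expected_enrichment",
              "is_planted_target", "is_sponge_responsive", "derepression")
    if (!all(need %in% colnames(df)))
        .stopf("%s: malformed truth table (missing %s)", path,
               paste(setdiff(need, colnames(df)), collapse = ", "))
    for (col in c("predicted_sites", "functional_sites"))
        df[[col]][is.na(df[[col]])] <- ""
    df
}
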