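#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end analysis: either a
#' generator configuration (`sim`) for a fully synthetic run, or paths to
#' existing count tables / site annotation, plus the analysis parameters
#' (anchor gene, window half-width, minimum reads, fold cutoff, top-n,
#' miRNA of interest, Monte-Carlo draws) and one root seed from which all
#' stage seeds derive.
#'
#' @param sim a [spongeSimConfig()], or `NULL` when counts are supplied
#'   via paths.
#' @param ripCountsPath,mrnaCountsPath,sitesPath optional input TSVs
#'   (count tables with embedded `#meta` lines; two-column site
#'   annotation). Must exist at run start.
#' @param anchorGene,halfWindow,minReads,cutoff enrichment parameters,
#'   see [relativeEnrichment()].
#' @param topN number of top rank-shifted genes, default 300.
#' @param mirna miRNA family of interest (site curves, predicted-subset
#'   report); defaults to the generator's inhibited family.
#' @param nullDraws Monte-Carlo draws for the site-curve null band.
#' @param seed root seed.
#' @return validated configuration (class `PipelineConfig`).
#' @export
pipelineConfig <- function(sim = spongeSimConfig(),
                           ripCountsPath = NULL, mrnaCountsPath = NULL,
                           sitesPath = NULL,
                           anchorGene = "Gapdh", halfWindow = 50L,
                           minReads = 10L, cutoff = 4, topN = 300L,
                           mirna = NULL, nullDraws = 200L, seed = 1L) {
    if (is.null(sim) && (is.null(ripCountsPath) || is.null(sitesPath)))
        .stopf("either a generator config or input paths are required")
    if (is.null(mirna))
        mirna <- if (!is.null(sim)) sim$inhibitedFamily else
            .stopf("mirna must be given when no generator config is used")
    if (halfWindow < 0 || minReads < 0 || cutoff <= 0 || topN < 1 ||
        nullDraws < 1)
        .stopf("parameter out of range")
    cfg <- list(sim = sim, ripCountsPath = ripCountsPath,
                mrnaCountsPath = mrnaCountsPath, sitesPath = sitesPath,
                anchorGene = anchorGene,
                halfWindow = as.integer(halfWindow),
                minReads = as.integer(minReads), cutoff = cutoff,
                topN = as.integer(topN), mirna = mirna,
                nullDraws = as.integer(nullDraws),
                seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from a flat key-value YAML file
#'
#' Keys mirror [pipelineConfig()] arguments; generator fields are
#' prefixed `sim_` (e.g. `sim_n_genes`, `sim_inhibition_efficiency`,
#' `sim_inhibited_family`, `sim_glia_fraction`, `sim_mean_derepression`).
#' `sim: false` disables the generator (paths required instead).
#'
#' @param path YAML file of flat scalar keys.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    y <- yaml::read_yaml(path)
    simKeys <- list(sim_n_genes = "nGenes",
                    sim_inhibited_family = "inhibitedFamily",
                    sim_inhibition_efficiency = "inhibitionEfficiency",
                    sim_glia_fraction = "gliaFraction",
                    sim_mean_derepression = "meanDerepression",
                    sim_dispersion_rip = "dispersionRip",
                    sim_dispersion_mrna = "dispersionMrna",
                    sim_expr_mean_log = "exprMeanLog",
                    sim_expr_sd_log = "exprSdLog",
                    sim_seed = "seed")
    sim <- if (isFALSE(y$sim)) NULL else {
        args <- list()
        for (k in names(simKeys))
            if (!is.null(y[[k]])) args[[simKeys[[k]]]] <- y[[k]]
        do.call(spongeSimConfig, args)
    }
    topKeys <- list(rip_counts = "ripCountsPath",
                    mrna_counts = "mrnaCountsPath", sites = "sitesPath",
                    anchor_gene = "anchorGene", half_window = "halfWindow",
                    min_reads = "minReads", cutoff = "cutoff",
                    top_n = "topN", mirna = "mirna",
                    null_draws = "nullDraws", seed = "seed")
    args <- list(sim = sim)
    for (k in names(topKeys))
        if (!is.null(y[[k]])) args[[topKeys[[k]]]] <- y[[k]]
    do.call(pipelineConfig, args)
}

.logLine <- function(logPath, ...) {
    cat(sprintf(...), "\n", sep = "", file = logPath, append = TRUE)
}

.runStage <- function(name, logPath, expr) {
    .logLine(logPath, "[stage %s] start", name)
    res <- tryCatch(expr, error = function(e) {
        .logLine(logPath, "[stage %s] FAILED: %s", name,
                 conditionMessage(e))
        .stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    .logLine(logPath, "[stage %s] done", name)
    res
}

.fragPath <- function(outDir, name) file.path(outDir,
                                              paste0("stage_", name, ".json"))

.writeFrag <- function(outDir, name, frag) {
    jsonlite::write_json(frag, .fragPath(outDir, name),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.readFrag <- function(outDir, name) {
    p <- .fragPath(outDir, name)
    if (!file.exists(p)) .stopf("missing stage output: %s", p)
    jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Run the full RIP-seq targetome pipeline
#'
#' Executes, in order: `simulate` (or loading of supplied counts),
#' `enrich` (sham-normalized enrichment for the control-sponge and
#' target-sponge arms), `rank` (shared-gene ranking, rank shift, top-n
#' selection, released-from-RISC count), `curve` (cumulative
#' predicted-site curves with Monte-Carlo null bands for every family in
#' the annotation) and `integrate` (mRNA-seq fold changes and the
#' derepression report). Every stage writes its intermediates as TSV plus
#' a JSON fragment into `outDir`, and a combined `summary.json` and
#' parameter log are produced at the end. Stage inputs are read from
#' `outDir`, so any suffix of stages can be re-run in isolation against
#' saved intermediates. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "enrich", "rank", "curve", "integrate")`, in pipeline
#'   order; earlier stages must have run before (their files must exist).
#' @return invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
runPipeline <- function(config, outDir,
                        stages = c("simulate", "enrich", "rank", "curve",
                                   "integrate")) {
    stopifnot(inherits(config, "PipelineConfig"))
    all_stages <- c("simulate", "enrich", "rank", "curve", "integrate")
    stages <- match.arg(stages, all_stages, several.ok = TRUE)
    # pre-flight: every referenced input must exist before any stage runs
    for (p in c(config$ripCountsPath, config$mrnaCountsPath,
                config$sitesPath))
        if (!is.null(p) && !file.exists(p))
            .stopf("input path does not exist: %s", p)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(outDir, "pipeline.log")
    if ("simulate" %in% stages) unlink(logPath)
    .logLine(logPath,
             paste0("parameters: anchor=%s half_window=%d min_reads=%d ",
                    "cutoff=%g top_n=%d mirna=%s null_draws=%d seed=%d"),
             config$anchorGene, config$halfWindow, config$minReads,
             config$cutoff, config$topN, config$mirna, config$nullDraws,
             config$seed)

    paths <- list(rip = file.path(outDir, "rip_counts.tsv"),
                  mrna = file.path(outDir, "mrna_counts.tsv"),
                  sites = file.path(outDir, "sites.tsv"),
                  truth = file.path(outDir, "truth.tsv"),
                  enrCtrl = file.path(outDir, "enrichment_control.tsv"),
                  enrSp = file.path(outDir, "enrichment_sponge.tsv"),
                  shift = file.path(outDir, "rank_shift.tsv"),
                  top = file.path(outDir, "top_shifted.txt"),
                  fc = file.path(outDir, "fold_changes.tsv"))

    if ("simulate" %in% stages) .runStage("simulate", logPath, {
        if (!is.null(config$sim)) {
            simCfg <- config$sim
            simCfg$seed <- config$seed
            sim <- simulateExperiment(simCfg)
            writeCountTable(sim$rip, paths$rip)
            writeCountTable(sim$mrna, paths$mrna)
            writeSiteAnnotation(sim$sites, paths$sites)
            writeTruth(sim$truth, paths$truth)
            .writeFrag(outDir, "simulate",
                       list(source = "generator", n_genes = simCfg$nGenes,
                            inhibited_family = simCfg$inhibitedFamily,
                            inhibition_efficiency =
                                simCfg$inhibitionEfficiency,
                            seed = config$seed))
        } else {
            file.copy(config$ripCountsPath, paths$rip, overwrite = TRUE)
            if (!is.null(config$mrnaCountsPath))
                file.copy(config$mrnaCountsPath, paths$mrna,
                          overwrite = TRUE)
            file.copy(config$sitesPath, paths$sites, overwrite = TRUE)
            .writeFrag(outDir, "simulate",
                       list(source = "files",
                            rip_counts = config$ripCountsPath,
                            mrna_counts = config$mrnaCountsPath,
                            sites = config$sitesPath))
        }
        NULL
    })

    if ("enrich" %in% stages) .runStage("enrich", logPath, {
        rip <- readCountTable(paths$rip)
        info <- sampleInfo(rip)
        sham <- info[info$assay == "sham", ]
        sham <- sham[order(sham$replicate), ]
        ripConds <- unique(info$condition[info$assay == "rip"])
        if (length(ripConds) < 2)
            .stopf("need RIP samples for two conditions, found: %s",
                   paste(ripConds, collapse = ", "))
        ctrlCond <- if ("control-sponge" %in% ripConds) "control-sponge"
                    else ripConds[1]
        spCond <- setdiff(ripConds, ctrlCond)[1]
        enrOne <- function(cond) {
            arm <- info[info$assay == "rip" & info$condition == cond, ]
            arm <- arm[order(arm$replicate), ]
            if (nrow(arm) != nrow(sham))
                .stopf("condition '%s': %d RIP but %d sham replicates",
                       cond, nrow(arm), nrow(sham))
            relativeEnrichment(rip, arm$sample_id, sham$sample_id,
                               anchorGene = config$anchorGene,
                               halfWindow = config$halfWindow,
                               minReads = config$minReads,
                               cutoff = config$cutoff)
        }
        enrCtrl <- enrOne(ctrlCond)
        enrSp <- enrOne(spCond)
        .writeTsv(enrichmentTable(enrCtrl, all = TRUE), paths$enrCtrl)
        .writeTsv(enrichmentTable(enrSp, all = TRUE), paths$enrSp)
        .writeFrag(outDir, "enrich",
                   list(control_condition = ctrlCond,
                        sponge_condition = spCond,
                        n_genes_control = length(enrichment(enrCtrl)),
                        n_genes_sponge = length(enrichment(enrSp)),
                        bound_control = length(boundGenes(enrCtrl)),
                        bound_sponge = length(boundGenes(enrSp))))
        NULL
    })

    if ("rank" %in% stages) .runStage("rank", logPath, {
        eC <- .readEnrTsv(paths$enrCtrl)
        eS <- .readEnrTsv(paths$enrSp)
        shared <- intersect(names(eC$E), names(eS$E))
        shared <- shared[order(shared, method = "radix")]
        rC <- assignRanks(eC$E[shared])
        rS <- assignRanks(eS$E[shared])
        universe <- intersect(eC$bound, shared)
        shift <- rankShift(rC, rS, universe)
        .writeTsv(shift, paths$shift)
        top <- topShifted(shift, config$topN)
        writeLines(top, paths$top)
        released <- setdiff(eC$bound, eS$bound)
        .writeFrag(outDir, "rank",
                   list(n_shared = length(shared),
                        n_universe = length(universe),
                        n_released = length(released),
                        top_n = config$topN,
                        top_shifted = top))
        NULL
    })

    if ("curve" %in% stages) .runStage("curve", logPath, {
        shift <- .readTsv(paths$shift)
        ranks <- stats::setNames(as.integer(shift$rank_control),
                                 shift$gene_id)
        sites <- readSiteAnnotation(paths$sites)
        fams <- sort(unique(unlist(sites, use.names = FALSE)),
                     method = "radix")
        stats_list <- list()
        for (i in seq_along(fams)) {
            fam <- fams[i]
            cv <- siteCurve(ranks, sites, fam)
            nul <- siteCurveNull(ranks, cv@nSiteGenes,
                                 draws = config$nullDraws,
                                 seed = .deriveSeed(config$seed, 20L + i))
            .writeTsv(as.data.frame(cv),
                      file.path(outDir, paste0(
                          "site_curve_", gsub("[^A-Za-z0-9]+", "_", fam),
                          ".tsv")))
            stats_list[[fam]] <- list(
                n_site_genes = cv@nSiteGenes,
                auc_dev = aucDev(cv), d_max = dMax(cv),
                null_band = nul$band,
                outside_null_band = abs(aucDev(cv)) > nul$band)
        }
        .writeFrag(outDir, "curve", stats_list)
        NULL
    })

    if ("integrate" %in% stages) .runStage("integrate", logPath, {
        if (!file.exists(paths$mrna))
            .stopf("no mRNA counts available for integration")
        mrna <- readCountTable(paths$mrna)
        info <- sampleInfo(mrna)
        ctrl <- info$sample_id[info$condition == "control"]
        sp <- info$sample_id[info$condition != "control"]
        fc <- foldChanges(mrna, ctrl, sp)
        .writeTsv(fc, paths$fc)
        top <- readLines(paths$top)
        sites <- readSiteAnnotation(paths$sites)
        drep <- derepressionAnalysis(top, fc, sites, config$mirna)
        frag <- list(
            n_expressed = drep$n_expressed,
            n_shift_expressed = drep$shift$n,
            shift_mean_fc = drep$shift$mean_fc,
            shift_sem_fc = drep$shift$sem_fc,
            other_mean_fc = drep$other$mean_fc,
            other_sem_fc = drep$other$sem_fc,
            ks_D = drep$ks$statistic, ks_p = drep$ks$p_value,
            t_statistic = drep$t_vs_all$statistic,
            t_p = drep$t_vs_all$p_value)
        if (!is.null(drep$predicted))
            frag$predicted <- list(
                mirna = drep$predicted$mirna, n = drep$predicted$n,
                mean_fc = drep$predicted$mean_fc,
                sem_fc = drep$predicted$sem_fc,
                ks_p = drep$predicted$ks$p_value,
                t_p = drep$predicted$t_vs_all$p_value)
        .writeFrag(outDir, "integrate", frag)
        NULL
    })

    summary <- list(
        parameters = list(anchor_gene = config$anchorGene,
                          half_window = config$halfWindow,
                          min_reads = config$minReads,
                          cutoff = config$cutoff, top_n = config$topN,
                          mirna = config$mirna,
                          null_draws = config$nullDraws,
                          seed = config$seed))
    for (st in all_stages)
        if (file.exists(.fragPath(outDir, st)))
            summary[[st]] <- .readFrag(outDir, st)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .logLine(logPath, "pipeline complete")
    invisible(summary)
}

# Reads an enrichment TSV written by the enrich stage back into the mean
# enrichment vector and bound set.
.readEnrTsv <- function(path) {
    df <- .readTsv(path)
    keep <- !is.na(df$E_mean)
    list(E = stats::setNames(df$E_mean[keep], df$gene_id[keep]),
         bound = df$gene_id[keep][df$is_bound[keep]])
}
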