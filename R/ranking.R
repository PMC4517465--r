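#' Rank genes by relative AGO2 enrichment
#'
#' Ascending ranks over the gene universe: the gene with the lowest
#' relative enrichment is ranked 1, the second lowest 2, and so on. Ties
#' are broken by gene identifier (C-locale) so rankings are deterministic.
#'
#' @param object an [EnrichmentResult-class] or a named numeric vector of
#'   enrichments.
#' @param ... unused.
#' @return named integer vector of ranks, a permutation of `1..N`.
#' @export
setMethod("assignRanks", "numeric", function(object, ...) {
    ids <- names(object)
    if (is.null(ids)) .stopf("enrichment vector must be named")
    if (anyDuplicated(ids)) .stopf("duplicate gene identifiers")
    ord <- .orderBy(object, ids)
    ranks <- integer(length(object))
    ranks[ord] <- seq_along(object)
    names(ranks) <- ids
    ranks
})

#' @rdname assignRanks
#' @export
setMethod("assignRanks", "EnrichmentResult", function(object, ...)
    assignRanks(enrichment(object)))

# genes of `sites` annotated with a site for `mirna`
.siteGenes <- function(sites, mirna) {
    s <- as.list(sites)
    names(s)[vapply(s, function(v) mirna %in% v, logical(1))]
}

#' Cumulative predicted-site curve
#'
#' Walks the enrichment ranking from lowest to highest AGO2 binding and
#' accumulates the fraction of genes carrying a predicted conserved site
#' for one miRNA family. If the family's predicted targets are randomly
#' scattered the curve follows the diagonal `y = x/N`; if the family is
#' active in the profiled cells, its targets concentrate at high ranks
#' and the curve sags below the diagonal. Two summary statistics quantify
#' the visual "curved appearance": `aucDev = mean(y - x/N)` (negative for
#' an active family) and `dMax = max |y - x/N|`.
#'
#' @param ranks named integer rank vector from [assignRanks()].
#' @param sites gene -> miRNA-family annotation
#'   (named list / `CharacterList`, see [readSiteAnnotation()]).
#' @param mirna miRNA family name.
#' @return a [SiteCurve-class].
#' @seealso [siteCurveNull()] for the Monte-Carlo null band.
#' @export
siteCurve <- function(ranks, sites, mirna) {
    n <- length(ranks)
    ids <- names(ranks)
    siteGenes <- .siteGenes(sites, mirna)
    has <- ids %in% siteGenes
    k <- sum(has)
    if (k == 0L) .stopf("empty site set for %s", mirna)
    y <- cumsum(has[order(ranks)]) / k
    x <- seq_len(n)
    dev <- y - x / n
    new("SiteCurve", mirna = mirna, x = x, y = y,
        aucDev = mean(dev), dMax = max(abs(dev)), nSiteGenes = as.integer(k))
}

#' @rdname siteCurve
#' @param object a `SiteCurve`.
#' @export
setMethod("aucDev", "SiteCurve", function(object) object@aucDev)

#' @rdname siteCurve
#' @export
setMethod("dMax", "SiteCurve", function(object) object@dMax)

#' @rdname siteCurve
#' @param x a `SiteCurve`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "SiteCurve", function(x, ...)
    data.frame(x = x@x, y = x@y, diag = x@x / length(x@x)))

setMethod("show", "SiteCurve", function(object) {
    cat(sprintf("SiteCurve for %s: %d site genes of %d; aucDev = %.4f, dMax = %.4f\n",
                object@mirna, object@nSiteGenes, length(object@x),
                object@aucDev, object@dMax))
})

#' Monte-Carlo null distribution for site-curve statistics
#'
#' Draws random site-gene sets of the observed size and returns the null
#' distribution of `aucDev`, from which a two-sided band (default 95%)
#' is derived. An observed `|aucDev|` above the band indicates
#' non-random placement of the family's predicted targets along the
#' AGO2-binding ranking.
#'
#' @param ranks named integer rank vector (defines the universe size N).
#' @param nSiteGenes number of site-bearing genes to plant per draw.
#' @param draws number of Monte-Carlo draws, default 200.
#' @param seed integer seed for reproducibility.
#' @param level band coverage, default 0.95.
#' @return list with `aucDev` (numeric vector of null values) and `band`
#'   (the `level` quantile of `|aucDev|`).
#' @export
siteCurveNull <- function(ranks, nSiteGenes, draws = 200L, seed = 1L,
                          level = 0.95) {
    n <- length(ranks)
    k <- as.integer(nSiteGenes)
    if (k < 1L || k > n) .stopf("nSiteGenes must be in 1..N")
    set.seed(as.integer(seed))
    vals <- vapply(seq_len(draws), function(i) {
        pos <- sample.int(n, k)
        # closed form: sum_x y(x) = sum_i (N - pos_i + 1) / k
        sum(n - pos + 1) / (k * n) - (n + 1) / (2 * n)
    }, numeric(1))
    list(aucDev = vals,
         band = unname(stats::quantile(abs(vals), level, type = 7)))
}

#' Rank shift between control-sponge and target-sponge conditions
#'
#' For each gene ranked in both conditions, the change in enrichment rank
#' `delta = rank_control - rank_sponge`. A gene released from the RISC by
#' the sponge loses AGO2 binding, drops in the sponge ranking, and gets a
#' positive delta. Ranks must come from the same shared gene set; deltas
#' therefore sum to zero over that set. Downstream analysis is restricted
#' to the AGO2-bound `universe` (flagged, not dropped) to avoid calling
#' shifts among unbound noise-level genes.
#'
#' @param control,sponge named integer rank vectors over the same genes
#'   (see [assignRanks()]); by convention `control` is the inert-sponge
#'   (e.g. miR-292 sponge) arm.
#' @param universe character vector of bound genes (e.g.
#'   [boundGenes()] of the control arm).
#' @return data.frame with columns `gene_id`, `rank_control`,
#'   `rank_sponge`, `delta`, `in_universe`.
#' @export
rankShift <- function(control, sponge, universe = character(0)) {
    miss1 <- setdiff(names(control), names(sponge))
    miss2 <- setdiff(names(sponge), names(control))
    if (length(miss1) || length(miss2))
        .stopf("rank tables cover different gene sets; missing: %s",
               paste(utils::head(c(miss1, miss2), 10), collapse = ", "))
    ids <- names(control)
    sp <- sponge[ids]
    data.frame(gene_id = ids,
               rank_control = unname(control),
               rank_sponge = unname(sp),
               delta = unname(control - sp),
               in_universe = ids %in% universe,
               stringsAsFactors = FALSE)
}

#' Top rank-shifted genes
#'
#' The `n` universe genes with the greatest loss of AGO2 binding
#' (largest positive `delta`), in descending order of delta, ties broken
#' by gene identifier.
#'
#' @param shift data.frame from [rankShift()].
#' @param n number of genes, default 300.
#' @return character vector of gene identifiers.
#' @export
topShifted <- function(shift, n = 300L) {
    n <- as.integer(n)
    if (n < 1L) .stopf("n must be at least 1")
    uni <- shift[shift$in_universe, , drop = FALSE]
    if (n > nrow(uni))
        .stopf("n (%d) exceeds universe size (%d)", n, nrow(uni))
    ord <- .orderBy(uni$delta, uni$gene_id, decreasing = TRUE)
    uni$gene_id[ord][seq_len(n)]
}

#' Intersect a gene list with predicted targets of a miRNA family
#'
#' Subset of `genes` carrying a predicted conserved site for `mirna`
#' (e.g. the rank-shifted genes that are also TargetScan-predicted
#' targets of the sponged family). Input order is preserved.
#'
#' @param genes character vector of gene identifiers.
#' @param sites gene -> family annotation.
#' @param mirna miRNA family name.
#' @return character vector.
#' @export
intersectPredicted <- function(genes, sites, mirna) {
    genes[genes %in% .siteGenes(sites, mirna)]
}
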