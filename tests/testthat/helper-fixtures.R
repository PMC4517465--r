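# Fixtures built in code; no data files.

# RipCountSet from a bare matrix with minimal metadata.
makeRipSet <- function(m, assay = rep("rip", ncol(m)),
                       condition = rep("x", ncol(m)),
                       replicate = seq_len(ncol(m)),
                       ids = paste0("s", seq_len(ncol(m)))) {
    if (is.null(rownames(m)))
        rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    RipCountSet(m, data.frame(sample_id = ids, assay = assay,
                              condition = condition,
                              replicate = replicate,
                              stringsAsFactors = FALSE))
}

# Single-replicate RIP/sham pair with all counts comfortably above the
# minimum-read filter, plus a mid-ratio anchor gene.
randPairTable <- function(nGenes = 300, seed = 1) {
    set.seed(seed)
    m <- cbind(sample(10:1000, nGenes, replace = TRUE),
               sample(10:1000, nGenes, replace = TRUE))
    rownames(m) <- sprintf("g%03d", seq_len(nGenes))
    r <- m[, 1] / m[, 2]
    anchor <- rownames(m)[order(r, rownames(m),
                                method = "radix")][nGenes %/% 2]
    list(set = makeRipSet(m, assay = c("rip", "sham"),
                          condition = c("control-sponge", "sham"),
                          replicate = c(1L, 1L),
                          ids = c("rip_1", "sham_1")),
         anchor = anchor)
}

# Reduced generator for fast pipeline-level tests.
smallSimConfig <- function(...) {
    spongeSimConfig(nGenes = 1500L, seed = 11L, ...)
}

# Rank-based AUROC of a score against binary labels (independent of any
# package code under test).
aurocOf <- function(score, labels) {
    r <- rank(score)
    np <- sum(labels); nn <- sum(!labels)
    (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}
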