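# Internal helpers shared across modules.

# Deterministic ordering: numeric key first, ties broken by identifier in
# C-locale (radix) collation so results do not depend on the session locale.
.orderBy <- function(key, id, decreasing = FALSE) {
    order(if (decreasing) -xtfrm(key) else key, id, method = "radix")
}

# Full-precision TSV writer: doubles serialized with %.17g so files
# round-trip losslessly and downstream stages reproduce in-memory values.
.writeTsv <- function(df, path) {
    fmt <- vapply(df, function(col) is.double(col), logical(1))
    out <- df
    for (j in which(fmt)) out[[j]] <- sprintf("%.17g", df[[j]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.readTsv <- function(path, ...) {
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      check.names = FALSE, ...)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Seeds derived from one root seed; kept well below .Machine$integer.max.
.deriveSeed <- function(seed, offset) {
    (as.integer(seed) %% 2000000000L) + as.integer(offset)
}
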