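# Small internal helpers: seeded evaluation that restores global RNG state,
# per-stage seed derivation, and a content hash for provenance stamping.

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old))
            suppressWarnings(rm(".Random.seed", envir = globalenv()))
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic stage seed derived from a global seed and a stage label,
# kept inside 32-bit integer range.
.stageSeed <- function(seed, label) {
    h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
    as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Cheap deterministic content hash (FNV-1a over the serialized text), used to
# stamp pipeline artifacts so artifacts from different configs cannot be mixed.
.configHash <- function(x) {
    txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
    bytes <- utf8ToInt(as.character(txt))
    h <- 2166136261
    for (b in bytes) {
        h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
        h <- (h * 16777619) %% 2^31
    }
    sprintf("%08x", as.integer(h))
}

.assertScalarNumber <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop("'", name, "' must be a single number")
    invisible(x)
}
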