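# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Coerce MetastasisExperiment / matrix input to a proteins x samples matrix.
asProteinMatrix <- function(x) {
    if (is(x, "MetastasisExperiment")) return(lfq(x))
    if (is.matrix(x) && is.numeric(x)) return(x)
    stop("expected a MetastasisExperiment or a numeric matrix")
}

# Labels aligned to the columns of a protein matrix.
asGroupFactor <- function(labels) {
    f <- factor(as.character(labels), levels = METASTASIS_LEVELS)
    if (anyNA(f)) stop("labels must lie in {NM, LM, M}")
    droplevels(f)
}

# Fixed-precision numeric formatting so repeated runs emit identical bytes.
formatNum <- function(x) {
    out <- trimws(formatC(x, digits = 10, format = "g"))
    if (is.matrix(x)) {
        dim(out) <- dim(x)
        dimnames(out) <- dimnames(x)
    }
    out
}
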