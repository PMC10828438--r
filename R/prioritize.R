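#' Per-protein one-way ANOVA p-values
#'
#' Fixed-effects one-way ANOVA of each protein's abundance across the
#' metastasis classes, computed rowwise from the sums-of-squares
#' decomposition (the standard vectorized formulation for feature-wise F
#' tests on expression matrices). A protein whose values are all identical
#' has no variance to partition and is assigned p = 1 with a warning.
#'
#' @param x complete [MetastasisExperiment-class] or proteins x samples
#'   matrix (no missing values).
#' @param labels class per sample; taken from `x` when it is a
#'   `MetastasisExperiment`.
#' @return named numeric vector of p-values in [0, 1].
#' @export
anovaPvalues <- function(x, labels = NULL) {
    vals <- asProteinMatrix(x)
    if (anyNA(vals)) stop("matrix contains missing values; impute first")
    if (is.null(labels) && is(x, "MetastasisExperiment"))
        labels <- metastasisGroup(x)
    g <- asGroupFactor(labels)
    if (length(g) != ncol(vals)) stop("labels do not match samples")
    sizes <- table(g)
    if (length(sizes) < 2L || any(sizes < 2L))
        stop("need >= 2 classes with >= 2 samples each")
    n <- ncol(vals)
    kg <- nlevels(g)
    ind <- stats::model.matrix(~ g - 1)
    gs <- vals %*% ind                       # group sums
    gm <- sweep(gs, 2, as.numeric(sizes), "/")
    grand <- rowMeans(vals)
    ssb <- rowSums(sweep((gm - grand)^2, 2, as.numeric(sizes), "*"))
    tss <- rowSums(vals^2) - n * grand^2
    ssw <- pmax(tss - ssb, 0)
    scale <- pmax(rowMeans(vals^2), 1)
    degen <- tss <= 1e-12 * scale
    f <- (ssb / (kg - 1)) / (ssw / (n - kg))
    p <- stats::pf(f, kg - 1, n - kg, lower.tail = FALSE)
    p[ssw <= 1e-12 * scale & !degen] <- 0    # perfect separation
    if (any(degen)) {
        warning(sum(degen), " protein(s) with all-identical values; p set to 1")
        p[degen] <- 1
    }
    stats::setNames(pmin(pmax(p, 0), 1), rownames(vals))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment.
#'
#' @param pvalues numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in [0, 1], same order and names as the input.
#' @export
adjustBH <- function(pvalues) {
    if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

#' Differential-abundance seed proteins
#'
#' Proteins whose BH-adjusted ANOVA p-value is strictly below `alpha`; these
#' act as the heat sources for network propagation.
#'
#' @param adjusted_pvalues named vector of adjusted p-values.
#' @param alpha significance threshold (strict inequality), default 0.1.
#' @return character vector of seed protein ids (possibly empty).
#' @export
selectSeeds <- function(adjusted_pvalues, alpha = 0.1) {
    names(adjusted_pvalues)[adjusted_pvalues < alpha]
}

#' Tercile discretization of one protein's abundances
#'
#' Assigns each value to `L` (low), `M` (medium) or `H` (high) by the 1/3
#' and 2/3 empirical quantiles of the supplied values (linear-interpolation
#' quantiles, R type 7): value <= q1/3 is `L`, <= q2/3 is `M`, else `H`.
#'
#' @param values numeric vector, length >= 3.
#' @return factor with levels `L`, `M`, `H`.
#' @export
discretizeTerciles <- function(values) {
    if (length(values) < 3L) stop("need >= 3 values to form terciles")
    if (anyNA(values)) stop("values contain NA")
    if (max(values) == min(values)) {
        warning("constant vector: all values assigned 'L' (MI will be 0)")
        return(factor(rep("L", length(values)), levels = c("L", "M", "H")))
    }
    qs <- stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
    cat_ <- ifelse(values <= qs[1], "L", ifelse(values <= qs[2], "M", "H"))
    factor(cat_, levels = c("L", "M", "H"))
}

#' Plug-in mutual information between two discrete variables
#'
#' Empirical (plug-in) mutual information in bits:
#' sum over cells of p(x,y) log2( p(x,y) / (p(x) p(y)) ), with 0 log 0 = 0.
#' Symmetric in its arguments and invariant under category relabeling.
#'
#' @param x,y equal-length vectors of categories (factor or character).
#' @return MI in bits, >= 0 and <= min(log2 |X|, log2 |Y|).
#' @export
mutualInformation <- function(x, y) {
    if (length(x) == 0L) stop("empty input")
    if (length(x) != length(y)) stop("inputs must have equal length")
    tab <- table(x, y)
    n <- sum(tab)
    pj <- tab / n
    px <- rowSums(pj)
    py <- colSums(pj)
    e <- outer(px, py)
    nz <- pj > 0
    sum(pj[nz] * log2(pj[nz] / e[nz]))
}

#' Class-balanced averaged mutual information per protein
#'
#' The class sizes are unbalanced (10/9/10), so MI is averaged over
#' `n_batches` resampling batches: in each batch an equal number of samples
#' per class (the minimum class size) is drawn without replacement, each
#' protein is tercile-discretized within the batch, and its MI with the
#' class label is computed; the per-protein mean over batches is returned.
#' Batch membership is drawn in R under `rng_seed`; the per-batch
#' discretization and MI run in compiled code.
#'
#' @param x complete [MetastasisExperiment-class] or proteins x samples
#'   matrix.
#' @param labels class per sample (taken from `x` if a
#'   `MetastasisExperiment`).
#' @param n_batches number of balanced resampling batches, default 100.
#' @param rng_seed integer seed for batch membership.
#' @return named numeric vector, averaged MI (bits) per protein.
#' @export
balancedMI <- function(x, labels = NULL, n_batches = 100L, rng_seed = 1L) {
    vals <- asProteinMatrix(x)
    if (anyNA(vals)) stop("matrix contains missing values; impute first")
    if (is.null(labels) && is(x, "MetastasisExperiment"))
        labels <- metastasisGroup(x)
    g <- asGroupFactor(labels)
    if (length(g) != ncol(vals)) stop("labels do not match samples")
    sizes <- table(g)
    if (any(sizes < 2L)) stop("every class needs >= 2 samples")
    idx <- miBatchIndices(g, n_batches, rng_seed)
    mi <- cpp_balanced_mi(vals, as.integer(g), idx, nlevels(g))
    stats::setNames(mi, rownames(vals))
}

# Balanced batch membership: n_balanced = min class size, drawn without
# replacement per class per batch. Returns a (n_balanced * n_classes) x
# n_batches integer matrix of 1-based sample indices.
miBatchIndices <- function(g, n_batches, rng_seed) {
    n_bal <- min(table(g))
    by_class <- split(seq_along(g), g)
    withSeed(rng_seed, {
        vapply(seq_len(n_batches), function(b)
            unlist(lapply(by_class, function(ix)
                if (length(ix) == n_bal) sample(ix) else sample(ix, n_bal)),
                use.names = FALSE),
            integer(n_bal * nlevels(g)))
    })
}

# Pure-R reference for balancedMI (same batch indices); used as the
# cross-check oracle for the compiled path.
balancedMIReference <- function(vals, g, idx) {
    mi <- numeric(nrow(vals))
    for (b in seq_len(ncol(idx))) {
        sel <- idx[, b]
        gb <- g[sel]
        for (p in seq_len(nrow(vals))) {
            d <- suppressWarnings(discretizeTerciles(vals[p, sel]))
            mi[p] <- mi[p] + mutualInformation(gb, d)
        }
    }
    stats::setNames(mi / ncol(idx), rownames(vals))
}

#' Insulated-diffusion network-propagation scores
#'
#' Edges with confidence below `confidence_threshold` are removed; the
#' remaining (binary) adjacency is column-normalized into a column-
#' stochastic walk matrix W (isolated nodes receive a self-loop); the
#' diffusion operator is F = beta (I - (1 - beta) W)^(-1), the insulated
#' heat-diffusion kernel used by HotNet2; scores are F h for a seed heat
#' vector h. With binary heat, h is 1 on seeds present in the network and 0
#' elsewhere. Since W is column-stochastic the total heat is conserved:
#' the scores sum to the total seed heat.
#'
#' @param network igraph with edge attribute `confidence` in [0, 1].
#' @param seeds character vector of seed protein ids.
#' @param beta restart (insulation) probability in (0, 1]; default 0.4, the
#'   usual choice for protein-interaction networks.
#' @param confidence_threshold edges with confidence strictly below this are
#'   dropped; default 0.5.
#' @param heat `"binary"` (1 per seed) or `"pvalue"` (-log10 adjusted p).
#' @param adjusted_pvalues named vector, required for `heat = "pvalue"`.
#' @return named numeric vector of scores over the network's nodes.
#' @export
networkPropagationScores <- function(network, seeds, beta = 0.4,
                                     confidence_threshold = 0.5,
                                     heat = c("binary", "pvalue"),
                                     adjusted_pvalues = NULL) {
    heat <- match.arg(heat)
    if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
        stop("'beta' must lie in (0, 1]")
    if (igraph::ecount(network) > 0) {
        conf <- igraph::E(network)$confidence
        if (is.null(conf))
            stop("network lacks a 'confidence' edge attribute")
        g <- igraph::delete_edges(network, which(conf < confidence_threshold))
    } else {
        g <- network
    }
    nodes <- igraph::V(g)$name
    n <- length(nodes)
    if (n == 0L) stop("network is empty")
    h <- stats::setNames(numeric(n), nodes)
    seeds_in <- intersect(seeds, nodes)
    if (length(seeds_in) == 0L) {
        warning("no seed present in the network: all propagation scores are 0")
        return(h)
    }
    if (heat == "binary") {
        h[seeds_in] <- 1
    } else {
        if (is.null(adjusted_pvalues))
            stop("heat = 'pvalue' requires 'adjusted_pvalues'")
        h[seeds_in] <- -log10(pmax(adjusted_pvalues[seeds_in], 1e-300))
    }
    a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    a <- (a > 0) * 1
    deg <- Matrix::colSums(a)
    iso <- which(deg == 0)
    if (length(iso)) {
        a <- a + Matrix::sparseMatrix(i = iso, j = iso, x = 1,
                                      dims = c(n, n))
        deg[iso] <- 1
    }
    w <- a %*% Matrix::Diagonal(x = 1 / deg)
    m <- Matrix::Diagonal(n) - (1 - beta) * w
    scores <- beta * as.numeric(Matrix::solve(m, h))
    stats::setNames(scores, nodes)
}

#' Rank proteins by MI with network-propagation tie-breaking
#'
#' Primary key: descending averaged MI. Proteins whose MI values differ by
#' at most `tie_epsilon` (chained along the sorted sequence) form a tie
#' group ordered by descending NP score; residual ties fall back to
#' lexicographic protein id, making the order fully deterministic.
#'
#' @param mi_scores named numeric vector of averaged MI per protein.
#' @param np_scores numeric vector of propagation scores over the same
#'   proteins (names aligned by id; proteins absent get 0).
#' @param tie_epsilon MI difference treated as a tie; default 1e-9.
#' @return a [RankedFeatures-class] object.
#' @export
rankFeatures <- function(mi_scores, np_scores, tie_epsilon = 1e-9) {
    ids <- names(mi_scores)
    if (is.null(ids)) stop("'mi_scores' must be named by protein")
    np <- rep(0, length(ids))
    names(np) <- ids
    if (!is.null(names(np_scores))) {
        common <- intersect(ids, names(np_scores))
        np[common] <- np_scores[common]
    } else {
        if (length(np_scores) != length(ids))
            stop("unnamed 'np_scores' must align with 'mi_scores'")
        np[] <- np_scores
    }
    mi <- as.numeric(mi_scores)
    ord1 <- order(-mi, ids)
    grp <- cumsum(c(1, -diff(mi[ord1]) > tie_epsilon))
    final <- ord1[order(grp, -np[ord1], ids[ord1])]
    tab <- data.frame(protein_id = ids[final],
                      mi_score = mi[final],
                      np_score = as.numeric(np[final]),
                      mi_rank = rank(-mi, ties.method = "average")[final],
                      np_rank = rank(-np, ties.method = "average")[final],
                      final_rank = seq_along(final),
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    new("RankedFeatures", table = tab, tie_epsilon = tie_epsilon)
}

#' Combined MI / NP rank table for candidate proteins
#'
#' Reports, for each candidate, its 1-based position in the full MI ordering
#' and in the full NP ordering (average ranks for ties) — the scatter used
#' to compare biomarker candidates against the rest of the proteome.
#'
#' @param ranked a [RankedFeatures-class] object.
#' @param candidates character vector of candidate protein ids.
#' @return data.frame with columns `protein_id`, `mi_rank`, `np_rank`.
#' @export
combinedRankTable <- function(ranked, candidates) {
    tab <- featureScores(ranked)
    unknown <- setdiff(candidates, tab$protein_id)
    if (length(unknown))
        stop("unknown candidate id: ", paste(unknown, collapse = ", "))
    sub <- tab[match(candidates, tab$protein_id),
               c("protein_id", "mi_rank", "np_rank")]
    rownames(sub) <- NULL
    sub
}
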