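#' Configuration for the leave-one-out consensus run
#'
#' Collects every tunable of the per-fold prioritization and selection
#' stages. Defaults follow the pipeline's standard settings: 100 balanced
#' MI batches, insulated diffusion with beta 0.4 on the network trimmed at
#' confidence 0.5, ANOVA/BH seeds at adjusted p < 0.1, five stratified
#' inner folds, recursive addition capped at 30 features with patience 5,
#' SVM cost 1, and a consensus threshold of 3 folds.
#'
#' @param n_batches balanced MI resampling batches per fold.
#' @param beta diffusion restart probability in (0, 1].
#' @param confidence_threshold edge-confidence trim threshold.
#' @param alpha_seed adjusted-p threshold for diffusion seeds (strict `<`).
#' @param tie_epsilon MI difference treated as a tie.
#' @param heat `"binary"` seed heat or `"pvalue"` (-log10 adjusted p).
#' @param inner_k inner CV folds for recursive feature addition.
#' @param max_features largest prefix size evaluated.
#' @param patience non-improving additions tolerated before stopping.
#' @param svm_cost SVM cost parameter C.
#' @param min_count consensus threshold: selected in at least this many
#'   folds.
#' @param seed master seed; fold f uses `seed + f` for its resampling and
#'   fold shuffles, so runs are reproducible without correlating folds.
#' @return a validated list of class `LoocvConfig`.
#' @export
loocvConfig <- function(n_batches = 100L, beta = 0.4,
                        confidence_threshold = 0.5, alpha_seed = 0.1,
                        tie_epsilon = 1e-9, heat = c("binary", "pvalue"),
                        inner_k = 5L, max_features = 30L, patience = 5L,
                        svm_cost = 1, min_count = 3L, seed = 1L) {
    heat <- match.arg(heat)
    if (beta <= 0 || beta > 1) stop("'beta' must lie in (0, 1]")
    if (alpha_seed <= 0 || alpha_seed > 1)
        stop("'alpha_seed' must lie in (0, 1]")
    if (inner_k < 2L) stop("'inner_k' must be >= 2")
    if (min_count < 1L) stop("'min_count' must be >= 1")
    cfg <- list(n_batches = as.integer(n_batches), beta = beta,
                confidence_threshold = confidence_threshold,
                alpha_seed = alpha_seed, tie_epsilon = tie_epsilon,
                heat = heat, inner_k = as.integer(inner_k),
                max_features = as.integer(max_features),
                patience = as.integer(patience), svm_cost = svm_cost,
                min_count = as.integer(min_count), seed = as.integer(seed))
    class(cfg) <- "LoocvConfig"
    cfg
}

# One outer fold: sample `fold` is excluded from every training computation
# (ANOVA seeds, propagation heat, balanced MI, discretization, recursive
# addition, classifier fitting) and only then predicted.
runFold <- function(vals, g, network, fold, config) {
    tr <- setdiff(seq_len(ncol(vals)), fold)
    vtr <- vals[, tr, drop = FALSE]
    gtr <- g[tr]
    fold_seed <- config$seed + fold

    p <- anovaPvalues(vtr, gtr)
    adj <- adjustBH(p)
    seeds <- selectSeeds(adj, config$alpha_seed)
    np <- withCallingHandlers(
        networkPropagationScores(network, seeds, beta = config$beta,
                                 confidence_threshold =
                                     config$confidence_threshold,
                                 heat = config$heat,
                                 adjusted_pvalues = adj),
        warning = function(w) invokeRestart("muffleWarning"))
    mi <- balancedMI(vtr, gtr, n_batches = config$n_batches,
                     rng_seed = fold_seed)
    ranked <- rankFeatures(mi, np, tie_epsilon = config$tie_epsilon)
    trace <- recursiveFeatureAddition(t(vtr), gtr, ranked,
                                      inner_k = config$inner_k,
                                      max_features = config$max_features,
                                      patience = config$patience,
                                      cost = config$svm_cost,
                                      seed = fold_seed)
    sel <- chosenFeatures(trace)
    pred <- fitAndPredict(t(vtr), gtr, sel, t(vals[, fold, drop = FALSE]),
                          cost = config$svm_cost)
    list(sample_id = colnames(vals)[fold],
         true_label = as.character(g[fold]),
         predicted_label = pred,
         selected = sel,
         n_seeds = length(seeds),
         trace = trace,
         seed = fold_seed,
         n_batches = config$n_batches)
}

#' Outer leave-one-out loop over samples
#'
#' For each sample in turn, the remaining samples are used for the complete
#' feature-selection stack — differential-abundance seeds, network
#' propagation, balanced MI ranking with tie-breaking, and SVM recursive
#' feature addition — and the fold's classifier, trained on its selected
#' features, predicts the held-out sample. Nothing derived from the
#' held-out sample enters any training computation.
#'
#' @param x complete [MetastasisExperiment-class] (impute first).
#' @param network igraph protein-interaction network with `confidence`
#'   edge attribute.
#' @param config a [loocvConfig()] object.
#' @return list of per-fold records, each with elements `sample_id`,
#'   `true_label`, `predicted_label`, `selected`, `n_seeds`, `trace`,
#'   `seed`, `n_batches`.
#' @export
runLoocv <- function(x, network, config = loocvConfig()) {
    vals <- lfq(x)
    if (anyNA(vals)) stop("matrix contains missing values; impute first")
    g <- metastasisGroup(x)
    if (ncol(vals) < 6L) stop("need at least 6 samples")
    sizes <- table(droplevels(g))
    if (length(sizes) < 2L)
        stop("need at least two metastasis classes")
    if (any(sizes < 2L))
        stop("class of size 1: its training splits would lose the class; ",
             "merge or drop that class, or add samples")
    lapply(seq_len(ncol(vals)), function(f)
        runFold(vals, g, network, f, config))
}

#' Aggregate fold selections into a consensus biomarker report
#'
#' Counts, for every protein in the pool, how many folds selected it; the
#' consensus set is every protein selected in at least `min_count` folds.
#' Pooled macro metrics over the held-out predictions and the
#' selection-frequency p-value are attached.
#'
#' @param folds list of fold records from [runLoocv()].
#' @param min_count inclusive selection-count threshold, default 3.
#' @param pool character vector of all candidate proteins (the matrix's
#'   proteins); defaults to the union of fold selections.
#' @param config optional configuration list echoed into the report.
#' @return a [ConsensusReport-class] object.
#' @export
consensusFeatures <- function(folds, min_count = 3L, pool = NULL,
                              config = list()) {
    if (min_count < 1L) stop("'min_count' must be >= 1")
    sel <- lapply(folds, `[[`, "selected")
    if (is.null(pool)) pool <- sort(unique(unlist(sel)))
    counts <- stats::setNames(integer(length(pool)), pool)
    for (s in sel) {
        s <- intersect(s, pool)
        counts[s] <- counts[s] + 1L
    }
    consensus <- names(counts)[counts >= min_count]
    truth <- vapply(folds, `[[`, character(1), "true_label")
    pred <- vapply(folds, `[[`, character(1), "predicted_label")
    metrics <- pooledMacroMetrics(truth, pred)
    mean_size <- mean(lengths(sel))
    pval <- if (length(pool) > mean_size && mean_size > 0)
        selectionPvalue(length(folds), length(pool), mean_size, min_count)
    else NA_real_
    new("ConsensusReport", counts = counts, consensus = consensus,
        min_count = as.integer(min_count), metrics = metrics,
        mean_set_size = mean_size, selection_pvalue = pval,
        n_folds = length(folds), folds = folds,
        config = if (is.list(config)) unclass(config) else list())
}

#' Pooled macro precision, recall and F1
#'
#' Pools the per-fold single-sample predictions into one confusion matrix
#' and reports the unweighted mean over classes (present in the pooled
#' truth) of per-class precision, recall, and F1, with 0/0 defined as 0.
#'
#' @param true_labels,predicted_labels equal-length class vectors.
#' @return named numeric: `precision`, `recall`, `f1`.
#' @export
pooledMacroMetrics <- function(true_labels, predicted_labels) {
    if (length(true_labels) == 0L) stop("empty input")
    tl <- as.character(true_labels)
    pl <- as.character(predicted_labels)
    classes <- unique(tl)
    div0 <- function(a, b) if (b == 0) 0 else a / b
    per <- vapply(classes, function(cl) {
        tp <- sum(tl == cl & pl == cl)
        prec <- div0(tp, sum(pl == cl))
        rec <- div0(tp, sum(tl == cl))
        f1 <- div0(2 * prec * rec, prec + rec)
        c(prec, rec, f1)
    }, numeric(3))
    stats::setNames(rowMeans(per), c("precision", "recall", "f1"))
}

#' Selection-frequency p-value under a uniform-selection null
#'
#' Null model: each fold selects its feature set uniformly at random, so a
#' given protein is included in any one fold with probability
#' q = mean_set_size / pool_size independently across folds. The returned
#' value is the binomial upper tail P(X >= min_count) for
#' X ~ Binomial(n_folds, q), computed by direct summation of the pmf.
#'
#' @param n_folds number of outer folds.
#' @param pool_size number of candidate proteins.
#' @param mean_set_size mean per-fold selected-set size (may be
#'   fractional).
#' @param min_count the consensus threshold.
#' @return probability in [0, 1].
#' @export
selectionPvalue <- function(n_folds, pool_size, mean_set_size, min_count) {
    if (n_folds < 1L || min_count < 0L || min_count > n_folds)
        stop("invalid n_folds / min_count")
    if (mean_set_size <= 0 || mean_set_size >= pool_size)
        stop("'mean_set_size' must lie in (0, pool_size)")
    if (min_count == 0L) return(1)
    q <- mean_set_size / pool_size
    sum(stats::dbinom(seq.int(min_count, n_folds), n_folds, q))
}
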