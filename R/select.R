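# Standardization fitted on a training split only: per-feature z-score with
# zero-variance columns left centered (sd treated as 1).
fitStandardizer <- function(xtr) {
    mu <- colMeans(xtr)
    sd_ <- apply(xtr, 2, stats::sd)
    sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
    list(mu = mu, sd = sd_)
}

applyStandardizer <- function(std, x) {
    sweep(sweep(x, 2, std$mu, "-"), 2, std$sd, "/")
}

# RBF gamma under the "scale" policy: 1 / (n_features * mean feature
# variance of the (standardized) training matrix).
rbfGamma <- function(xtr_std) {
    v <- mean(apply(xtr_std, 2, stats::var))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(xtr_std) * v)
}

svmFit <- function(xtr_std, ytr, cost) {
    ytr <- droplevels(ytr)
    e1071::svm(x = xtr_std, y = ytr, kernel = "radial", cost = cost,
               gamma = rbfGamma(xtr_std), scale = FALSE)
}

#' Macro-averaged multiclass accuracy
#'
#' Unweighted mean over classes (those present in the truth) of the
#' per-class recall. A constant predictor on a balanced three-class problem
#' scores 1/3.
#'
#' @param true_labels,predicted_labels equal-length class vectors.
#' @return fraction in [0, 1].
#' @export
macroAccuracy <- function(true_labels, predicted_labels) {
    if (length(true_labels) == 0L) stop("empty input")
    if (length(true_labels) != length(predicted_labels))
        stop("inputs must have equal length")
    tl <- as.character(true_labels)
    pl <- as.character(predicted_labels)
    classes <- unique(tl)
    mean(vapply(classes, function(cl)
        mean(pl[tl == cl] == cl), numeric(1)))
}

#' Train an RBF-kernel SVM on selected features and predict
#'
#' Feature columns are z-scored by the training-set mean and SD and the
#' same transform is applied to the test rows; the classifier is an
#' RBF-kernel SVM (one-vs-one multiclass) with fixed cost.
#'
#' @param train_x samples x proteins training matrix.
#' @param train_labels class per training sample.
#' @param features character vector of feature (protein) ids to use.
#' @param test_x samples x proteins matrix to predict (must contain
#'   `features`).
#' @param cost SVM cost parameter C; default 1.
#' @return character vector of predicted classes, one per test row.
#' @export
fitAndPredict <- function(train_x, train_labels, features, test_x, cost = 1) {
    miss <- setdiff(features, colnames(train_x))
    if (length(miss))
        stop("feature missing from training matrix: ",
             paste(miss, collapse = ", "))
    miss <- setdiff(features, colnames(test_x))
    if (length(miss))
        stop("feature missing from test matrix: ",
             paste(miss, collapse = ", "))
    xtr <- train_x[, features, drop = FALSE]
    xte <- test_x[, features, drop = FALSE]
    y <- asGroupFactor(train_labels)
    std <- fitStandardizer(xtr)
    fit <- svmFit(applyStandardizer(std, xtr), y, cost)
    as.character(stats::predict(fit, applyStandardizer(std, xte)))
}

#' Recursive feature addition along a ranking
#'
#' Grows a feature prefix along the supplied ranking. Each prefix size is
#' scored by stratified inner k-fold cross-validation: within each split an
#' RBF-kernel SVM is fitted on the standardized training part and its macro
#' accuracy measured on the held-out part; the trace records the mean over
#' splits. Addition stops when `max_features` is reached or no prefix has
#' improved the running maximum for `patience` consecutive additions. The
#' returned prefix is the global accuracy argmax over evaluated sizes, with
#' ties resolved to the smallest prefix (parsimony).
#'
#' @param x samples x proteins matrix (or [MetastasisExperiment-class],
#'   transposed internally).
#' @param labels class per sample.
#' @param ranking a [RankedFeatures-class] object or a character vector of
#'   protein ids in priority order; must cover the matrix's proteins.
#' @param inner_k inner fold count, default 5.
#' @param max_features largest prefix size evaluated, default 30.
#' @param patience consecutive non-improving additions tolerated, default 5.
#' @param cost SVM cost parameter, default 1.
#' @param seed integer seed for the stratified fold shuffle.
#' @return an [RfaTrace-class] object.
#' @export
recursiveFeatureAddition <- function(x, labels = NULL, ranking,
                                     inner_k = 5L, max_features = 30L,
                                     patience = 5L, cost = 1, seed = 1L) {
    if (is(x, "MetastasisExperiment")) {
        if (is.null(labels)) labels <- metastasisGroup(x)
        x <- t(lfq(x))
    }
    if (inner_k < 2L) stop("'inner_k' must be >= 2")
    if (nrow(x) < inner_k) stop("fewer samples than inner_k")
    y <- asGroupFactor(labels)
    if (nlevels(y) < 2L) stop("a class is absent from the training set")
    if (length(y) != nrow(x)) stop("labels do not match samples")
    ids <- if (is(ranking, "RankedFeatures")) rankedIds(ranking) else ranking
    if (!all(colnames(x) %in% ids))
        stop("ranking does not cover the matrix's proteins")
    ids <- ids[ids %in% colnames(x)]

    # stratified fold assignment under a seeded shuffle
    fold <- integer(nrow(x))
    withSeed(seed, {
        for (cl in levels(y)) {
            ix <- which(y == cl)
            fold[ix[sample.int(length(ix))]] <-
                rep_len(seq_len(inner_k), length(ix))
        }
    })

    # per-fold standardization of the full matrix, reused across prefixes
    splits <- lapply(seq_len(inner_k), function(f) {
        tr <- fold != f
        std <- fitStandardizer(x[tr, , drop = FALSE])
        list(xtr = applyStandardizer(std, x[tr, , drop = FALSE]),
             xte = applyStandardizer(std, x[!tr, , drop = FALSE]),
             ytr = y[tr], yte = y[!tr])
    })
    splits <- Filter(function(s) length(s$yte) > 0, splits)

    limit <- min(max_features, length(ids))
    acc <- numeric(0)
    best_acc <- -Inf
    best_size <- 0L
    for (s in seq_len(limit)) {
        feats <- ids[seq_len(s)]
        a <- vapply(splits, function(sp) {
            fit <- svmFit(sp$xtr[, feats, drop = FALSE], sp$ytr, cost)
            pred <- stats::predict(fit, sp$xte[, feats, drop = FALSE])
            macroAccuracy(as.character(sp$yte), as.character(pred))
        }, numeric(1))
        acc[s] <- mean(a)
        if (acc[s] > best_acc + 1e-12) {
            best_acc <- acc[s]
            best_size <- s
        }
        if (s - best_size >= patience) break
    }
    new("RfaTrace", sizes = seq_along(acc), accuracy = acc,
        chosen = ids[seq_len(best_size)], inner_k = as.integer(inner_k),
        params = list(cost = cost, gamma = "scale", standardize = TRUE,
                      patience = as.integer(patience),
                      max_features = as.integer(max_features),
                      seed = as.integer(seed)))
}
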