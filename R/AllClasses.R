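#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

METASTASIS_LEVELS <- c("NM", "LM", "M")

#' Container for a labelled LFQ proteomics cohort
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"lfq"` assay of log2 label-free quantification intensities with
#' proteins as rows and samples as columns, plus a `group` column in
#' `colData` giving each sample's metastasis class (`NM`, no metastasis;
#' `LM`, late metastasis; `M`, early metastasis). Missing intensities are
#' encoded as `NA` in the assay.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @exportClass MetastasisExperiment
setClass("MetastasisExperiment", contains = "SummarizedExperiment")

setValidity("MetastasisExperiment", function(object) {
    msg <- character()
    if (!"lfq" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'lfq' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd)) {
        msg <- c(msg, "colData column 'group' is required")
    } else {
        g <- cd$group
        if (!is.factor(g) || !all(levels(g) %in% METASTASIS_LEVELS))
            msg <- c(msg, "'group' must be a factor with levels among NM, LM, M")
        if (anyNA(g))
            msg <- c(msg, "'group' contains NA")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate protein identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    if ("lfq" %in% SummarizedExperiment::assayNames(object)) {
        v <- SummarizedExperiment::assay(object, "lfq")
        if (any(is.infinite(v)))
            msg <- c(msg, "non-missing values must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MetastasisExperiment
#'
#' @param values numeric matrix of log2 LFQ intensities, proteins as rows and
#'   samples as columns, with complete dimnames; `NA` marks a missing value.
#' @param labels metastasis class per sample, a character or factor of the
#'   same length as `ncol(values)` with values in `NM`, `LM`, `M`. If named,
#'   names must match the sample (column) names and are used for alignment.
#' @return A [MetastasisExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12, 28), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' me <- MetastasisExperiment(m, c("NM", "NM", "LM", "M"))
#' metastasisGroup(me)
#' @export
MetastasisExperiment <- function(values, labels) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix (proteins x samples)")
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have protein rownames and sample colnames")
    if (!is.null(names(labels))) {
        if (!setequal(names(labels), colnames(values)))
            stop("label names do not match sample identifiers")
        labels <- labels[colnames(values)]
    }
    if (length(labels) != ncol(values))
        stop("'labels' must have one entry per sample")
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), METASTASIS_LEVELS)
    if (length(bad))
        stop("unknown metastasis class: ", paste(bad, collapse = ", "))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(lfq = values),
        colData = DataFrame(group = factor(labels, levels = METASTASIS_LEVELS),
                            row.names = colnames(values)))
    new("MetastasisExperiment", se)
}

#' Ranked protein features
#'
#' Total order over proteins produced by [rankFeatures()]: descending
#' averaged mutual information, with network-propagation scores breaking
#' MI ties and the protein identifier as a final deterministic tie-break.
#' Both score vectors and their 1-based average ranks are retained.
#'
#' @slot table data.frame with columns `protein_id`, `mi_score`, `np_score`,
#'   `mi_rank`, `np_rank`, `final_rank`, rows in final rank order.
#' @slot tie_epsilon numeric, the MI tie tolerance used.
#' @exportClass RankedFeatures
setClass("RankedFeatures",
         representation(table = "data.frame", tie_epsilon = "numeric"))

setValidity("RankedFeatures", function(object) {
    need <- c("protein_id", "mi_score", "np_score", "mi_rank", "np_rank",
              "final_rank")
    if (!all(need %in% colnames(object@table)))
        return("table lacks required columns")
    if (anyDuplicated(object@table$protein_id))
        return("duplicate protein identifiers in ranking")
    if (!identical(object@table$final_rank, seq_len(nrow(object@table))))
        return("rows must be ordered by final_rank 1..n")
    TRUE
})

#' Recursive-feature-addition trace
#'
#' Record of one recursive feature addition run: the inner-CV macro accuracy
#' observed at each candidate prefix size and the accuracy-maximizing prefix
#' (smallest size on ties).
#'
#' @slot sizes integer vector of evaluated prefix sizes (1, 2, ...).
#' @slot accuracy mean inner-CV macro accuracy at each size.
#' @slot chosen character vector, the selected feature prefix.
#' @slot inner_k integer, inner cross-validation fold count.
#' @slot params list echoing classifier settings (cost, gamma policy,
#'   standardization, patience, max_features, seed).
#' @exportClass RfaTrace
setClass("RfaTrace",
         representation(sizes = "integer", accuracy = "numeric",
                        chosen = "character", inner_k = "integer",
                        params = "list"))

setValidity("RfaTrace", function(object) {
    if (length(object@sizes) != length(object@accuracy))
        return("sizes and accuracy lengths differ")
    if (!length(object@chosen))
        return("chosen prefix is empty")
    k <- length(object@chosen)
    best <- max(object@accuracy)
    if (abs(object@accuracy[k] - best) > 1e-12)
        return("chosen prefix accuracy is not the trace maximum")
    TRUE
})

#' Consensus biomarker report
#'
#' Aggregate of an outer leave-one-out run: per-protein selection counts
#' across folds, the consensus set at the selection-count threshold, pooled
#' macro classification metrics over the held-out predictions, and the
#' selection-frequency p-value under a uniform-random-selection null.
#'
#' @slot counts named integer vector, selection count per protein (full pool).
#' @slot consensus character vector, proteins with count >= min_count.
#' @slot min_count integer threshold ("selected in at least min_count folds").
#' @slot metrics named numeric: pooled macro `precision`, `recall`, `f1`.
#' @slot mean_set_size mean per-fold selected-set size.
#' @slot selection_pvalue binomial-tail p-value for reaching min_count.
#' @slot n_folds number of outer folds.
#' @slot folds list of per-fold records (see [runLoocv()]).
#' @slot config list echoing the run configuration.
#' @exportClass ConsensusReport
setClass("ConsensusReport",
         representation(counts = "integer", consensus = "character",
                        min_count = "integer", metrics = "numeric",
                        mean_set_size = "numeric",
                        selection_pvalue = "numeric", n_folds = "integer",
                        folds = "list", config = "list"))

setValidity("ConsensusReport", function(object) {
    if (is.null(names(object@counts)))
        return("counts must be named by protein")
    if (any(object@counts < 0L) || any(object@counts > object@n_folds))
        return("counts must lie in [0, n_folds]")
    if (!setequal(object@consensus,
                  names(object@counts)[object@counts >= object@min_count]))
        return("consensus set inconsistent with counts and min_count")
    if (!all(names(object@metrics) %in% c("precision", "recall", "f1")))
        return("metrics must be precision/recall/f1")
    if (any(object@metrics < 0 | object@metrics > 1))
        return("metrics must lie in [0, 1]")
    TRUE
})
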