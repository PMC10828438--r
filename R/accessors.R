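#' @describeIn MetastasisExperiment the log2 LFQ matrix (proteins x samples).
#' @export
setMethod("lfq", "MetastasisExperiment", function(x)
    SummarizedExperiment::assay(x, "lfq"))

#' @describeIn MetastasisExperiment per-sample metastasis class factor.
#' @export
setMethod("metastasisGroup", "MetastasisExperiment", function(x)
    SummarizedExperiment::colData(x)$group)

#' @describeIn MetastasisExperiment logical matrix, TRUE where missing.
#' @export
setMethod("missingMask", "MetastasisExperiment", function(x)
    is.na(SummarizedExperiment::assay(x, "lfq")))

setMethod("show", "MetastasisExperiment", function(object) {
    cat("MetastasisExperiment:", nrow(object), "proteins x",
        ncol(object), "samples\n")
    print(table(metastasisGroup(object)))
    miss <- mean(missingMask(object))
    cat(sprintf("missing: %.1f%%\n", 100 * miss))
})

#' @describeIn RankedFeatures-class protein ids in final rank order.
#' @export
setMethod("rankedIds", "RankedFeatures", function(x) x@table$protein_id)

#' @describeIn RankedFeatures-class full score/rank table, rank order.
#' @export
setMethod("featureScores", "RankedFeatures", function(x) x@table)

setMethod("show", "RankedFeatures", function(object) {
    cat("RankedFeatures:", nrow(object@table), "proteins",
        sprintf("(tie_epsilon = %g)\n", object@tie_epsilon))
    print(utils::head(object@table, 5))
    if (nrow(object@table) > 5) cat("...\n")
})

#' @describeIn RfaTrace-class the selected feature prefix.
#' @export
setMethod("chosenFeatures", "RfaTrace", function(x) x@chosen)

#' @describeIn RfaTrace-class named accuracy vector over prefix sizes.
#' @export
setMethod("accuracyTrace", "RfaTrace", function(x)
    stats::setNames(x@accuracy, x@sizes))

setMethod("show", "RfaTrace", function(object) {
    cat("RfaTrace:", length(object@sizes), "prefix sizes evaluated,",
        "chosen size", length(object@chosen),
        sprintf("(accuracy %.3f)\n", max(object@accuracy)))
})

#' @describeIn ConsensusReport-class selection count per protein.
#' @export
setMethod("selectionCounts", "ConsensusReport", function(x) x@counts)

#' @describeIn ConsensusReport-class the consensus biomarker set.
#' @export
setMethod("consensusSet", "ConsensusReport", function(x) x@consensus)

#' @describeIn ConsensusReport-class pooled macro precision/recall/F1.
#' @export
setMethod("pooledMetrics", "ConsensusReport", function(x) x@metrics)

#' @describeIn ConsensusReport-class list of per-fold records.
#' @export
setMethod("foldResults", "ConsensusReport", function(x) x@folds)

setMethod("show", "ConsensusReport", function(object) {
    cat("ConsensusReport:", object@n_folds, "leave-one-out folds over",
        length(object@counts), "proteins\n")
    cat("consensus set (count >=", object@min_count, "):",
        length(object@consensus), "proteins\n")
    if (length(object@consensus))
        cat(" ", paste(utils::head(object@consensus, 10), collapse = ", "),
            if (length(object@consensus) > 10) "..." else "", "\n")
    m <- object@metrics
    cat(sprintf("pooled macro precision %.3f, recall %.3f, F1 %.3f\n",
                m["precision"], m["recall"], m["f1"]))
    cat(sprintf("mean selected-set size %.2f; selection p-value %.3g\n",
                object@mean_set_size, object@selection_pvalue))
})
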