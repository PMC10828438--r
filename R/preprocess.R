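#' Filter proteins by completeness
#'
#' Retains exactly the proteins whose fraction of missing values is at most
#' `max_missing_fraction`; samples and protein order are unchanged.
#'
#' @param x a [MetastasisExperiment-class] (or proteins x samples matrix).
#' @param max_missing_fraction maximum tolerated missing fraction per
#'   protein, in [0, 1).
#' @return object of the same class with the failing proteins removed.
#' @export
filterByCompleteness <- function(x, max_missing_fraction = 0.3) {
    if (max_missing_fraction < 0 || max_missing_fraction >= 1)
        stop("'max_missing_fraction' must lie in [0, 1)")
    vals <- asProteinMatrix(x)
    frac <- rowMeans(is.na(vals))
    keep <- frac <= max_missing_fraction
    if (!any(keep))
        stop("empty matrix after filtering: no protein passes ",
             "max_missing_fraction = ", max_missing_fraction)
    if (is(x, "MetastasisExperiment")) x[keep, ] else vals[keep, , drop = FALSE]
}

#' k-nearest-neighbor imputation of missing intensities
#'
#' Neighbors are proteins. The distance between two proteins is the
#' root-mean-square difference over the samples in which both are observed
#' (Euclidean distance scaled by the number of shared coordinates), so
#' proteins with different missingness patterns remain comparable. A missing
#' entry (protein p, sample s) is replaced by the unweighted mean of the
#' values at s of the k nearest proteins that are observed at s. A protein
#' with no scorable neighbor falls back to its own observed mean, with a
#' warning. Observed values are never changed.
#'
#' @param x a [MetastasisExperiment-class] (or proteins x samples matrix)
#'   in which every protein has at least one observed value.
#' @param k number of neighbor proteins, >= 1.
#' @return the input with all missing entries imputed.
#' @export
knnImpute <- function(x, k = 10L) {
    if (k < 1L) stop("'k' must be >= 1")
    vals <- asProteinMatrix(x)
    miss <- is.na(vals)
    if (!any(miss)) return(x)
    if (any(rowSums(!miss) == 0L))
        stop("protein with no observed value; filter before imputing")

    obs <- !miss
    x0 <- vals
    x0[miss] <- 0
    # NA-aware squared distances via cross products:
    # d2(p,q) = [sum_shared xp^2 + sum_shared xq^2 - 2 sum_shared xp*xq] / n_shared
    om <- obs * 1
    n_shared <- om %*% t(om)
    sq <- (x0 * x0) %*% t(om)
    cross <- x0 %*% t(x0)
    d2 <- sq + t(sq) - 2 * cross
    d2 <- pmax(d2, 0) / ifelse(n_shared > 0, n_shared, NA)
    d2[n_shared == 0] <- Inf
    diag(d2) <- Inf

    out <- vals
    fallback <- character()
    need <- which(rowSums(miss) > 0L)
    for (p in need) {
        ord <- order(d2[p, ], seq_len(nrow(vals)))
        ord <- ord[is.finite(d2[p, ord])]
        for (s in which(miss[p, ])) {
            cand <- ord[obs[ord, s]]
            if (length(cand) == 0L) {
                out[p, s] <- mean(vals[p, obs[p, ]])
                fallback <- c(fallback, rownames(vals)[p])
            } else {
                nb <- cand[seq_len(min(k, length(cand)))]
                out[p, s] <- mean(vals[nb, s])
            }
        }
    }
    if (length(fallback))
        warning("no scorable neighbor for ",
                paste(unique(fallback), collapse = ", "),
                "; fell back to the protein's own observed mean")
    if (is(x, "MetastasisExperiment")) {
        SummarizedExperiment::assay(x, "lfq") <- out
        x
    } else out
}
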