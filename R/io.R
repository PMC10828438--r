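#' Read a protein abundance matrix
#'
#' Two TSV dialects are supported. `plain`: rows are samples, first column
#' `sample_id`, remaining columns are proteins; empty fields or `NA` mark
#' missing values. `proteingroups`: a minimal MaxQuant proteinGroups-style
#' table with rows as proteins, a `Majority protein IDs` column, and one
#' `LFQ intensity <sample>` column per sample; zeros mark missing values
#' (the MaxQuant convention). Both are normalized to the internal proteins
#' x samples orientation.
#'
#' @param path TSV file path.
#' @param dialect `"plain"` or `"proteingroups"`.
#' @return numeric matrix, proteins x samples, `NA` for missing.
#' @export
readAbundanceMatrix <- function(path, dialect = c("plain", "proteingroups")) {
    dialect <- match.arg(dialect)
    df <- utils::read.delim(path, check.names = FALSE,
                            na.strings = c("NA", ""), strip.white = TRUE,
                            stringsAsFactors = FALSE)
    if (dialect == "plain") {
        if (colnames(df)[1] != "sample_id")
            stop("plain dialect requires a first column 'sample_id'")
        ids <- as.character(df$sample_id)
        if (anyDuplicated(ids))
            stop("duplicate sample id at line ",
                 which(duplicated(ids))[1] + 1L)
        if (anyDuplicated(colnames(df)[-1]))
            stop("duplicate protein id in header")
        vals <- t(data.matrix(df[, -1, drop = FALSE]))
        colnames(vals) <- ids
    } else {
        idcol <- "Majority protein IDs"
        if (!idcol %in% colnames(df))
            stop("proteingroups dialect requires a '", idcol, "' column")
        lfq_cols <- grep("^LFQ intensity ", colnames(df), value = TRUE)
        if (!length(lfq_cols))
            stop("no 'LFQ intensity <sample>' columns found")
        ids <- as.character(df[[idcol]])
        if (anyDuplicated(ids))
            stop("duplicate protein id at line ",
                 which(duplicated(ids))[1] + 1L)
        vals <- data.matrix(df[, lfq_cols, drop = FALSE])
        rownames(vals) <- ids
        colnames(vals) <- sub("^LFQ intensity ", "", lfq_cols)
        vals[vals == 0] <- NA_real_
    }
    storage.mode(vals) <- "double"
    vals
}

#' Read a sample-label table
#'
#' @param path TSV with columns `sample_id` and `label` (NM, LM or M).
#' @return named character vector of labels, named by sample id.
#' @export
readSampleLabels <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "label") %in% colnames(df)))
        stop("labels file must have columns 'sample_id' and 'label'")
    bad <- setdiff(unique(df$label), METASTASIS_LEVELS)
    if (length(bad))
        stop("unknown label: ", paste(bad, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample id in labels file")
    stats::setNames(as.character(df$label), as.character(df$sample_id))
}

#' Read a STRING-style interaction edge list
#'
#' Expects columns `protein1`, `protein2`, `combined_score` with integer
#' scores on the 0-1000 scale; confidences are `combined_score / 1000`.
#' Duplicate undirected edges are collapsed keeping the maximum confidence;
#' self-loops are dropped with a warning.
#'
#' @param path TSV file path.
#' @param vertices optional character vector of node ids to include even
#'   when they have no edge.
#' @return undirected igraph with edge attribute `confidence`.
#' @export
readInteractionNetwork <- function(path, vertices = NULL) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein1", "protein2", "combined_score")
    if (!all(need %in% colnames(df)))
        stop("network file must have columns ", paste(need, collapse = ", "))
    if (nrow(df)) {
        if (any(df$combined_score < 0 | df$combined_score > 1000))
            stop("combined_score outside 0-1000 at line ",
                 which(df$combined_score < 0 | df$combined_score > 1000)[1] + 1L)
        loops <- df$protein1 == df$protein2
        if (any(loops)) {
            warning(sum(loops), " self-loop(s) dropped")
            df <- df[!loops, , drop = FALSE]
        }
    }
    if (nrow(df)) {
        a <- pmin(df$protein1, df$protein2)
        b <- pmax(df$protein1, df$protein2)
        conf <- df$combined_score / 1000
        keyord <- order(paste(a, b), -conf)
        a <- a[keyord]; b <- b[keyord]; conf <- conf[keyord]
        keep <- !duplicated(paste(a, b))
        edges <- data.frame(from = a[keep], to = b[keep],
                            confidence = conf[keep],
                            stringsAsFactors = FALSE)
    } else {
        edges <- data.frame(from = character(), to = character(),
                            confidence = numeric())
    }
    verts <- unique(c(edges$from, edges$to, vertices))
    igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = data.frame(name = verts, stringsAsFactors = FALSE))
}

#' Full pipeline configuration
#'
#' Extends [loocvConfig()] with the preprocessing tunables and the input
#' dialect. Every value is echoed into the written reports.
#'
#' @param max_missing_fraction completeness threshold, see
#'   [filterByCompleteness()].
#' @param knn_k imputation neighbor count, see [knnImpute()].
#' @param dialect abundance-matrix dialect for [readAbundanceMatrix()].
#' @param log2_transform set `TRUE` when the input matrix holds raw
#'   intensities: zeros become missing, then values are log2-transformed.
#' @param ... passed to [loocvConfig()].
#' @return a list of class `PipelineConfig` containing a `LoocvConfig`.
#' @export
pipelineConfig <- function(max_missing_fraction = 0.3, knn_k = 10L,
                           dialect = c("plain", "proteingroups"),
                           log2_transform = FALSE, ...) {
    dialect <- match.arg(dialect)
    cfg <- list(max_missing_fraction = max_missing_fraction,
                knn_k = as.integer(knn_k), dialect = dialect,
                log2_transform = isTRUE(log2_transform),
                loocv = loocvConfig(...))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the complete biomarker-discovery pipeline
#'
#' Reads the abundance matrix, labels and network (file paths or in-memory
#' objects), applies completeness filtering and kNN imputation, runs the
#' outer leave-one-out consensus loop, and optionally writes the report
#' artifacts (`consensus.tsv`, `metrics.json`, `fold_results.json`).
#'
#' @param matrix path to the abundance TSV, or a proteins x samples matrix.
#' @param labels path to the labels TSV, or a named label vector.
#' @param network path to the edge-list TSV, or an igraph.
#' @param config a [pipelineConfig()] object.
#' @param output_dir directory for report files; `NULL` skips writing.
#' @return a [ConsensusReport-class] object (invisibly when writing files).
#' @export
runPipeline <- function(matrix, labels, network,
                        config = pipelineConfig(), output_dir = NULL) {
    if (!inherits(config, "PipelineConfig"))
        stop("'config' must come from pipelineConfig()")
    if (is.character(matrix))
        matrix <- readAbundanceMatrix(matrix, config$dialect)
    if (is.character(labels)) labels <- readSampleLabels(labels)
    if (is.character(network)) network <- readInteractionNetwork(network)
    if (config$log2_transform) {
        matrix[matrix == 0] <- NA_real_
        matrix <- log2(matrix)
    }
    x <- MetastasisExperiment(matrix, labels)
    n0 <- nrow(x)
    x <- filterByCompleteness(x, config$max_missing_fraction)
    message("completeness filter: ", n0, " -> ", nrow(x), " proteins")
    x <- knnImpute(x, config$knn_k)
    folds <- runLoocv(x, network, config$loocv)
    report <- consensusFeatures(folds, min_count = config$loocv$min_count,
                                pool = rownames(x),
                                config = c(unclass(config)[
                                    c("max_missing_fraction", "knn_k",
                                      "dialect", "log2_transform")],
                                    unclass(config$loocv)))
    if (!is.null(output_dir)) {
        writeConsensusReport(report, output_dir)
        return(invisible(report))
    }
    report
}

#' Write the consensus report artifacts
#'
#' Emits `consensus.tsv` (protein_id, selection_count, in_consensus, sorted
#' by count then id), `metrics.json` (pooled macro metrics, mean set size,
#' selection p-value, config echo) and `fold_results.json` (per-fold
#' held-out sample, truth, prediction, selected set and accuracy trace).
#' Output is byte-identical across runs with the same configuration and
#' master seed.
#'
#' @param report a [ConsensusReport-class] object.
#' @param dir output directory (created if absent).
#' @return named character vector of written paths.
#' @export
writeConsensusReport <- function(report, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(consensus = file.path(dir, "consensus.tsv"),
               metrics = file.path(dir, "metrics.json"),
               folds = file.path(dir, "fold_results.json"))
    counts <- selectionCounts(report)
    ord <- order(-counts, names(counts))
    utils::write.table(
        data.frame(protein_id = names(counts)[ord],
                   selection_count = as.integer(counts[ord]),
                   in_consensus = names(counts)[ord] %in%
                       consensusSet(report)),
        paths["consensus"], sep = "\t", quote = FALSE, row.names = FALSE)
    metrics <- list(
        pooled_macro = as.list(pooledMetrics(report)),
        mean_set_size = report@mean_set_size,
        selection_pvalue = report@selection_pvalue,
        n_folds = report@n_folds,
        min_count = report@min_count,
        consensus_size = length(consensusSet(report)),
        config = report@config)
    jsonlite::write_json(metrics, paths["metrics"], auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    folds <- lapply(foldResults(report), function(f)
        list(sample_id = f$sample_id, true_label = f$true_label,
             predicted_label = f$predicted_label, selected = f$selected,
             n_seeds = f$n_seeds, seed = f$seed,
             trace_sizes = f$trace@sizes,
             trace_accuracy = round(f$trace@accuracy, 10)))
    jsonlite::write_json(folds, paths["folds"], auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    paths
}
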