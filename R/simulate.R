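#' Configuration for synthetic-cohort simulation
#'
#' Defaults mirror the discovery-cohort geometry the pipeline targets: 29
#' samples in three metastasis classes (10 NM, 9 LM, 10 M), ~2000 proteins
#' on the log2 LFQ scale (baseline around 28.5), and a small set of planted
#' markers whose class means decrease by `effect_step` per step along
#' NM -> LM -> M, the monotone pattern a genuine metastasis marker shows.
#'
#' @param n_per_class integer(3), samples per class for (NM, LM, M).
#' @param n_proteins total number of protein features.
#' @param n_planted number of planted marker proteins.
#' @param baseline_mean baseline log2 LFQ mean across proteins.
#' @param baseline_sd_between_proteins SD of per-protein baseline means.
#' @param within_group_sd within-class SD of a protein's values (log2 units).
#' @param effect_step log2 decrease per class step for planted proteins.
#' @param missing_rate fraction of entries masked missing, in [0, 1).
#' @param missing_mode `"MCAR"` (uniform) or `"left_censored"` (mask the
#'   lowest `missing_rate` quantile of the matrix, mimicking intensity-
#'   dependent dropout).
#' @param network_background_edges_per_node preferential-attachment edges
#'   added per node in the background interaction network.
#' @param planted_module_confidence edge confidence within the planted
#'   module, in [0, 1].
#' @param rng_seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_per_class = c(10L, 9L, 10L),
                             n_proteins = 2000L,
                             n_planted = 9L,
                             baseline_mean = 28.5,
                             baseline_sd_between_proteins = 1.0,
                             within_group_sd = 0.5,
                             effect_step = 0.7,
                             missing_rate = 0.05,
                             missing_mode = c("MCAR", "left_censored"),
                             network_background_edges_per_node = 3L,
                             planted_module_confidence = 0.9,
                             rng_seed = 1L) {
    missing_mode <- match.arg(missing_mode)
    cfg <- list(n_per_class = as.integer(n_per_class),
                n_proteins = as.integer(n_proteins),
                n_planted = as.integer(n_planted),
                baseline_mean = baseline_mean,
                baseline_sd_between_proteins = baseline_sd_between_proteins,
                within_group_sd = within_group_sd,
                effect_step = effect_step,
                missing_rate = missing_rate,
                missing_mode = missing_mode,
                network_background_edges_per_node =
                    as.integer(network_background_edges_per_node),
                planted_module_confidence = planted_module_confidence,
                rng_seed = as.integer(rng_seed))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

validateSimulationConfig <- function(cfg) {
    chk <- function(ok, field, why)
        if (!ok) stop("invalid simulation config: '", field, "' ", why,
                      call. = FALSE)
    chk(length(cfg$n_per_class) == 3L && all(cfg$n_per_class >= 1L),
        "n_per_class", "must give three positive class sizes")
    chk(cfg$n_proteins >= 1L, "n_proteins", "must be positive")
    chk(cfg$n_planted >= 0L && cfg$n_planted <= cfg$n_proteins,
        "n_planted", "must lie in [0, n_proteins]")
    chk(cfg$baseline_sd_between_proteins >= 0,
        "baseline_sd_between_proteins", "must be >= 0")
    chk(cfg$within_group_sd >= 0, "within_group_sd", "must be >= 0")
    chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
        "missing_rate", "must lie in [0, 1)")
    chk(cfg$network_background_edges_per_node >= 1L,
        "network_background_edges_per_node", "must be >= 1")
    chk(cfg$planted_module_confidence >= 0 &&
        cfg$planted_module_confidence <= 1,
        "planted_module_confidence", "must lie in [0, 1]")
    invisible(cfg)
}

#' Simulate a labelled proteomics cohort with planted markers
#'
#' Non-planted proteins share one class-independent mean (drawn per protein
#' around the baseline); planted proteins have class means
#' (mu, mu - effect_step, mu - 2 effect_step) for (NM, LM, M). Values are
#' Gaussian around the class mean with `within_group_sd`, then masked
#' missing according to `missing_mode`.
#'
#' @param config a [simulationConfig()] object.
#' @return list with elements `experiment` (a
#'   [MetastasisExperiment-class]) and `truth` (list with `planted_ids` and
#'   the planted `class_means` matrix, proteins x classes).
#' @examples
#' sim <- simulateCohort(simulationConfig(n_proteins = 50, rng_seed = 7))
#' sim$truth$planted_ids
#' @export
simulateCohort <- function(config = simulationConfig()) {
    validateSimulationConfig(config)
    n_s <- sum(config$n_per_class)
    n_p <- config$n_proteins
    protein_ids <- sprintf("PROT%05d", seq_len(n_p))
    labels <- rep(METASTASIS_LEVELS, times = config$n_per_class)
    sample_ids <- sprintf("%s_%02d", labels,
                          unlist(lapply(config$n_per_class, seq_len)))
    withSeed(config$rng_seed, {
        planted <- sort(sample(protein_ids, config$n_planted))
        mu <- stats::rnorm(n_p, config$baseline_mean,
                           config$baseline_sd_between_proteins)
        names(mu) <- protein_ids
        # class means: proteins x 3; planted decrease by effect_step per step
        steps <- stats::setNames(0:2, METASTASIS_LEVELS)
        class_means <- outer(mu, rep(1, 3))
        colnames(class_means) <- METASTASIS_LEVELS
        class_means[planted, ] <- class_means[planted, , drop = FALSE] -
            outer(rep(1, length(planted)), steps * config$effect_step)
        vals <- class_means[, labels, drop = FALSE] +
            matrix(stats::rnorm(n_p * n_s, 0, config$within_group_sd),
                   n_p, n_s)
        dimnames(vals) <- list(protein_ids, sample_ids)
        if (config$missing_rate > 0) {
            if (config$missing_mode == "MCAR") {
                mask <- matrix(stats::runif(n_p * n_s) < config$missing_rate,
                               n_p, n_s)
            } else {
                thr <- stats::quantile(vals, config$missing_rate,
                                       names = FALSE)
                mask <- vals < thr
            }
            vals[mask] <- NA_real_
        }
    })
    truth <- list(planted_ids = planted,
                  class_means = class_means[planted, , drop = FALSE])
    list(experiment = MetastasisExperiment(vals, labels), truth = truth)
}

#' Simulate a protein-protein interaction network with a planted module
#'
#' Background edges follow a preferential-attachment model (fixed number of
#' edges per incoming node) so the degree distribution is right-skewed as in
#' real interactomes; background confidences are uniform on [0, 1]. Planted
#' proteins are wired into a connected module (a random recursive tree)
#' whose edges all carry `planted_module_confidence`, so they survive the
#' downstream confidence filter together.
#'
#' @param config a [simulationConfig()] object.
#' @param truth the `truth` element returned by [simulateCohort()].
#' @param proteins character vector of all protein identifiers.
#' @return an undirected [igraph::igraph] with an edge attribute
#'   `confidence` in [0, 1]; no self-loops, no duplicate edges.
#' @export
simulateNetwork <- function(config, truth, proteins) {
    validateSimulationConfig(config)
    planted <- truth$planted_ids
    if (!all(planted %in% proteins))
        stop("planted protein not present in the protein list")
    withSeed(config$rng_seed + 1L, {
        g <- igraph::sample_pa(length(proteins),
                               m = config$network_background_edges_per_node,
                               directed = FALSE)
        igraph::V(g)$name <- proteins
        g <- igraph::simplify(g)
        ef <- igraph::as_edgelist(g)
        conf <- stats::runif(nrow(ef))
        edges <- data.frame(from = ef[, 1], to = ef[, 2],
                            confidence = conf,
                            stringsAsFactors = FALSE)
        if (length(planted) >= 2L) {
            ord <- sample(planted)
            parent <- vapply(seq_along(ord)[-1], function(i)
                ord[sample.int(i - 1L, 1L)], character(1))
            mod <- data.frame(from = ord[-1], to = parent,
                              confidence = config$planted_module_confidence,
                              stringsAsFactors = FALSE)
            edges <- rbind(edges, mod)
        }
    })
    # canonical undirected key; planted-module confidence wins on overlap
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    keep <- !duplicated(key, fromLast = TRUE)  # module rows appended last
    edges <- edges[keep, , drop = FALSE]
    # every edge inside the planted module carries the module confidence
    inside <- edges$from %in% planted & edges$to %in% planted
    edges$confidence[inside] <- config$planted_module_confidence
    out <- igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = data.frame(name = proteins, stringsAsFactors = FALSE))
    out
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Emits the abundance matrix in both supported dialects (plain
#' samples-by-proteins TSV and a minimal MaxQuant proteinGroups-style TSV),
#' the sample-label TSV, and a STRING-style edge list with confidences
#' rescaled to integer 0-1000 `combined_score`s. Files round-trip through
#' [readAbundanceMatrix()], [readSampleLabels()] and
#' [readInteractionNetwork()].
#'
#' @param experiment a [MetastasisExperiment-class].
#' @param network an igraph with a `confidence` edge attribute.
#' @param dir output directory (created if absent).
#' @return named character vector of the written file paths.
#' @export
writeFixture <- function(experiment, network, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    vals <- lfq(experiment)
    paths <- c(plain = file.path(dir, "abundance_plain.tsv"),
               proteingroups = file.path(dir, "proteinGroups.tsv"),
               labels = file.path(dir, "labels.tsv"),
               network = file.path(dir, "network.tsv"))

    plain <- t(vals)  # samples x proteins
    df <- data.frame(sample_id = rownames(plain), formatNum(plain),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, paths["plain"], sep = "\t", quote = FALSE,
                       row.names = FALSE)

    # proteinGroups dialect: rows = proteins, zeros encode missing values
    pg_vals <- vals
    pg_vals[is.na(pg_vals)] <- 0
    pg <- data.frame(`Majority protein IDs` = rownames(vals),
                     formatNum(pg_vals),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(pg)[-1] <- paste("LFQ intensity", colnames(vals))
    utils::write.table(pg, paths["proteingroups"], sep = "\t", quote = FALSE,
                       row.names = FALSE)

    utils::write.table(
        data.frame(sample_id = colnames(vals),
                   label = as.character(metastasisGroup(experiment))),
        paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)

    if (igraph::ecount(network) > 0) {
        el <- igraph::as_edgelist(network)
        net <- data.frame(protein1 = el[, 1], protein2 = el[, 2],
                          combined_score =
                              as.integer(round(1000 *
                                  igraph::E(network)$confidence)))
    } else {
        net <- data.frame(protein1 = character(), protein2 = character(),
                          combined_score = integer())
    }
    utils::write.table(net, paths["network"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths
}
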