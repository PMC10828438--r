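# Independent oracles and small fixture builders shared across tests.

# Plug-in MI (bits) from a joint count table, summed cell by cell.
bruteMIFromTable <- function(tab) {
    n <- sum(tab)
    mi <- 0
    for (i in seq_len(nrow(tab))) {
        for (j in seq_len(ncol(tab))) {
            pij <- tab[i, j] / n
            if (pij > 0) {
                pi_ <- sum(tab[i, ]) / n
                pj_ <- sum(tab[, j]) / n
                mi <- mi + pij * log2(pij / (pi_ * pj_))
            }
        }
    }
    mi
}

# Expand a joint count table into paired category vectors.
tableToVectors <- function(tab) {
    x <- character(0); y <- character(0)
    for (i in seq_len(nrow(tab))) {
        for (j in seq_len(ncol(tab))) {
            k <- tab[i, j]
            x <- c(x, rep(paste0("x", i), k))
            y <- c(y, rep(paste0("y", j), k))
        }
    }
    list(x = x, y = y)
}

# Benjamini-Hochberg step-up, written independently of p.adjust.
bhStepUp <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
        val <- min(prev, p[o[i]] * m / i)
        adj[o[i]] <- val
        prev <- val
    }
    adj
}

# Brute-force kNN imputation mirroring the documented convention:
# protein neighbors, RMS distance over co-observed samples, unweighted mean
# of the k nearest proteins observed at the missing sample, index tie-break.
bruteKnnImpute <- function(vals, k) {
    obs <- !is.na(vals)
    out <- vals
    np <- nrow(vals)
    for (p in seq_len(np)) {
        for (s in which(!obs[p, ])) {
            d <- rep(Inf, np)
            for (q in seq_len(np)) {
                if (q == p) next
                sh <- obs[p, ] & obs[q, ]
                if (any(sh))
                    d[q] <- sqrt(mean((vals[p, sh] - vals[q, sh])^2))
            }
            cand <- which(obs[, s] & is.finite(d))
            if (!length(cand)) {
                out[p, s] <- mean(vals[p, obs[p, ]])
            } else {
                cand <- cand[order(d[cand], cand)]
                nb <- cand[seq_len(min(k, length(cand)))]
                out[p, s] <- mean(vals[nb, s])
            }
        }
    }
    out
}

# Small labelled cohort for structural tests.
smallCohort <- function(n_per_class = c(4L, 4L, 4L), n_proteins = 80L,
                        n_planted = 5L, missing_rate = 0, rng_seed = 42L,
                        ...) {
    simulateCohort(simulationConfig(
        n_per_class = n_per_class, n_proteins = n_proteins,
        n_planted = n_planted, missing_rate = missing_rate,
        rng_seed = rng_seed, ...))
}

# Random undirected network with uniform confidences over given node names.
randomConfNetwork <- function(nodes, p_edge = 0.3, seed = 1L) {
    set.seed(seed)
    g <- igraph::sample_gnp(length(nodes), p_edge, directed = FALSE)
    igraph::V(g)$name <- nodes
    if (igraph::ecount(g) > 0)
        igraph::E(g)$confidence <- stats::runif(igraph::ecount(g))
    g
}

# Shared default-cohort pipeline run used by the heavier acceptance checks.
runDefaultCohort <- function(master_seed, effect_step = 0.7) {
    cfg <- simulationConfig(rng_seed = master_seed, effect_step = effect_step)
    sim <- simulateCohort(cfg)
    net <- simulateNetwork(cfg, sim$truth, rownames(sim$experiment))
    x <- filterByCompleteness(sim$experiment, 0.3)
    x <- knnImpute(x, 10L)
    folds <- runLoocv(x, net, loocvConfig(seed = master_seed))
    report <- consensusFeatures(folds, min_count = 3L, pool = rownames(x))
    list(report = report, truth = sim$truth, experiment = x, network = net)
}
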