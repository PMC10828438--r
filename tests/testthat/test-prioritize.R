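test_that("rowwise ANOVA matches aov and handles degenerate proteins", {
    g <- factor(rep(c("NM", "LM", "M"), each = 2), levels = c("NM", "LM", "M"))

    # textbook sums of squares: groups (1,2), (3,4), (5,6) -> F = 16
    vals <- matrix(1:6, 1, dimnames = list("P1", paste0("S", 1:6)))
    p <- anovaPvalues(vals, g)
    expect_equal(unname(p), stats::pf(16, 2, 3, lower.tail = FALSE),
                 tolerance = 1e-12)

    # identical group means -> F = 0 -> p = 1
    vals2 <- matrix(c(1, 2, 1, 2, 1, 2), 1,
                    dimnames = list("P1", paste0("S", 1:6)))
    expect_equal(unname(anovaPvalues(vals2, g)), 1, tolerance = 1e-12)

    # all values identical -> degenerate convention p = 1, with warning
    vals3 <- matrix(5, 1, 6, dimnames = list("P1", paste0("S", 1:6)))
    expect_warning(p3 <- anovaPvalues(vals3, g), "all-identical")
    expect_identical(unname(p3), 1)

    # dual route: random matrix against stats::aov fold by fold
    set.seed(4)
    vals4 <- matrix(rnorm(10 * 12, 28), 10, 12,
                    dimnames = list(paste0("P", 1:10), paste0("S", 1:12)))
    g4 <- factor(rep(c("NM", "LM", "M"), each = 4),
                 levels = c("NM", "LM", "M"))
    mine <- anovaPvalues(vals4, g4)
    ref <- apply(vals4, 1, function(v)
        summary(stats::aov(v ~ g4))[[1]][["Pr(>F)"]][1])
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("BH adjustment matches an independent step-up oracle", {
    expect_identical(adjustBH(0.02), 0.02)
    expect_identical(adjustBH(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)),
                 c(0.04, 0.04, 0.04, 0.04), tolerance = 1e-15)
    expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
    set.seed(10)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        expect_equal(adjustBH(p), bhStepUp(p), tolerance = 1e-12)
    }
})

test_that("seed selection uses a strict threshold", {
    adj <- c(a = 0.05, b = 0.099, c = 0.1)
    expect_identical(selectSeeds(adj, 0.1), c("a", "b"))
    expect_identical(selectSeeds(c(a = 0.5, b = 0.5), 0.1), character(0))
})

test_that("planted proteins are ANOVA/BH seeds at the default effect size", {
    sim <- simulateCohort(simulationConfig(missing_rate = 0, rng_seed = 17L))
    adj <- adjustBH(anovaPvalues(sim$experiment))
    expect_true(all(sim$truth$planted_ids %in% selectSeeds(adj, 0.1)))
})

test_that("tercile discretization splits by the interpolated quantiles", {
    expect_identical(as.character(discretizeTerciles(c(9, 1, 5, 2, 8, 3, 7, 4, 6))[
        order(c(9, 1, 5, 2, 8, 3, 7, 4, 6))]),
        rep(c("L", "M", "H"), each = 3))
    expect_identical(as.character(discretizeTerciles(c(1, 1, 1, 2, 2, 2, 3, 3, 3))),
                     rep(c("L", "M", "H"), each = 3))
    expect_warning(d <- discretizeTerciles(rep(2, 5)), "constant")
    expect_identical(as.character(d), rep("L", 5))
    expect_equal(mutualInformation(rep(c("NM", "LM", "M"), 2)[1:5], d), 0)
})

test_that("plug-in MI matches hand cases and is symmetric and relabel-invariant", {
    x <- rep(c("NM", "LM", "M"), each = 3)
    expect_equal(mutualInformation(x, rep("L", 9)), 0)
    y <- rep(c("H", "L", "M"), each = 3)   # bijective relabeling of x
    expect_equal(mutualInformation(x, y), log2(3), tolerance = 1e-12)
    set.seed(2)
    for (i in 1:10) {
        tab <- matrix(rpois(9, 3) + 1, 3, 3)
        v <- tableToVectors(tab)
        expect_equal(mutualInformation(v$x, v$y),
                     mutualInformation(v$y, v$x), tolerance = 1e-12)
        relab <- c(x1 = "B", x2 = "C", x3 = "A")[v$x]
        expect_equal(mutualInformation(relab, v$y),
                     mutualInformation(v$x, v$y), tolerance = 1e-12)
    }
    expect_error(mutualInformation(character(0), character(0)), "empty")
})

test_that("balanced MI reduces to single-batch MI for equal class sizes", {
    sim <- smallCohort(n_per_class = c(5L, 5L, 5L), n_proteins = 30L,
                       rng_seed = 6L)
    g <- metastasisGroup(sim$experiment)
    vals <- lfq(sim$experiment)
    avg <- balancedMI(vals, g, n_batches = 25L, rng_seed = 3L)
    single <- vapply(rownames(vals), function(p)
        mutualInformation(g, discretizeTerciles(vals[p, ])), numeric(1))
    expect_equal(avg, single, tolerance = 1e-12)
})

test_that("compiled balanced MI equals the R reference on unbalanced classes", {
    sim <- smallCohort(n_per_class = c(5L, 4L, 6L), n_proteins = 25L,
                       rng_seed = 8L)
    g <- metastasisGroup(sim$experiment)
    vals <- lfq(sim$experiment)
    idx <- lfqmarker:::miBatchIndices(g, 30L, 12L)
    expect_equal(unname(lfqmarker:::cpp_balanced_mi(vals, as.integer(g), idx, 3L)),
                 unname(lfqmarker:::balancedMIReference(vals, g, idx)),
                 tolerance = 1e-12)
    # batch membership is balanced and drawn without replacement
    expect_true(all(apply(idx, 2, function(ix) {
        !anyDuplicated(ix) && all(table(g[ix]) == min(table(g)))
    })))
})

test_that("a perfectly separating protein saturates the averaged MI", {
    n <- 9
    vals <- matrix(c(rep(20, n), rep(25, n), rep(30, n)), 1,
                   dimnames = list("P1", sprintf("S%02d", 1:(3 * n))))
    g <- rep(c("NM", "LM", "M"), each = n)
    expect_equal(unname(balancedMI(vals, g, n_batches = 10L, rng_seed = 1L)),
                 log2(3), tolerance = 1e-12)
})

test_that("a null protein's balanced MI sits below its permutation null tail", {
    set.seed(31)
    vals <- matrix(rnorm(29, 28, 0.5), 1,
                   dimnames = list("P1", sprintf("S%02d", 1:29)))
    g <- rep(c("NM", "LM", "M"), times = c(10, 9, 10))
    obs <- balancedMI(vals, g, n_batches = 100L, rng_seed = 1L)
    null <- vapply(1:60, function(i) {
        unname(balancedMI(vals, sample(g), n_batches = 100L,
                          rng_seed = 1000L + i))
    }, numeric(1))
    expect_lt(unname(obs), stats::quantile(null, 0.95))
})

test_that("insulated diffusion matches closed forms and conserves heat", {
    # isolated seed keeps its unit heat
    g <- igraph::make_graph(~ B - C)
    g <- igraph::add_vertices(g, 1, name = "A")
    igraph::E(g)$confidence <- 0.9
    s <- networkPropagationScores(g, "A", beta = 0.4)
    expect_equal(unname(s[c("A", "B", "C")]), c(1, 0, 0), tolerance = 1e-12)

    # two-node path closed form at beta = 0.5
    g2 <- igraph::make_graph(~ N1 - N2)
    igraph::E(g2)$confidence <- 1
    s2 <- networkPropagationScores(g2, "N1", beta = 0.5)
    expect_equal(unname(s2[c("N1", "N2")]), c(2 / 3, 1 / 3),
                 tolerance = 1e-12)

    # beta = 1 returns the seed indicator
    s3 <- networkPropagationScores(g2, "N1", beta = 1)
    expect_equal(unname(s3[c("N1", "N2")]), c(1, 0), tolerance = 1e-12)

    # sub-threshold edges transmit no heat
    igraph::E(g2)$confidence <- 0.4
    s4 <- networkPropagationScores(g2, "N1", beta = 0.5,
                                   confidence_threshold = 0.5)
    expect_equal(unname(s4[c("N1", "N2")]), c(1, 0), tolerance = 1e-12)

    expect_error(networkPropagationScores(g2, "N1", beta = 0), "beta")
    expect_warning(s5 <- networkPropagationScores(g2, character(0)),
                   "no seed")
    expect_true(all(s5 == 0))
})

test_that("heat conservation holds on random graphs of varying size", {
    for (i in 1:12) {
        n <- sample(2:50, 1)
        net <- randomConfNetwork(sprintf("N%02d", seq_len(n)),
                                 p_edge = 0.2, seed = 100L + i)
        seeds <- sample(igraph::V(net)$name, sample.int(n, 1))
        s <- networkPropagationScores(net, seeds, beta = 0.4,
                                      confidence_threshold = 0.3)
        expect_equal(sum(s), length(seeds), tolerance = 1e-9)
        expect_true(all(s >= -1e-12))
    }
})

test_that("ranking is MI-first with NP only inside tie groups", {
    mi <- c(p1 = 0.9, p2 = 0.5, p3 = 0.5)
    np <- c(p1 = 0.1, p2 = 0.2, p3 = 0.7)
    r <- rankFeatures(mi, np, tie_epsilon = 1e-9)
    expect_identical(rankedIds(r), c("p1", "p3", "p2"))

    # strictly distinct MI: NP never consulted
    mi2 <- c(a = 0.3, b = 0.2, c = 0.1)
    r2 <- rankFeatures(mi2, c(a = 0, b = 9, c = 9))
    expect_identical(rankedIds(r2), c("a", "b", "c"))

    # all MI equal: pure NP order; residual NP ties fall back to the id
    mi3 <- c(z = 0.2, y = 0.2, x = 0.2, w = 0.2)
    r3 <- rankFeatures(mi3, c(z = 0.5, y = 0.9, x = 0.5, w = 0.1))
    expect_identical(rankedIds(r3), c("y", "x", "z", "w"))

    tab <- featureScores(r3)
    expect_equal(tab$mi_rank, rep(2.5, 4))    # average ranks for exact ties
})

test_that("the combined rank table reports 1-based positions per candidate", {
    mi <- c(a = 0.9, b = 0.8, c = 0.7, d = 0.1)
    np <- c(a = 3, b = 9, c = 1, d = 0)
    r <- rankFeatures(mi, np)
    top <- combinedRankTable(r, "a")
    expect_identical(top$mi_rank, 1)
    expect_identical(top$np_rank, 2)
    all_ranks <- combinedRankTable(r, names(mi))
    expect_setequal(all_ranks$mi_rank, 1:4)
    expect_setequal(all_ranks$np_rank, 1:4)
    expect_error(combinedRankTable(r, "nope"), "unknown candidate")
})

test_that("planted proteins outrank random background in combined rank", {
    cfg <- simulationConfig(n_proteins = 300L, missing_rate = 0,
                            rng_seed = 19L)
    sim <- simulateCohort(cfg)
    net <- simulateNetwork(cfg, sim$truth, rownames(sim$experiment))
    adj <- adjustBH(anovaPvalues(sim$experiment))
    np <- networkPropagationScores(net, selectSeeds(adj, 0.1))
    mi <- balancedMI(sim$experiment, n_batches = 50L, rng_seed = 19L)
    r <- rankFeatures(mi, np)
    planted <- combinedRankTable(r, sim$truth$planted_ids)
    set.seed(19)
    bg <- combinedRankTable(r, sample(setdiff(rownames(sim$experiment),
                                              sim$truth$planted_ids), 9))
    expect_lt(median(planted$mi_rank + planted$np_rank),
              median(bg$mi_rank + bg$np_rank))
})
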