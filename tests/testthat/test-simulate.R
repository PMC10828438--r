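test_that("cohort simulation is deterministic under a fixed seed", {
    cfg <- simulationConfig(n_proteins = 120L, rng_seed = 5L)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(lfq(a$experiment), lfq(b$experiment))
    expect_identical(a$truth, b$truth)
    na <- simulateNetwork(cfg, a$truth, rownames(a$experiment))
    nb <- simulateNetwork(cfg, b$truth, rownames(b$experiment))
    expect_identical(igraph::as_edgelist(na), igraph::as_edgelist(nb))
    expect_identical(igraph::E(na)$confidence, igraph::E(nb)$confidence)
})

test_that("invalid configurations are rejected naming the offending field", {
    expect_error(simulationConfig(missing_rate = 1), "missing_rate")
    expect_error(simulationConfig(n_planted = 10, n_proteins = 5),
                 "n_planted")
    expect_error(simulationConfig(within_group_sd = -1), "within_group_sd")
    expect_error(simulationConfig(planted_module_confidence = 1.5),
                 "planted_module_confidence")
})

test_that("planted proteins track their configured class means", {
    sim <- simulateCohort(simulationConfig(rng_seed = 21L))
    g <- metastasisGroup(sim$experiment)
    vals <- lfq(sim$experiment)
    sizes <- table(g)
    for (pid in sim$truth$planted_ids) {
        for (cl in levels(g)) {
            emp <- mean(vals[pid, g == cl], na.rm = TRUE)
            bound <- 3 * 0.5 / sqrt(sizes[[cl]])
            expect_lt(abs(emp - sim$truth$class_means[pid, cl]), bound)
        }
    }
    # the planted signature: monotone decrease NM > LM > M (near-exact at
    # small within-class noise)
    quiet <- simulateCohort(simulationConfig(within_group_sd = 0.05,
                                             missing_rate = 0,
                                             rng_seed = 21L))
    vq <- lfq(quiet$experiment)
    gq <- metastasisGroup(quiet$experiment)
    for (pid in quiet$truth$planted_ids) {
        m <- tapply(vq[pid, ], gq, mean)
        expect_true(m[["NM"]] > m[["LM"]] && m[["LM"]] > m[["M"]])
    }
})

test_that("zero effect removes any planted/background distinction in the means", {
    sim <- simulateCohort(simulationConfig(effect_step = 0, rng_seed = 3L))
    expect_true(all(sim$truth$class_means[, "NM"] ==
                    sim$truth$class_means[, "M"]))
})

test_that("left-censored masking removes the low quantile, MCAR is uniform", {
    cfgL <- simulationConfig(n_proteins = 300L, missing_rate = 0.1,
                             missing_mode = "left_censored", rng_seed = 8L)
    simL <- simulateCohort(cfgL)
    vals <- lfq(simL$experiment)
    # every observed value exceeds every censored one by construction
    cfg0 <- simulationConfig(n_proteins = 300L, missing_rate = 0,
                             rng_seed = 8L)
    expect_true(min(vals, na.rm = TRUE) >=
                stats::quantile(lfq(simulateCohort(cfg0)$experiment), 0.1) -
                1e-9)
    expect_equal(mean(is.na(vals)), 0.1, tolerance = 0.01)
})

test_that("planted proteins form a connected module at the module confidence", {
    cfg <- simulationConfig(n_proteins = 200L, rng_seed = 13L)
    sim <- simulateCohort(cfg)
    net <- simulateNetwork(cfg, sim$truth, rownames(sim$experiment))
    expect_false(any(igraph::which_loop(net)))
    expect_false(any(igraph::which_multiple(net)))
    sub <- igraph::induced_subgraph(net, sim$truth$planted_ids)
    expect_equal(igraph::components(sub)$no, 1L)
    expect_true(all(igraph::E(sub)$confidence == 0.9))
    # module edges all survive a downstream 0.5 confidence trim
    expect_true(all(igraph::E(sub)$confidence >= 0.5))
})

test_that("a singleton planted module yields a valid edgeless module", {
    cfg <- simulationConfig(n_proteins = 50L, n_planted = 1L, rng_seed = 2L)
    sim <- simulateCohort(cfg)
    net <- simulateNetwork(cfg, sim$truth, rownames(sim$experiment))
    sub <- igraph::induced_subgraph(net, sim$truth$planted_ids)
    expect_equal(igraph::ecount(sub), 0L)
    expect_equal(igraph::vcount(net), 50L)
    expect_error(simulateNetwork(cfg, list(planted_ids = "NOT_THERE"),
                                 rownames(sim$experiment)),
                 "not present")
})

test_that("fixtures round-trip through the readers", {
    cfg <- simulationConfig(n_per_class = c(3L, 3L, 3L), n_proteins = 25L,
                            n_planted = 4L, missing_rate = 0.1,
                            rng_seed = 9L)
    sim <- simulateCohort(cfg)
    net <- simulateNetwork(cfg, sim$truth, rownames(sim$experiment))
    dir <- withr::local_tempdir()
    paths <- writeFixture(sim$experiment, net, dir)
    vals <- lfq(sim$experiment)

    plain <- readAbundanceMatrix(paths["plain"], "plain")
    expect_equal(plain, vals, tolerance = 1e-8)
    expect_identical(is.na(plain), is.na(vals))

    pg <- readAbundanceMatrix(paths["proteingroups"], "proteingroups")
    expect_equal(pg, vals, tolerance = 1e-8)

    labs <- readSampleLabels(paths["labels"])
    expect_identical(unname(labs[colnames(vals)]),
                     as.character(metastasisGroup(sim$experiment)))

    back <- readInteractionNetwork(paths["network"])
    expect_equal(igraph::ecount(back), igraph::ecount(net))
    expect_equal(sort(igraph::E(back)$confidence),
                 sort(igraph::E(net)$confidence), tolerance = 1e-3)
})

test_that("score scale convention and the empty network are handled", {
    dir <- withr::local_tempdir()
    g <- igraph::make_graph(~ A - B)
    igraph::E(g)$confidence <- 0.5
    m <- matrix(c(28, 29, 30, 28, 29, 30), nrow = 1,
                dimnames = list("A", paste0("S", 1:6)))
    me <- MetastasisExperiment(m, c("NM", "NM", "LM", "LM", "M", "M"))
    paths <- writeFixture(me, g, dir)
    raw <- utils::read.delim(paths["network"])
    expect_identical(raw$combined_score, 500L)

    empty <- igraph::make_empty_graph(0, directed = FALSE)
    paths2 <- writeFixture(me, empty, file.path(dir, "e"))
    expect_identical(readLines(paths2["network"]),
                     "protein1\tprotein2\tcombined_score")
    back <- readInteractionNetwork(paths2["network"])
    expect_equal(igraph::ecount(back), 0L)
})
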