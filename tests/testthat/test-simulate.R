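test_that("retention factor has the right limits and closed form", {
    expect_equal(retentionFactor(0), 1)
    expect_equal(retentionFactor(1), 1 - exp(-1))
    expect_equal(retentionFactor(c(2, 4)), (1 - exp(-c(2, 4))) / c(2, 4))
    expect_error(retentionFactor(-1))
    # continuous through the series switch-over
    expect_equal(retentionFactor(1e-9), retentionFactor(1.0000001e-8),
                 tolerance = 1e-7)
})

test_that("retention factor matches Monte-Carlo fragment survival", {
    # a fragment at fractional 3'-distance t survives with prob exp(-k t)
    set.seed(101)
    for (k in c(0.5, 1.3, 3)) {
        t <- runif(1e5)
        surv <- rbinom(1e5, 1, exp(-k * t))
        se <- sd(surv) / sqrt(length(surv))
        expect_lt(abs(mean(surv) - retentionFactor(k)), 3 * se)
    }
})

test_that("simulated counts follow the mixture-plus-degradation expectation", {
    genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                        length = c(1000L, 2000L, 1500L),
                        mu_bs = c(10, 0, 5), mu_m = c(0, 10, 5),
                        deg_sens = c(0, 1, 2))
    samples <- data.frame(
        sample_id = c("a", "b"), study_id = "s", slice = 1L,
        label = c("BS", "M"), purity_bs = c(1, 0),
        deg_severity = c(0, 2), lib_size = c(1e4, 1e4))
    me <- simulateCounts(genes, samples, simConfig(n_genes = 3, seed = 1))
    exp_a <- assay(me, "expected")[, "a"]
    exp_b <- assay(me, "expected")[, "b"]
    # undegraded pure-BS sample: proportions follow mu_bs alone
    expect_equal(unname(exp_a), 1e4 * genes$mu_bs / sum(genes$mu_bs))
    # retention matches the closed form for the degraded sample
    expect_equal(unname(assay(me, "retention")[, "b"]),
                 retentionFactor(2 * genes$deg_sens))
    # pure-M sample: g1 (mu_m = 0) has zero expectation
    expect_equal(unname(exp_b[1]), 0)
    w <- genes$mu_m * retentionFactor(2 * genes$deg_sens)
    expect_equal(unname(exp_b), 1e4 * w / sum(w))
})

test_that("d = 0 gives an undegraded NB mixture and k = 1 the 1 - 1/e retention", {
    genes <- simulateGeneModels(simConfig(n_genes = 50, seed = 2))
    samples <- studyTemplate("filtration", replicates = 2, d = 0)
    me <- simulateCounts(genes, samples, simConfig(n_genes = 50, seed = 2))
    expect_true(all(assay(me, "retention") == 1))
    i <- which(genes$deg_sens > 0)[1]
    samples$deg_severity <- 1 / genes$deg_sens[i]  # k = 1 for gene i
    me2 <- simulateCounts(genes, samples, simConfig(n_genes = 50, seed = 2))
    expect_equal(unname(assay(me2, "retention")[i, 1]), 1 - exp(-1))
})

test_that("count simulation is deterministic given the seed and validates input", {
    genes <- simulateGeneModels(simConfig(n_genes = 30, seed = 5))
    samples <- studyTemplate("mech", replicates = 2)
    a <- simulateCounts(genes, samples, simConfig(n_genes = 30, seed = 9))
    b <- simulateCounts(genes, samples, simConfig(n_genes = 30, seed = 9))
    expect_identical(assay(a, "counts"), assay(b, "counts"))
    c_ <- simulateCounts(genes, samples, simConfig(n_genes = 30, seed = 10))
    expect_false(identical(assay(a, "counts"), assay(c_, "counts")))
    expect_error(simulateCounts(genes[0, ], samples, simConfig(30, seed = 1)),
                 "empty")
})

test_that("expected coverage is uniform without degradation, 3'-increasing with it", {
    expect_equal(simulateCoverage(100, 0, 2, depth = 7), rep(7, 100))
    cov <- simulateCoverage(500, 1.5, 1, depth = 10)
    expect_true(all(diff(cov) > 0))
    expect_equal(cov[500], 10)   # 3' end keeps full depth
    # 5' end retains exp(-d*s)
    expect_equal(cov[1], 10 * exp(-1.5))
    expect_error(simulateCoverage(0, 1, 1))
})

test_that("poisson coverage mode is seed-deterministic with the expected mean", {
    a <- simulateCoverage(2000, 1, 1, depth = 30, mode = "poisson", seed = 4)
    b <- simulateCoverage(2000, 1, 1, depth = 30, mode = "poisson", seed = 4)
    expect_identical(a, b)
    expect_equal(mean(a[1900:2000]), 30, tolerance = 0.1)
})

test_that("activity simulation honours alpha and purity ordering", {
    # alpha = 0.5: expected abundance identical across fractions
    act <- noiselessActivity(c(even = 0.5))
    even <- act[act$analyte_id == "even", ]
    expect_equal(length(unique(round(even$value, 12))), 1)
    # BS marker expected abundance ordered by purity
    nadp <- act[act$analyte_id == "NADPME", ]
    m_by_frac <- tapply(nadp$value, nadp$fraction, mean)
    expect_true(m_by_frac[["BS_e"]] > m_by_frac[["I_e"]])
    expect_true(m_by_frac[["I_e"]] > m_by_frac[["M_e"]])
    expect_error(noiselessActivity(c(bad = 1.2)), "alpha")
})

test_that("between two samples differing only in d, the degraded one loses more", {
    genes <- simulateGeneModels(simConfig(n_genes = 200, seed = 3))
    samples <- data.frame(
        sample_id = c("low", "high"), study_id = "s", slice = 1L,
        label = "unseparated", purity_bs = 0.5,
        deg_severity = c(0.2, 2.5), lib_size = 1e6)
    me <- simulateCounts(genes, samples, simConfig(n_genes = 200, seed = 3))
    s <- degSensitivity(me)
    high_s <- s > quantile(s, 0.75)
    R <- assay(me, "retention")
    # (a) lower total retained signal for sensitive genes
    expect_true(all(R[high_s, "high"] < R[high_s, "low"]))
    # (b) higher 3' bias in the degraded sample (expected profiles)
    bias <- expectedBiasTable(me, window = 50)
    b_low <- bias$bias3[bias$sample_id == "low"]
    b_high <- bias$bias3[bias$sample_id == "high"]
    keep <- !is.na(b_low) & !is.na(b_high) & high_s
    expect_true(all(b_high[keep] > b_low[keep]))
})
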