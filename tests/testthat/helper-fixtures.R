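# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# a tiny noiseless activity table on an explicit purity design
noiselessActivity <- function(alphas, purities = c(BS_e = 0.8, I_e = 0.5,
                                                   M_e = 0.25),
                              replicates = 4, slice = 2L) {
    analytes <- data.frame(
        analyte_id = names(alphas), alpha = unname(alphas), scale = 1,
        stringsAsFactors = FALSE)
    simulateActivityTable(analytes, purities = purities,
                          replicates = replicates,
                          config = simConfig(noise_sigma = 0, seed = 1),
                          slice = slice)
}

# brute-force grid oracle: fit T = alpha*B + (1-alpha)*M by least squares
# over a grid of alpha values, on fraction-of-total profiles
gridAlphaOracle <- function(Tv, Mv, Bv, step = 1e-3) {
    alphas <- seq(0, 1, by = step)
    sse <- vapply(alphas, function(a)
        sum((Tv - (a * Bv + (1 - a) * Mv))^2), numeric(1))
    alphas[which.min(sse)]
}

# exhaustive hypergeometric two-sided p for a 2x2 table (independent of
# fisher.test): sum of probabilities of all tables with the same margins
# that are no more likely than the observed one
hyperExactP <- function(k, K, n, N) {
    lo <- max(0, n + K - N); hi <- min(n, K)
    x <- lo:hi
    d <- dhyper(x, K, N - K, n)
    sum(d[d <= d[x == k] * (1 + 1e-7)])
}

# small mixture experiment used by several files
tinyMixture <- function(seed = 7, n_genes = 60, dispersion = 0,
                        samples = NULL) {
    cfg <- simConfig(n_genes = n_genes, dispersion = dispersion, seed = seed)
    genes <- simulateGeneModels(cfg)
    if (is.null(samples))
        samples <- rbind(studyTemplate("mech", replicates = 2),
                         studyTemplate("unseparated", replicates = 2))
    simulateCounts(genes, samples, cfg)
}
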