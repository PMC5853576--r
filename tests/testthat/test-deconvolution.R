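test_that("marker profiles align, sum to one per replicate, and catch zeros", {
    act <- noiselessActivity(c(x = 0.3))
    prof <- markerProfiles(act, "PEPC", "NADPME")
    expect_equal(nrow(prof), 12)   # 3 fractions x 4 replicates
    expect_equal(as.numeric(tapply(prof$M, prof$replicate, sum)), rep(1, 4))
    expect_equal(as.numeric(tapply(prof$B, prof$replicate, sum)), rep(1, 4))
    act0 <- act
    act0$value[act0$analyte_id == "PEPC"][1] <- 0
    expect_error(markerProfiles(act0, "PEPC", "NADPME"), "zero")
    expect_error(markerProfiles(act, "PEPC", "missing"), "missing")
})

test_that("targets equal to a marker give slopes exactly 0 and 1", {
    act <- noiselessActivity(c(x = 0.3))
    prof <- markerProfiles(act, "PEPC", "NADPME")
    em <- estimateFractionBS(prof$M, prof$M, prof$B)
    eb <- estimateFractionBS(prof$B, prof$M, prof$B)
    expect_equal(em$slope_b, 0, tolerance = 1e-12)
    expect_equal(eb$slope_b, 1, tolerance = 1e-12)
})

test_that("the log-ratio slope matches the nonlinear mixing oracle", {
    # noiseless alpha = 0.75 analyte on purities (0.8, 0.5, 0.25)
    act <- noiselessActivity(c(t75 = 0.75))
    ord <- function(df) df[order(df$replicate, df$fraction), ]
    raw_t <- ord(act[act$analyte_id == "t75", ])$value
    raw_m <- ord(act[act$analyte_id == "PEPC", ])$value
    raw_b <- ord(act[act$analyte_id == "NADPME", ])$value
    # mixing is exactly linear on the raw scale: the grid oracle is exact
    oracle <- gridAlphaOracle(raw_t, raw_m, raw_b)
    expect_lt(abs(oracle - 0.75), 1e-3)
    # the log-ratio regression works on fraction-of-total profiles and
    # approximates the mixing fraction
    prof <- markerProfiles(act, "PEPC", "NADPME")
    x <- ord(act[act$analyte_id == "t75", ])
    x$value <- fractionOfTotal(x$value, x$replicate)
    est <- estimateFractionBS(x$value, prof$M, prof$B)
    expect_lt(abs(est$slope_b - 0.75), 0.05)
    expect_lt(abs(est$slope_b - oracle), 0.05)
})

test_that("swapping the marker roles maps slope b to 1 - b", {
    act <- noiselessActivity(c(t = 0.3))
    prof <- markerProfiles(act, "PEPC", "NADPME")
    x <- act[act$analyte_id == "t", ]
    x$value <- fractionOfTotal(x$value, x$replicate)
    x <- x[order(x$replicate, x$fraction), ]
    fwd <- estimateFractionBS(x$value, prof$M, prof$B)
    rev_ <- estimateFractionBS(x$value, prof$B, prof$M)
    expect_equal(fwd$slope_b + rev_$slope_b, 1, tolerance = 0.02)
})

test_that("slope converges to alpha as purities narrow towards 0.5", {
    for (alpha in c(0.2, 0.65, 0.9)) {
        act <- noiselessActivity(setNames(alpha, "t"),
                                 purities = c(BS_e = 0.55, I_e = 0.5,
                                              M_e = 0.45))
        prof <- markerProfiles(act, "PEPC", "NADPME")
        x <- act[act$analyte_id == "t", ]
        x$value <- fractionOfTotal(x$value, x$replicate)
        x <- x[order(x$replicate, x$fraction), ]
        est <- estimateFractionBS(x$value, prof$M, prof$B)
        expect_lt(abs(est$slope_b - alpha), 0.01)
    }
})

test_that("degenerate regressions are refused", {
    expect_error(estimateFractionBS(c(1, 2), c(1, 2), c(2, 1)), "3")
    expect_error(estimateFractionBS(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3) * 2),
                 "not separated")
    expect_error(estimateFractionBS(c(1, -2, 3), c(1, 2, 3), c(3, 2, 1)),
                 "positive")
})

test_that("the slope test is symmetric around 0.5 with exact t-CDF p-values", {
    expect_equal(slopeTest(0.5, 0.1, 12)$p_value, 1)
    expect_equal(slopeTest(0.5, 0.1, 12)$t_stat, 0)
    up <- slopeTest(0.6, 0.05, 10); dn <- slopeTest(0.4, 0.05, 10)
    expect_equal(up$p_value, dn$p_value)
    # b = 0.9, se = 0.1, n = 12: p = 2 (1 - F_10(4))
    res <- slopeTest(0.9, 0.1, 12)
    expect_equal(res$t_stat, 4)
    expect_equal(res$p_value, 2 * (1 - pt(4, 10)))
    # documented se = 0 convention
    expect_equal(slopeTest(0.7, 0, 5)$p_value, 0)
    expect_equal(slopeTest(0.5, 0, 5)$p_value, 1)
})

test_that("pure abundances split twice the slice mean by the clamped slope", {
    expect_equal(pureAbundances(0.5, 10)[c("bs_pure", "m_pure")],
                 list(bs_pure = 10, m_pure = 10))
    expect_equal(pureAbundances(1, 3)[c("bs_pure", "m_pure")],
                 list(bs_pure = 6, m_pure = 0))
    over <- pureAbundances(1.2, 5)
    expect_equal(over$bs_pure, 10)
    expect_equal(over$m_pure, 0)
    expect_true(over$clamped)
    expect_false(pureAbundances(0.4, 5)$clamped)
})

test_that("parameter recovery holds across 200 simulated analytes", {
    set.seed(20)
    alphas <- runif(200)
    analytes <- data.frame(analyte_id = sprintf("a%03d", 1:200),
                           alpha = alphas, scale = 1)
    act <- simulateActivityTable(
        analytes, purities = c(BS_e = 0.8, I_e = 0.5, M_e = 0.25),
        replicates = 4, config = simConfig(noise_sigma = 0.1, seed = 21))
    res <- as.data.frame(deconvolveActivity(act))
    res <- res[match(analytes$analyte_id, res$analyte_id), ]
    expect_lt(mean(abs(res$slope_b - alphas)), 0.10)
    expect_gt(cor(res$slope_b, alphas, method = "spearman"), 0.9)
    # estimates and truth agree on which analytes are BS-skewed
    expect_gt(mean((res$slope_b > 0.5) == (alphas > 0.5)), 0.85)
    # pure abundances always split 2x the slice mean; for fraction-of-total
    # data over 3 fractions the slice mean is exactly 1/3
    expect_equal(res$bs_pure + res$m_pure, rep(2 / 3, 200))
})

test_that("deconvolveActivity reports BH FDR and the test count", {
    act <- noiselessActivity(c(u = 0.5, v = 0.9, w = 0.1))
    res <- deconvolveActivity(act)
    expect_s4_class(res, "DeconvResults")
    expect_true(all(res$fdr >= res$p_value - 1e-12))
    expect_equal(S4Vectors::metadata(res)$n_tests, 3)
    expect_false(S4Vectors::metadata(res)$fdr_reported)
})
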