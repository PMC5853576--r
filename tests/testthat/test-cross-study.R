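mkres <- function(gene_id, log2fc, fdr = 0.01, stage = "s1", study = "A",
                  mean_tpm = 10) {
    data.frame(study_id = study, stage_id = stage, gene_id = gene_id,
               log2fc = log2fc, p_value = fdr, fdr = fdr,
               mean_tpm = mean_tpm, stringsAsFactors = FALSE)
}

test_that("quantile normalization equalizes sorted columns exactly", {
    m <- cbind(a = c(1, 2, 3), b = c(10, 20, 30))
    qn <- quantileNormalizeLFC(m)
    expect_equal(unname(qn[, "a"]), c(5.5, 11, 16.5))
    expect_equal(unname(qn[, "b"]), c(5.5, 11, 16.5))
    # identical columns are unchanged
    m2 <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
    expect_equal(quantileNormalizeLFC(m2), m2)
    # sorted values identical across columns, ranks preserved
    set.seed(51)
    m3 <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("u", "v", "w")))
    qn3 <- quantileNormalizeLFC(m3)
    expect_identical(sort(qn3[, 1]), sort(qn3[, 2]))
    expect_identical(sort(qn3[, 1]), sort(qn3[, 3]))
    for (j in 1:3) expect_equal(rank(qn3[, j]), rank(m3[, j]))
    expect_error(quantileNormalizeLFC(cbind(c(NA, NA, 1), c(1, 2, 3))),
                 "finite")
})

test_that("back-calculated TPM pairs satisfy both defining identities", {
    expect_equal(backCalculateTPM(0, 7), data.frame(tpm_bs = 7, tpm_m = 7))
    expect_equal(backCalculateTPM(1, 3), data.frame(tpm_bs = 4, tpm_m = 2))
    expect_equal(backCalculateTPM(2, 0), data.frame(tpm_bs = 0, tpm_m = 0))
    # infinite fold changes put everything in one tissue
    expect_equal(backCalculateTPM(Inf, 5), data.frame(tpm_bs = 10, tpm_m = 0))
    expect_equal(backCalculateTPM(-Inf, 5), data.frame(tpm_bs = 0, tpm_m = 10))
    set.seed(52)
    l <- rnorm(1000, 0, 3); m <- rlnorm(1000, 2, 1)
    bc <- backCalculateTPM(l, m)
    expect_equal((bc$tpm_bs + bc$tpm_m) / 2, m, tolerance = 1e-12)
    expect_equal(log2(bc$tpm_bs / bc$tpm_m), l, tolerance = 1e-12)
})

test_that("conflict sets pick opposite-significant genes with provenance", {
    genes <- paste0("g", 1:6)
    resA <- mkres(genes, log2fc = c(0.2, 2, -0.1, 1, -2, 0.5),
                  fdr = c(0.5, 0.01, 0.9, 0.2, 0.01, 0.3))
    resB <- mkres(genes, log2fc = c(0.3, -1.5, 0.2, 1, 1.8, -0.2),
                  fdr = c(0.5, 0.01, 0.9, 0.01, 0.01, 0.4), study = "B")
    pairing <- data.frame(stage_a = "s1", stage_b = "s1")
    cs <- buildConflictSets(resA, resB, pairing)
    expect_equal(cs$set1, "g2")
    expect_equal(cs$set2, "g5")
    expect_equal(nrow(cs$provenance), 2)
    expect_length(intersect(cs$set1, cs$set2), 0)
    # no significant genes: both sets empty
    cs0 <- buildConflictSets(mkres(genes, 1, fdr = 0.9),
                             mkres(genes, -1, fdr = 0.9), pairing)
    expect_length(cs0$set1, 0); expect_length(cs0$set2, 0)
    # flipping the sign convention in both studies swaps the sets
    fA <- resA; fA$log2fc <- -fA$log2fc
    fB <- resB; fB$log2fc <- -fB$log2fc
    swapped <- buildConflictSets(fA, fB, pairing)
    expect_equal(swapped$set1, cs$set2)
    expect_equal(swapped$set2, cs$set1)
    expect_error(buildConflictSets(resA, resB,
                                   data.frame(stage_a = "s9", stage_b = "s1")),
                 "stage")
})

test_that("ortholog agreement counts signed directions over mapped genes", {
    genes <- paste0("g", 1:10)
    # only 4 genes have orthologs; 3 of the mapped agree
    omap <- setNames(paste0("o", 1:4), genes[1:4])
    other <- data.frame(gene_id = paste0("o", 1:4),
                        log2fc = c(1, 1, -1, -1), stringsAsFactors = FALSE)
    dirs <- c("BS", "BS", "BS", "M", rep("BS", 6))
    got <- agreementFraction(genes, dirs, omap, other)
    expect_equal(got$n_mapped, 4)
    expect_equal(got$n_same_direction, 3)  # g1, g2 (BS) and g4 (M) agree
    expect_equal(got$fraction, 0.75)
    # perfect agreement
    all_bs <- agreementFraction(genes[1:2], c("BS", "BS"), omap, other)
    expect_equal(all_bs$fraction, 1)
    # nothing maps: NA fraction
    none <- agreementFraction("gX", "BS", omap, other)
    expect_true(is.na(none$fraction))
})

test_that("overlap test equals the hypergeometric oracle", {
    universe <- paste0("u", 1:25)
    setA <- universe[1:10]; setB <- universe[6:17]
    got <- overlapTest(setA, setB, universe)
    expect_equal(got$p_value, hyperExactP(5, 12, 10, 25), tolerance = 1e-10)
    expect_equal(got$table[1, 1], 5)
    # disjoint halves: OR 0 and the most extreme p of those margins
    half <- overlapTest(universe[1:12], universe[13:24], universe[1:24])
    expect_equal(half$odds_ratio, 0)
    expect_equal(half$p_value, hyperExactP(0, 12, 12, 24), tolerance = 1e-10)
    expect_error(overlapTest(setA, setB, character()), "universe")
})

test_that("random subsets have odds ratios scattered around 1", {
    set.seed(53)
    universe <- paste0("u", 1:400)
    ors <- replicate(40, {
        a <- sample(universe, 120); b <- sample(universe, 120)
        overlapTest(a, b, universe)$odds_ratio
    })
    expect_lt(abs(median(log(ors))), 0.3)
})

test_that("sample clustering filters genes and uses correlation distances", {
    base <- c(120, 340, 800, 75, 510)
    tpm <- cbind(s1 = base, s2 = base * c(1.05, 0.95, 1.1, 0.9, 1.02),
                 s3 = rev(base), s4 = base)
    rownames(tpm) <- paste0("g", 1:5)
    tpm["g2", 1] <- 0          # zero-containing gene dropped
    tpm["g4", ] <- c(10, 12, 9, 11)  # low-max gene dropped
    cl <- clusterSamples(tpm, max_thresh = 50)
    expect_equal(nrow(cl$matrix), 3)
    # duplicated/rank-identical sample columns merge first at distance ~0
    expect_lt(min(cl$sample_tree$height), 1e-10)
    first <- cl$sample_tree$merge[1, ]
    expect_true(all(abs(first) %in% c(1, 2, 4)))  # s3 is the reversed outlier
    expect_match(cl$sample_newick, "^\\(")
    # perfectly anti-correlated samples sit at distance 2
    anti <- cbind(a = c(100, 200, 400), b = c(390, 210, 95))
    rownames(anti) <- paste0("g", 1:3)
    cl2 <- clusterSamples(anti, max_thresh = 50)
    expect_equal(max(cl2$sample_tree$height), 2)
    expect_error(clusterSamples(tpm * 0 + 1, max_thresh = 50), "filter")
})

test_that("developmental switch support is scored by signed patterns", {
    genes <- paste0("g", 1:8)
    yA <- mkres(genes, log2fc = c(1, 1, -1, -1, 1, -1, 1, -1),
                fdr = c(rep(0.01, 6), 0.5, 0.5))
    oA <- mkres(genes, log2fc = c(1, -1, -1, 1, 1, -1, 1, -1),
                fdr = c(rep(0.01, 6), 0.5, 0.5))
    # B replicates A exactly: full support in both classes
    full <- developmentalSwitchClassification(yA, oA, yA, oA)
    expect_equal(full$support_consistent, 1)
    expect_equal(full$support_switching, 1)
    expect_equal(nrow(full$classes), 6)   # g7, g8 not significant
    # sign-flipped B: no support anywhere
    yB <- yA; yB$log2fc <- -yB$log2fc
    oB <- oA; oB$log2fc <- -oB$log2fc
    none <- developmentalSwitchClassification(yA, oA, yB, oB)
    expect_equal(none$support_consistent, 0)
    expect_equal(none$support_switching, 0)
    # the Fisher p matches a direct test of the same table
    expect_equal(full$p_value, fisher.test(full$table)$p.value)
})

test_that("keyword set expression is additive and symmetric at lfc 0", {
    res1 <- mkres(paste0("g", 1:4), log2fc = c(0, 0, 1, -1),
                  mean_tpm = c(5, 3, 8, 2))
    out1 <- keywordSetExpression(list(res1), c("g1", "g2"))
    expect_equal(out1$tpm_bs, out1$tpm_m)   # all-lfc-0 genes
    single <- keywordSetExpression(list(res1), "g3")
    bc <- backCalculateTPM(1, 8)
    expect_equal(single$tpm_bs, bc$tpm_bs)
    expect_equal(single$tpm_m, bc$tpm_m)
    # additivity over disjoint sets
    ab <- keywordSetExpression(list(res1), c("g3", "g4"))
    a <- keywordSetExpression(list(res1), "g3")
    b <- keywordSetExpression(list(res1), "g4")
    expect_equal(ab$tpm_bs, a$tpm_bs + b$tpm_bs)
    expect_equal(ab$tpm_m, a$tpm_m + b$tpm_m)
})

test_that("identical separated and unseparated groups yield no candidates", {
    counts <- matrix(rpois(200, 50), 50, 4,
                     dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
    counts <- cbind(counts, counts)
    got <- degradationSensitiveGenes(counts, 1:4, 5:8, phi = 0.1)
    expect_length(got$down, 0)
    expect_length(got$up, 0)
})

test_that("the lmd-style comparison recovers degradation-sensitive genes", {
    cfg <- simConfig(n_genes = 1000, dispersion = 0.05, seed = 55)
    genes <- simulateGeneModels(cfg)
    sheet <- rbind(studyTemplate("lmd", replicates = 3),
                   studyTemplate("unseparated", replicates = 3))
    me <- simulateCounts(genes, sheet, cfg)
    got <- degradationSensitiveGenes(me, which(sheet$label != "unseparated"),
                                     which(sheet$label == "unseparated"))
    s <- degSensitivity(me)
    top <- names(s)[s > quantile(s, 0.9)]
    sens <- length(intersect(got$down, top)) / length(top)
    expect_gt(sens, 0.8)
    # insensitive genes almost never end up in the down list
    zero <- names(s)[s == 0]
    expect_lt(length(intersect(got$down, zero)) / length(zero), 0.05)
})
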