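#' @importFrom limma normalizeQuantiles
#' @importFrom stats fisher.test cor hclust as.dist
#' @importFrom ape as.phylo write.tree
NULL

#' Quantile normalize log2 fold changes across studies
#'
#' Makes the per-study fold-change distributions directly comparable: after
#' normalization every column's sorted values equal the across-column mean
#' of sorted values (ties receive the mean of their would-be quantiles);
#' within-column ranks are preserved exactly. Columns must be aligned on
#' shared genes (inner join) beforehand.
#'
#' @param lfc Numeric matrix, genes x studies (>= 2 columns).
#' @return Quantile-normalized matrix with the same dimnames.
#' @export
quantileNormalizeLFC <- function(lfc) {
    stopifnot(is.matrix(lfc), ncol(lfc) >= 2)
    nfin <- colSums(is.finite(lfc))
    if (any(nfin < 2))
        stop("column(s) with fewer than 2 finite values: ",
             paste(colnames(lfc)[nfin < 2], collapse = ", "))
    out <- normalizeQuantiles(lfc, ties = TRUE)
    dimnames(out) <- dimnames(lfc)
    out
}

#' Back-calculate tissue TPM from normalized fold change and mean
#'
#' Inverts the (log2fc, mean) parameterization: for normalized log2 fold
#' change l and mean TPM m, `tpm_bs = 2m / (1 + 2^-l)` and
#' `tpm_m = 2m / (1 + 2^l)`, so that `(tpm_bs + tpm_m)/2 = m` and
#' `log2(tpm_bs/tpm_m) = l` hold exactly. `m = 0` gives `(0, 0)`.
#'
#' @param lfc Normalized log2 fold change (BS over M); may be +/-Inf.
#' @param mean_tpm Mean TPM (>= 0).
#' @return data.frame with columns `tpm_bs`, `tpm_m`.
#' @export
backCalculateTPM <- function(lfc, mean_tpm) {
    stopifnot(all(mean_tpm >= 0))
    ## both tissue fractions computed directly from the logistic form:
    ## deriving one as 1 - other loses precision at large |lfc|
    f_bs <- 1 / (1 + 2^(-lfc))          # fraction of the 2m total in BS
    f_m <- 1 / (1 + 2^lfc)
    f_bs[lfc == Inf] <- 1; f_m[lfc == Inf] <- 0
    f_bs[lfc == -Inf] <- 0; f_m[lfc == -Inf] <- 1
    data.frame(tpm_bs = 2 * mean_tpm * f_bs, tpm_m = 2 * mean_tpm * f_m)
}

.checkStudyResult <- function(res) {
    stopifnot(all(c("gene_id", "stage_id", "log2fc", "p_value", "fdr",
                    "mean_tpm") %in% colnames(res)))
    res
}

#' Assemble a StudyResult table
#'
#' The unit of all cross-study operations: one row per (gene, stage) with
#' BS-vs-M log2 fold change, p-value, FDR and mean TPM.
#'
#' @param de A differential expression table ([nbTest()] or
#'   [purityAdjustedDE()] output).
#' @param study_id,stage_id Study and stage (slice/section) labels.
#' @return data.frame with columns `study_id`, `stage_id`, `gene_id`,
#'   `log2fc`, `p_value`, `fdr`, `mean_tpm`.
#' @export
studyResult <- function(de, study_id, stage_id) {
    data.frame(study_id = study_id, stage_id = stage_id,
               de[, c("gene_id", "log2fc", "p_value", "fdr", "mean_tpm")],
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Build cross-study conflict sets
#'
#' For explicitly paired stages of two studies: conflict set 1 holds genes
#' significantly BS-enriched (fdr < alpha, log2fc > 0) in study A and
#' significantly M-enriched in the paired stage of study B; conflict set 2
#' is the mirror image. A gene qualifying in any designated pair is
#' included, with per-gene provenance.
#'
#' @param resA,resB StudyResult tables (see [studyResult()]).
#' @param pairing data.frame with columns `stage_a`, `stage_b`.
#' @param alpha Significance threshold on FDR (default 0.05).
#' @return list(`set1`, `set2` = gene id vectors, `provenance` =
#'   data.frame(gene_id, stage_a, stage_b, set)).
#' @export
buildConflictSets <- function(resA, resB, pairing, alpha = 0.05) {
    .checkStudyResult(resA); .checkStudyResult(resB)
    prov <- list()
    for (i in seq_len(nrow(pairing))) {
        sa <- pairing$stage_a[i]; sb <- pairing$stage_b[i]
        a <- resA[resA$stage_id == sa, ]
        b <- resB[resB$stage_id == sb, ]
        if (nrow(a) == 0) stop("study A has no stage '", sa, "'")
        if (nrow(b) == 0) stop("study B has no stage '", sb, "'")
        shared <- intersect(a$gene_id, b$gene_id)
        a <- a[match(shared, a$gene_id), ]
        b <- b[match(shared, b$gene_id), ]
        sigA_bs <- a$fdr < alpha & a$log2fc > 0
        sigA_m <- a$fdr < alpha & a$log2fc < 0
        sigB_bs <- b$fdr < alpha & b$log2fc > 0
        sigB_m <- b$fdr < alpha & b$log2fc < 0
        s1 <- shared[sigA_bs & sigB_m]
        s2 <- shared[sigA_m & sigB_bs]
        if (length(s1))
            prov[[length(prov) + 1L]] <- data.frame(
                gene_id = s1, stage_a = sa, stage_b = sb, set = "set1",
                stringsAsFactors = FALSE)
        if (length(s2))
            prov[[length(prov) + 1L]] <- data.frame(
                gene_id = s2, stage_a = sa, stage_b = sb, set = "set2",
                stringsAsFactors = FALSE)
    }
    prov <- if (length(prov)) do.call(rbind, prov)
            else data.frame(gene_id = character(), stage_a = character(),
                            stage_b = character(), set = character(),
                            stringsAsFactors = FALSE)
    list(set1 = unique(prov$gene_id[prov$set == "set1"]),
         set2 = unique(prov$gene_id[prov$set == "set2"]),
         provenance = prov)
}

#' Genes depleted or enriched by tissue separation
#'
#' Compares separated against unseparated libraries of a comparable stage
#' with the NB test: `down` genes are significantly less abundant in the
#' separated samples (degradation-sensitive candidates), `up` genes
#' significantly more abundant (the relative gainers).
#'
#' @param counts Count matrix or [MixtureExperiment-class].
#' @param separated,unseparated Column names/indices of the two groups.
#' @param alpha FDR threshold (default 0.05).
#' @param phi Optional common dispersion passed to [nbTest()].
#' @return list(`down`, `up` = gene id vectors, `de` = the full DE table).
#' @export
degradationSensitiveGenes <- function(counts, separated, unseparated,
                                      alpha = 0.05, phi = NULL) {
    de <- nbTest(counts, group_a = separated, group_b = unseparated,
                 phi = phi)
    list(down = de$gene_id[de$fdr < alpha & de$log2fc < 0],
         up = de$gene_id[de$fdr < alpha & de$log2fc > 0],
         de = de)
}

#' Cross-species direction agreement of a gene set
#'
#' Maps a direction-labelled gene set through an ortholog map and asks what
#' fraction of the mapped orthologs shows the same enrichment direction
#' (sign of log2fc, regardless of significance) in the other study. Genes
#' without an ortholog or without a finite fold change are excluded from
#' the denominator.
#'
#' @param genes Gene ids of the set.
#' @param directions Per-gene direction, `"BS"` or `"M"`.
#' @param ortholog_map Named character vector: source gene id -> target id.
#' @param other StudyResult-like table with `gene_id` and `log2fc` for the
#'   target study.
#' @return list(`n_mapped`, `n_same_direction`, `fraction` (NA when no gene
#'   maps)).
#' @export
agreementFraction <- function(genes, directions, ortholog_map, other) {
    stopifnot(length(genes) == length(directions),
              all(directions %in% c("BS", "M")))
    tgt <- ortholog_map[genes]
    lfc <- other$log2fc[match(tgt, other$gene_id)]
    ok <- !is.na(tgt) & is.finite(lfc)
    want <- ifelse(directions == "BS", 1, -1)
    same <- sign(lfc[ok]) == want[ok]
    n_mapped <- sum(ok)
    list(n_mapped = n_mapped, n_same_direction = sum(same),
         fraction = if (n_mapped) sum(same) / n_mapped else NA_real_)
}

#' Fisher exact overlap test of two gene sets
#'
#' Two-sided Fisher exact test of the 2x2 table
#' `[[|A&B|, |A\\B|], [|B\\A|, |U\\(A|B)|]]` over a common universe, with
#' the conditional-MLE odds ratio.
#'
#' @param setA,setB Gene id vectors (subsets of `universe`).
#' @param universe Universe of gene ids (nonempty).
#' @return list(`odds_ratio`, `p_value`, `table`).
#' @export
overlapTest <- function(setA, setB, universe) {
    if (length(universe) == 0) stop("empty universe")
    setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
    stopifnot(all(setA %in% universe), all(setB %in% universe))
    k <- length(intersect(setA, setB))
    tab <- matrix(c(k, length(setA) - k,
                    length(setB) - k,
                    length(universe) - length(setA) - length(setB) + k),
                  2, 2, byrow = TRUE)
    ft <- fisher.test(tab, alternative = "two.sided")
    list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Hierarchical clustering of expression samples and genes
#'
#' The interstudy clustering protocol: genes kept only when expressed in
#' every sample (TPM > `min_expr`) and well expressed in at least one
#' (TPM > `max_thresh`); the matrix is log2 transformed; distances are
#' 1 - Pearson correlation for genes and 1 - Spearman correlation for
#' samples; average linkage.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param min_expr Per-sample floor every gene must exceed (default 0).
#' @param max_thresh Threshold some sample must exceed (default 50).
#' @param linkage hclust method (default "average").
#' @return list(`gene_tree`, `sample_tree` (hclust), `matrix` (filtered
#'   log2 TPM), `gene_newick`, `sample_newick`).
#' @export
clusterSamples <- function(tpm, min_expr = 0, max_thresh = 50,
                           linkage = "average") {
    stopifnot(is.matrix(tpm), ncol(tpm) >= 2)
    keep <- apply(tpm, 1, min) > min_expr & apply(tpm, 1, max) > max_thresh
    if (!any(keep)) stop("no genes survive the expression filter")
    m <- log2(tpm[keep, , drop = FALSE])
    gd <- as.dist(1 - cor(t(m), method = "pearson"))
    sd_ <- as.dist(1 - cor(m, method = "spearman"))
    gt <- hclust(gd, method = linkage)
    st <- hclust(sd_, method = linkage)
    list(gene_tree = gt, sample_tree = st, matrix = m,
         gene_newick = write.tree(as.phylo(gt)),
         sample_newick = write.tree(as.phylo(st)))
}

#' Classify developmental switches and their cross-study support
#'
#' Genes significant (fdr < alpha) at both stages of study A are classified
#' as `consistent` (same fold-change sign young and old) or `switching`
#' (opposite signs). A gene is `supported` when study B shows the same
#' signed pattern at the matching stages (sign only, significance in B not
#' required unless `require_significance`). Returns the 2x2
#' class-by-support table with a two-sided Fisher exact p: switching genes
#' finding less support than consistent ones indicates switches are mostly
#' artifacts.
#'
#' @param youngA,oldA,youngB,oldB StudyResult tables aligned on genes.
#' @param alpha FDR threshold in study A.
#' @param require_significance Also require fdr < alpha in study B.
#' @return list(`classes` = per-gene data.frame, `table`, `p_value`,
#'   `support_consistent`, `support_switching`).
#' @export
developmentalSwitchClassification <- function(youngA, oldA, youngB, oldB,
                                              alpha = 0.05,
                                              require_significance = FALSE) {
    genes <- Reduce(intersect, list(youngA$gene_id, oldA$gene_id,
                                    youngB$gene_id, oldB$gene_id))
    ya <- youngA[match(genes, youngA$gene_id), ]
    oa <- oldA[match(genes, oldA$gene_id), ]
    yb <- youngB[match(genes, youngB$gene_id), ]
    ob <- oldB[match(genes, oldB$gene_id), ]
    sig <- ya$fdr < alpha & oa$fdr < alpha &
           sign(ya$log2fc) != 0 & sign(oa$log2fc) != 0
    cls <- ifelse(sign(ya$log2fc) == sign(oa$log2fc), "consistent",
                  "switching")
    sup <- sign(yb$log2fc) == sign(ya$log2fc) &
           sign(ob$log2fc) == sign(oa$log2fc)
    if (require_significance) sup <- sup & yb$fdr < alpha & ob$fdr < alpha
    keep <- sig & !is.na(sup)
    classes <- data.frame(gene_id = genes[keep], class = cls[keep],
                          supported = sup[keep], stringsAsFactors = FALSE)
    tab <- table(factor(classes$class, c("consistent", "switching")),
                 factor(classes$supported, c(TRUE, FALSE)))
    p <- if (all(dim(tab) == c(2, 2)) && sum(tab) > 0)
        fisher.test(tab)$p.value else NA_real_
    frac <- function(cl) {
        n <- sum(classes$class == cl)
        if (n == 0) NA_real_ else sum(classes$supported[classes$class == cl]) / n
    }
    list(classes = classes, table = tab, p_value = p,
         support_consistent = frac("consistent"),
         support_switching = frac("switching"))
}

#' Cumulative tissue expression of a keyword gene set
#'
#' Sums the back-calculated pure-tissue TPM over a gene set, per
#' study/stage — the keyword ("phloem", "epidermal", ...) co-purification
#' diagnostic.
#'
#' @param results List of StudyResult tables (with quantile-normalized
#'   `log2fc` and `mean_tpm`).
#' @param gene_set Nonempty gene id vector.
#' @return data.frame with columns `study_id`, `stage_id`, `n_genes`,
#'   `tpm_bs`, `tpm_m`.
#' @export
keywordSetExpression <- function(results, gene_set) {
    stopifnot(length(gene_set) > 0)
    rows <- lapply(results, function(res) {
        .checkStudyResult(res)
        r <- res[res$gene_id %in% gene_set, ]
        bc <- backCalculateTPM(r$log2fc, r$mean_tpm)
        data.frame(study_id = unique(res$study_id)[1],
                   stage_id = unique(res$stage_id)[1],
                   n_genes = nrow(r),
                   tpm_bs = sum(bc$tpm_bs), tpm_m = sum(bc$tpm_m),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
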