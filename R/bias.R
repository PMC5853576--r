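#' @importFrom stats median IQR
NULL

#' 3' coverage bias of one transcript
#'
#' Mean coverage over the 3'-most `window` bases divided by mean coverage
#' over the whole transcript. Uniform coverage gives 1; degradation that
#' preferentially removes 5' signal pushes the ratio above 1, with upper
#' bound `length/window`. Undefined (NA) for transcripts shorter than
#' `2 * window` or with zero total coverage.
#'
#' @param cov Numeric coverage vector, 0-based position 5' to 3'.
#' @param window 3' window size in nt (default 100).
#' @return The bias ratio, or `NA_real_` when undefined.
#' @export
geneThreePrimeBias <- function(cov, window = 100L) {
    stopifnot(window >= 1)
    L <- length(cov)
    if (L < 2 * window) return(NA_real_)
    if (any(cov < 0)) stop("coverage must be nonnegative")
    m_all <- mean(cov)
    if (m_all == 0) return(NA_real_)
    mean(cov[(L - window + 1):L]) / m_all
}

#' Per-gene, per-sample bias table
#'
#' Applies [geneThreePrimeBias()] to a collection of coverage profiles.
#' Profiles may be supplied as a long data.frame (`gene_id`, `sample_id`,
#' `pos`, `depth`; `pos` 0-based 5' to 3') or as a nested list
#' `profiles[[sample_id]][[gene_id]]` of numeric vectors.
#'
#' @param profiles Long coverage data.frame or nested list.
#' @param window 3' window size in nt.
#' @return data.frame with columns `gene_id`, `sample_id`, `bias3`
#'   (NA when undefined), `mean_cov`.
#' @export
computeBiasTable <- function(profiles, window = 100L) {
    if (is.data.frame(profiles)) {
        stopifnot(all(c("gene_id", "sample_id", "pos", "depth") %in%
                      colnames(profiles)))
        profiles <- profiles[order(profiles$sample_id, profiles$gene_id,
                                   profiles$pos), ]
        key <- interaction(profiles$sample_id, profiles$gene_id,
                           drop = TRUE, sep = "\t")
        covs <- split(profiles$depth, key)
        ids <- do.call(rbind, strsplit(names(covs), "\t", fixed = TRUE))
        out <- data.frame(gene_id = ids[, 2], sample_id = ids[, 1],
                          stringsAsFactors = FALSE)
    } else {
        out <- do.call(rbind, lapply(names(profiles), function(s) {
            data.frame(gene_id = names(profiles[[s]]), sample_id = s,
                       stringsAsFactors = FALSE)
        }))
        covs <- lapply(seq_len(nrow(out)), function(i)
            profiles[[out$sample_id[i]]][[out$gene_id[i]]])
    }
    out$bias3 <- vapply(covs, geneThreePrimeBias, numeric(1), window = window)
    out$mean_cov <- vapply(covs, mean, numeric(1))
    rownames(out) <- NULL
    out
}

#' Expected-coverage bias table from a mixture model
#'
#' Computes the 3' bias of the deterministic expected coverage profile of
#' every (gene, sample) pair of a [MixtureExperiment-class], i.e. the bias
#' each library would show at infinite depth given its degradation severity
#' and the gene's sensitivity. Genes shorter than `2 * window` get NA.
#'
#' @param me A [MixtureExperiment-class].
#' @param window 3' window size in nt.
#' @param depth Nominal 3'-end depth (the bias ratio is scale invariant).
#' @return data.frame as in [computeBiasTable()].
#' @export
expectedBiasTable <- function(me, window = 100L, depth = 50) {
    genes <- geneModels(me)
    d <- degSeverity(me)
    rows <- vector("list", length(d))
    for (j in seq_along(d)) {
        b <- vapply(seq_len(nrow(genes)), function(i) {
            cov <- simulateCoverage(genes$length[i], d[j], genes$deg_sens[i],
                                    depth = depth, mode = "expected")
            geneThreePrimeBias(cov, window = window)
        }, numeric(1))
        rows[[j]] <- data.frame(gene_id = genes$gene_id,
                                sample_id = names(d)[j], bias3 = b,
                                mean_cov = depth, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-sample median 3' bias over highly expressed genes
#'
#' The genomic-background summary: per sample, the median bias over the
#' `top_n` genes by expression in that sample (among genes with a defined
#' bias). If fewer than `top_n` are defined, all are used with a warning.
#'
#' @param bias Bias table ([computeBiasTable()]).
#' @param expression Expression matrix (genes x samples, e.g. TPM) with
#'   dimnames matching the bias table.
#' @param top_n Number of top-expressed genes (default 1000).
#' @return data.frame with columns `sample_id`, `n_genes`, `median_bias`.
#' @export
sampleBiasSummary <- function(bias, expression, top_n = 1000L) {
    samples <- unique(bias$sample_id)
    out <- lapply(samples, function(s) {
        b <- bias[bias$sample_id == s & !is.na(bias$bias3), ]
        expr <- expression[match(b$gene_id, rownames(expression)), s]
        if (nrow(b) < top_n)
            warning("sample ", s, ": only ", nrow(b),
                    " genes with defined bias (requested top ", top_n, ")")
        keep <- head(order(expr, decreasing = TRUE), top_n)
        data.frame(sample_id = s, n_genes = length(keep),
                   median_bias = median(b$bias3[keep]),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' 3' bias profile of gene sets
#'
#' Median and IQR of the 3' bias per (gene set, sample); the full gene
#' universe is always included as set `"background"`. This is the
#' conflict-set diagnostic: a gene set whose median bias exceeds the
#' background across samples is flagged as degradation-driven.
#'
#' @param bias Bias table ([computeBiasTable()]).
#' @param gene_sets Named list of gene id vectors.
#' @return data.frame with columns `set`, `sample_id`, `n`, `median_bias`,
#'   `iqr_bias` (NA rows, with a warning, for empty sets).
#' @export
setBiasProfile <- function(bias, gene_sets) {
    sets <- c(list(background = unique(bias$gene_id)), gene_sets)
    samples <- unique(bias$sample_id)
    rows <- list()
    for (nm in names(sets)) {
        if (length(sets[[nm]]) == 0 && nm != "background")
            warning("gene set '", nm, "' is empty")
        for (s in samples) {
            b <- bias$bias3[bias$sample_id == s &
                            bias$gene_id %in% sets[[nm]] & !is.na(bias$bias3)]
            rows[[length(rows) + 1L]] <- data.frame(
                set = nm, sample_id = s, n = length(b),
                median_bias = if (length(b)) median(b) else NA_real_,
                iqr_bias = if (length(b)) IQR(b) else NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
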