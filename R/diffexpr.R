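#' @importFrom stats dbinom pnorm pt p.adjust var
NULL

#' Method-of-moments common NB dispersion
#'
#' A single dispersion phi shared across genes, estimated from replicated
#' groups after library-size normalization: for each gene and group,
#' \eqn{(s^2 - a\,\mu)/\mu^2} (with a the mean normalization scale factor of
#' the group, correcting the Poisson term for the rescaling), averaged over
#' all (gene, group) pairs and floored at zero.
#'
#' @param counts Count matrix (genes x samples) or
#'   [MixtureExperiment-class].
#' @param groups Factor/vector of group labels per sample.
#' @param lib_sizes Library sizes; default column sums.
#' @return list(`phi`, `method = "moments"`, `n_samples`).
#' @export
estimateCommonDispersion <- function(counts, groups, lib_sizes = NULL) {
    if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
    if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
    stopifnot(ncol(counts) == length(groups),
              all(lib_sizes > 0))
    groups <- as.factor(groups)
    sf <- mean(lib_sizes) / lib_sizes
    y <- sweep(counts, 2, sf, "*")
    contrib <- c()
    any_rep <- FALSE
    for (g in levels(groups)) {
        idx <- which(groups == g)
        if (length(idx) < 2) next
        any_rep <- TRUE
        m <- rowMeans(y[, idx, drop = FALSE])
        v <- apply(y[, idx, drop = FALSE], 1, var)
        a <- mean(sf[idx])
        ok <- m > 0
        contrib <- c(contrib, (v[ok] - a * m[ok]) / m[ok]^2)
    }
    if (!any_rep)
        stop("no group has replicates; supply a dispersion estimated elsewhere")
    list(phi = max(0, mean(contrib)), method = "moments",
         n_samples = length(groups))
}

## Exact conditional two-group NB test on library-equalized summed counts.
## Given equal per-sample means within and between groups under H0 and a
## common dispersion phi, the distribution of the group-A sum conditional on
## the total is free of the mean (negative hypergeometric; binomial when
## phi = 0). Two-sided p sums the probabilities of all outcomes no more
## likely than the observed one.
.condNBTest <- function(yA, yB, nA, nB, phi) {
    s <- yA + yB
    if (s == 0) return(1)
    if (s > 2e5) {
        ## huge totals: normal approximation on the conditional moments
        ## (binomial for phi = 0; Dirichlet-multinomial otherwise)
        if (phi <= 0) {
            pr <- nA / (nA + nB)
            m0 <- s * pr; v0 <- s * pr * (1 - pr)
        } else {
            a1 <- nA / phi; a2 <- nB / phi; a0 <- a1 + a2
            m0 <- s * a1 / a0
            v0 <- s * (a1 * a2 / a0^2) * (s + a0) / (a0 + 1)
        }
        z <- (abs(yA - m0) - 0.5) / sqrt(v0)
        return(min(1, 2 * pnorm(-max(z, 0))))
    }
    y <- 0:s
    if (phi <= 0) {
        lp <- dbinom(y, s, nA / (nA + nB), log = TRUE)
    } else {
        r1 <- nA / phi; r2 <- nB / phi
        lp <- lchoose(y + r1 - 1, y) + lchoose(s - y + r2 - 1, s - y)
    }
    lp <- lp - max(lp)
    p <- exp(lp); p <- p / sum(p)
    sum(p[p <= p[yA + 1] * (1 + 1e-7)])
}

#' Negative binomial differential expression between two groups
#'
#' Library sizes are equalized by total-count scaling (scaled counts are
#' rounded to integers for the exact test), group counts are summed per
#' gene, and a two-sided exact conditional NB test at the supplied or
#' estimated common dispersion is applied. The log2 fold change (A over B)
#' comes from the normalized group means with a 0.5 counts-per-million
#' pseudo-count. With no replicates the supplied `phi` is used as-is —
#' mirroring the reuse of a dispersion estimated from other studies.
#'
#' @param counts Count matrix or [MixtureExperiment-class].
#' @param group_a,group_b Column names/indices of the two groups (A is the
#'   BS side throughout this package: positive log2fc = higher in A).
#' @param phi Common NB dispersion; `NULL` estimates it from the data via
#'   [estimateCommonDispersion()].
#' @param lib_sizes Library sizes; default column sums.
#' @param mean_expr Optional per-gene mean expression to report in the
#'   `mean_tpm` column (e.g. a TPM row mean); defaults to the mean CPM over
#'   both groups.
#' @return data.frame with columns `gene_id`, `log2fc`, `p_value`, `fdr`,
#'   `mean_tpm`, `phi`.
#' @export
nbTest <- function(counts, group_a, group_b, phi = NULL, lib_sizes = NULL,
                   mean_expr = NULL) {
    if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
    stopifnot(is.matrix(counts))
    A <- counts[, group_a, drop = FALSE]
    B <- counts[, group_b, drop = FALSE]
    if (is.null(lib_sizes)) lib_sizes <- colSums(cbind(A, B))
    stopifnot(all(lib_sizes > 0), length(lib_sizes) == ncol(A) + ncol(B))
    if (is.null(phi)) {
        grp <- rep(c("A", "B"), c(ncol(A), ncol(B)))
        phi <- estimateCommonDispersion(cbind(A, B), grp, lib_sizes)$phi
    }
    stopifnot(phi >= 0)
    ref <- mean(lib_sizes)
    sf <- ref / lib_sizes
    yA <- sweep(A, 2, sf[seq_len(ncol(A))], "*")
    yB <- sweep(B, 2, sf[ncol(A) + seq_len(ncol(B))], "*")
    cpmA <- rowMeans(yA) / ref * 1e6
    cpmB <- rowMeans(yB) / ref * 1e6
    log2fc <- log2((cpmA + 0.5) / (cpmB + 0.5))
    sA <- round(rowSums(yA)); sB <- round(rowSums(yB))
    p <- vapply(seq_len(nrow(counts)), function(i) {
        if (sA[i] + sB[i] == 0) return(1)
        .condNBTest(sA[i], sB[i], ncol(A), ncol(B), phi)
    }, numeric(1))
    if (is.null(mean_expr)) mean_expr <- (cpmA + cpmB) / 2
    gene_id <- rownames(counts)
    if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(counts)))
    out <- data.frame(gene_id = gene_id, log2fc = log2fc, p_value = p,
                      fdr = p.adjust(p, method = "BH"),
                      mean_tpm = mean_expr, phi = phi,
                      stringsAsFactors = FALSE, row.names = NULL)
    out$log2fc[sA == 0 & sB == 0] <- 0
    out
}

#' Purity-adjusted differential expression (contamination-tolerant)
#'
#' For imperfectly enriched samples, per-gene library-normalized expression
#' y_r is regressed (least squares, no intercept) on the two-column mixing
#' design `[pi_r, 1 - pi_r]`, where `pi_r` is the BS purity of sample r.
#' The coefficients estimate the pure-BS and pure-M expression; the log2
#' fold change uses nonnegativity-clipped coefficients plus a 0.5 CPM
#' pseudo-count, while the two-sided p-value tests the unclipped contrast
#' B - M with the per-gene residual variance (t, n - 2 df). With perfect
#' separation (`pi` in {0, 1}) this reduces to ordinary group means.
#'
#' @param counts Count matrix or [MixtureExperiment-class] (purities are
#'   then taken from `colData` unless overridden).
#' @param purity BS purity per sample, in `[0, 1]`, not all identical.
#' @param lib_sizes Library sizes; default column sums.
#' @param mean_expr Optional per-gene mean expression for the `mean_tpm`
#'   column; defaults to mean CPM.
#' @return data.frame with columns `gene_id`, `log2fc`, `p_value`, `fdr`,
#'   `mean_tpm`, `bs_hat`, `m_hat` (pure-tissue CPM estimates).
#' @export
purityAdjustedDE <- function(counts, purity = NULL, lib_sizes = NULL,
                             mean_expr = NULL) {
    if (is(counts, "SummarizedExperiment")) {
        if (is.null(purity)) purity <- colData(counts)$purity_bs
        counts <- assay(counts, "counts")
    }
    stopifnot(is.matrix(counts), !is.null(purity),
              length(purity) == ncol(counts),
              all(purity >= 0 & purity <= 1))
    if (length(unique(purity)) < 2)
        stop("all purities identical: mixing design is singular")
    if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
    cpm <- sweep(counts, 2, lib_sizes / 1e6, "/")
    X <- cbind(bs = purity, m = 1 - purity)
    XtXi <- solve(crossprod(X))
    H <- X %*% XtXi                       # samples x 2
    beta <- t(cpm %*% H)                  # 2 x genes
    fitted <- X %*% beta
    n <- ncol(counts)
    rss <- colSums((t(cpm) - fitted)^2)
    sigma2 <- rss / (n - 2)
    cvec <- c(1, -1)
    vc <- drop(t(cvec) %*% XtXi %*% cvec)
    tstat <- (beta[1, ] - beta[2, ]) / sqrt(pmax(sigma2 * vc, 1e-300))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    bs_hat <- pmax(beta[1, ], 0)
    m_hat <- pmax(beta[2, ], 0)
    log2fc <- log2((bs_hat + 0.5) / (m_hat + 0.5))
    if (is.null(mean_expr)) mean_expr <- rowMeans(cpm)
    gene_id <- rownames(counts)
    if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(counts)))
    zero <- rowSums(counts) == 0
    log2fc[zero] <- 0; p[zero] <- 1
    data.frame(gene_id = gene_id, log2fc = log2fc, p_value = p,
               fdr = p.adjust(p, method = "BH"), mean_tpm = mean_expr,
               bs_hat = bs_hat, m_hat = m_hat,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment with monotonicity enforcement, as applied
#' throughout the package whenever a test is repeated.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (empty input gives empty output).
#' @export
bhFDR <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    p.adjust(p, method = "BH")
}
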