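#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MixtureExperiment: a two-tissue mixture RNA-seq experiment with known truth
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the per-gene and
#' per-sample metadata the bundle-sheath/mesophyll mixture model needs.
#' `rowData` must carry the gene model (`length`, `mu_bs`, `mu_m`, `deg_sens`)
#' and `colData` the sample specification (`study_id`, `slice`, `label`,
#' `purity_bs`, `deg_severity`, `lib_size`). Objects produced by
#' [simulateCounts()] additionally carry `expected` (expected counts) and
#' `retention` (positional-degradation retention factors) assays.
#'
#' The mixture model: a sample with BS purity \eqn{\pi} and degradation
#' severity \eqn{d} observes gene g with expected relative signal
#' \eqn{e_g R_g}, where \eqn{e_g = \pi \mu_{BS,g} + (1-\pi)\mu_{M,g}} and
#' \eqn{R_g = (1 - e^{-d s_g})/(d s_g)} is the mean retained fraction of a
#' transcript whose positional survival decays exponentially from the 3' end
#' with gene-specific sensitivity \eqn{s_g}.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("MixtureExperiment", contains = "SummarizedExperiment")

.ME_ROW_COLS <- c("length", "mu_bs", "mu_m", "deg_sens")
.ME_COL_COLS <- c("study_id", "slice", "label", "purity_bs", "deg_severity",
                  "lib_size")
.SAMPLE_LABELS <- c("BS_e", "I_e", "M_e", "BS", "M", "unseparated")

setValidity("MixtureExperiment", function(object) {
    msg <- character()
    rd <- rowData(object)
    cd <- colData(object)
    miss <- setdiff(.ME_ROW_COLS, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    miss <- setdiff(.ME_COL_COLS, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(msg)) {
        if (any(rd$length < 1)) msg <- c(msg, "gene lengths must be >= 1")
        if (any(rd$mu_bs < 0) || any(rd$mu_m < 0))
            msg <- c(msg, "pure-tissue expression must be nonnegative")
        if (any(rd$deg_sens < 0))
            msg <- c(msg, "degradation sensitivity must be nonnegative")
        if (any(cd$purity_bs < 0 | cd$purity_bs > 1))
            msg <- c(msg, "purity_bs must lie in [0, 1]")
        if (any(cd$deg_severity < 0))
            msg <- c(msg, "deg_severity must be nonnegative")
        if (any(cd$lib_size <= 0))
            msg <- c(msg, "lib_size must be positive")
        if (!all(cd$label %in% .SAMPLE_LABELS))
            msg <- c(msg, paste0("sample labels must be one of: ",
                                 paste(.SAMPLE_LABELS, collapse = ", ")))
        if (!"counts" %in% names(assays(object)))
            msg <- c(msg, "a 'counts' assay is required")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MixtureExperiment
#'
#' @param counts integer matrix, genes x samples.
#' @param genes data.frame of gene models with columns `gene_id`, `length`,
#'   `mu_bs`, `mu_m`, `deg_sens`.
#' @param samples data.frame of sample specifications with columns
#'   `sample_id`, `study_id`, `slice`, `label`, `purity_bs`, `deg_severity`,
#'   `lib_size`.
#' @param ... further assays (e.g. `expected`, `retention`), matrices of the
#'   same dimension as `counts`.
#' @return A [MixtureExperiment-class] object.
#' @export
MixtureExperiment <- function(counts, genes, samples, ...) {
    stopifnot(is.matrix(counts),
              nrow(counts) == nrow(genes),
              ncol(counts) == nrow(samples))
    rd <- DataFrame(genes[setdiff(colnames(genes), "gene_id")],
                    row.names = genes$gene_id)
    cd <- DataFrame(samples[setdiff(colnames(samples), "sample_id")],
                    row.names = samples$sample_id)
    dimnames(counts) <- list(genes$gene_id, samples$sample_id)
    extra <- lapply(list(...), function(a) {
        dimnames(a) <- dimnames(counts)
        a
    })
    se <- SummarizedExperiment(
        assays = c(list(counts = counts), extra),
        rowData = rd, colData = cd)
    new("MixtureExperiment", se)
}

setMethod("show", "MixtureExperiment", function(object) {
    callNextMethod()
    cd <- colData(object)
    cat(sprintf("studies: %s\n",
                paste(unique(cd$study_id), collapse = ", ")))
    cat(sprintf("degradation severity range: [%.3g, %.3g]; BS purity range: [%.3g, %.3g]\n",
                min(cd$deg_severity), max(cd$deg_severity),
                min(cd$purity_bs), max(cd$purity_bs)))
})

#' Accessors for MixtureExperiment metadata
#'
#' `geneLengths`, `degSensitivity` return per-gene vectors; `purityBS`,
#' `degSeverity`, `librarySizes` return per-sample vectors; `geneModels` and
#' `sampleSpecs` return the full tables as data.frames.
#'
#' @param x A [MixtureExperiment-class].
#' @return Numeric vectors named by gene/sample, or data.frames.
#' @name mixture-accessors
#' @aliases geneLengths degSensitivity purityBS degSeverity librarySizes
#'   geneModels sampleSpecs
NULL

#' @rdname mixture-accessors
#' @export
geneLengths <- function(x) setNames(rowData(x)$length, rownames(x))

#' @rdname mixture-accessors
#' @export
degSensitivity <- function(x) setNames(rowData(x)$deg_sens, rownames(x))

#' @rdname mixture-accessors
#' @export
purityBS <- function(x) setNames(colData(x)$purity_bs, colnames(x))

#' @rdname mixture-accessors
#' @export
degSeverity <- function(x) setNames(colData(x)$deg_severity, colnames(x))

#' @rdname mixture-accessors
#' @export
librarySizes <- function(x) setNames(colData(x)$lib_size, colnames(x))

#' @rdname mixture-accessors
#' @export
geneModels <- function(x) {
    rd <- rowData(x)
    data.frame(gene_id = rownames(x), rd[, .ME_ROW_COLS, drop = FALSE])
}

#' @rdname mixture-accessors
#' @export
sampleSpecs <- function(x) {
    cd <- colData(x)
    data.frame(sample_id = colnames(x), cd[, .ME_COL_COLS, drop = FALSE])
}

#' DeconvResults: per-analyte tissue-specificity estimates
#'
#' A [S4Vectors::DataFrame] subclass holding, per analyte and developmental
#' slice, the regression slope (estimated fraction of the analyte located in
#' pure BS tissue), its standard error, the t statistic and p-value against
#' the 50/50 null, the number of regression points, and the reconstructed
#' pure-tissue abundances. Metadata records the marker identifiers used.
#'
#' @export
setClass("DeconvResults", contains = "DFrame")

.DECONV_COLS <- c("analyte_id", "slice", "slope_b", "se", "t_stat", "p_value",
                  "n_points", "bs_pure", "m_pure", "clamped")

setValidity("DeconvResults", function(object) {
    msg <- character()
    miss <- setdiff(.DECONV_COLS, colnames(object))
    if (length(miss))
        msg <- c(msg, paste0("missing column(s): ", paste(miss, collapse = ", ")))
    else {
        p <- object$p_value
        if (any(p < 0 | p > 1, na.rm = TRUE))
            msg <- c(msg, "p_value must lie in [0, 1]")
        if (any(object$n_points < 3, na.rm = TRUE))
            msg <- c(msg, "regressions need at least 3 points")
    }
    if (length(msg)) msg else TRUE
})

DeconvResults <- function(df, m_marker, bs_marker) {
    out <- new("DeconvResults", DataFrame(df))
    metadata(out)$m_marker <- m_marker
    metadata(out)$bs_marker <- bs_marker
    out
}

setMethod("show", "DeconvResults", function(object) {
    cat(sprintf("DeconvResults: %d analyte/slice estimates (markers M=%s, BS=%s)\n",
                nrow(object), metadata(object)$m_marker,
                metadata(object)$bs_marker))
    callNextMethod()
})
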