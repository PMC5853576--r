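#' @importFrom stats ave quantile sd
NULL

#' Transcripts per million
#'
#' \eqn{TPM_{gs} = 10^6 (c_{gs}/l_g) / \sum_g (c_{gs}/l_g)}: counts are
#' length-normalized, then each sample column is scaled to sum to one
#' million. All-zero genes get TPM 0; an all-zero sample column is an error.
#'
#' @param counts Count matrix (genes x samples) or a
#'   [MixtureExperiment-class].
#' @param lengths Per-gene lengths in nt; taken from `rowData` for a
#'   `MixtureExperiment`.
#' @return Numeric matrix of TPM values, same dimnames as `counts`.
#' @export
computeTPM <- function(counts, lengths = NULL) {
    if (is(counts, "SummarizedExperiment")) {
        if (is.null(lengths)) lengths <- rowData(counts)$length
        counts <- assay(counts, "counts")
    }
    stopifnot(is.matrix(counts), !is.null(lengths),
              length(lengths) == nrow(counts))
    if (any(lengths < 1)) stop("gene lengths must be >= 1")
    if (any(counts < 0)) stop("counts must be nonnegative")
    rate <- counts / lengths
    tot <- colSums(rate)
    if (any(tot == 0)) {
        bad <- colnames(counts)[tot == 0]
        if (is.null(bad)) bad <- which(tot == 0)
        stop("all-zero sample column(s): ", paste(bad, collapse = ", "))
    }
    sweep(rate, 2, tot, "/") * 1e6
}

#' Convert values to fraction of total within groups
#'
#' Within each group (typically analyte x slice x replicate, across the
#' enrichment fractions) values are divided by the group sum, so each group
#' sums to 1. Idempotent.
#'
#' @param values Positive numeric vector.
#' @param group Grouping factor/vector (or list of such, interacted).
#' @return Numeric vector of fractions, same order as `values`.
#' @export
fractionOfTotal <- function(values, group) {
    stopifnot(all(values >= 0))
    if (is.list(group)) group <- interaction(group, drop = TRUE)
    sums <- ave(values, group, FUN = sum)
    if (any(sums == 0)) stop("group with all-zero values")
    values / sums
}

#' Fraction-of-total conversion of an activity table
#'
#' Applies [fractionOfTotal()] across enrichment fractions, within each
#' analyte x slice x replicate.
#'
#' @param activity data.frame with columns `analyte_id`, `slice`,
#'   `fraction`, `replicate`, `value`.
#' @return The table with `value` replaced by fractions of total.
#' @export
fractionOfTotalActivity <- function(activity) {
    activity$value <- fractionOfTotal(
        activity$value,
        list(activity$analyte_id, activity$slice, activity$replicate))
    activity
}

#' Normalize GC-MS metabolite peaks
#'
#' Each integrated peak is divided by the internal-standard (ribitol) peak
#' area and the sample fresh weight, then by the mean normalized abundance
#' over all analytes of the same replicate (compensating fresh/dry weight
#' differences between cell fractions). After the second step the mean over
#' analytes within each replicate is exactly 1: values are relative to the
#' other metabolites, not absolute.
#'
#' @param peaks data.frame with columns `analyte_id`, `replicate` (any
#'   further grouping columns such as `slice`/`fraction` may be folded into
#'   `replicate`), `peak`, `ribitol`, `fresh_weight`.
#' @return The table with a `value` column of normalized abundances.
#' @export
normalizeMetabolitePeaks <- function(peaks) {
    stopifnot(all(c("analyte_id", "replicate", "peak", "ribitol",
                    "fresh_weight") %in% colnames(peaks)))
    if (any(peaks$ribitol <= 0)) stop("ribitol peak areas must be positive")
    if (any(peaks$fresh_weight <= 0)) stop("fresh weights must be positive")
    v1 <- peaks$peak / (peaks$ribitol * peaks$fresh_weight)
    repmean <- ave(v1, peaks$replicate, FUN = mean)
    peaks$value <- v1 / repmean
    peaks
}

#' Filter low-signal analytes and outlier replicates
#'
#' Two documented exclusion rules, applied in order: (1) analytes whose
#' maximum value is below `min_signal` (default: the bottom 5% quantile of
#' per-analyte maxima) are dropped; (2) within each analyte x slice,
#' replicates whose percentage abundance in BS — computed as
#' `BS_e / (BS_e + M_e)` — lies more than `k_sd` standard deviations from
#' the mean of the other replicates are dropped (all fractions of that
#' replicate). The leave-one-out form is used because with the candidate
#' included a replicate of a small group can never reach `k_sd` SDs
#' (max |z| is `(n-1)/sqrt(n)`). A zero SD (identical remaining replicates)
#' excludes nothing; groups of fewer than 3 replicates are never filtered.
#'
#' @param activity data.frame with columns `analyte_id`, `slice`,
#'   `fraction`, `replicate`, `value`.
#' @param min_signal Absolute low-signal threshold; `NULL` uses the
#'   `signal_quantile` quantile of per-analyte maxima.
#' @param k_sd SD multiple for the outlier rule (default 3).
#' @param signal_quantile Quantile used when `min_signal` is `NULL`.
#' @return list(`table` = filtered table, `log` = data.frame of exclusions
#'   with columns `analyte_id`, `slice`, `replicate`, `reason`).
#' @export
filterMetabolites <- function(activity, min_signal = NULL, k_sd = 3,
                              signal_quantile = 0.05) {
    log <- data.frame(analyte_id = character(), slice = integer(),
                      replicate = integer(), reason = character(),
                      stringsAsFactors = FALSE)
    maxima <- tapply(activity$value, activity$analyte_id, max)
    if (is.null(min_signal))
        min_signal <- unname(quantile(maxima, signal_quantile))
    low <- names(maxima)[maxima < min_signal]
    if (length(low)) {
        log <- rbind(log, data.frame(
            analyte_id = low, slice = NA_integer_, replicate = NA_integer_,
            reason = "low_signal", stringsAsFactors = FALSE))
        activity <- activity[!activity$analyte_id %in% low, , drop = FALSE]
    }
    ## percentage abundance in BS per (analyte, slice, replicate)
    wide <- activity[activity$fraction %in% c("BS_e", "M_e"), ]
    if (nrow(wide)) {
        key <- interaction(wide$analyte_id, wide$slice, wide$replicate,
                           drop = TRUE)
        bs <- tapply(wide$value[wide$fraction == "BS_e"],
                     key[wide$fraction == "BS_e"], sum)
        mm <- tapply(wide$value[wide$fraction == "M_e"],
                     key[wide$fraction == "M_e"], sum)
        common <- intersect(names(bs), names(mm))
        pct <- bs[common] / (bs[common] + mm[common])
        info <- unique(data.frame(
            key = as.character(key),
            analyte_id = wide$analyte_id, slice = wide$slice,
            replicate = wide$replicate, stringsAsFactors = FALSE))
        info <- info[match(common, info$key), ]
        info$pct <- as.numeric(pct)
        grp <- interaction(info$analyte_id, info$slice, drop = TRUE)
        ## leave-one-out mean/SD: with the candidate included, a small
        ## replicate group could never reach k SDs (max |z| = (n-1)/sqrt(n))
        out <- logical(nrow(info))
        for (g in levels(grp)) {
            idx <- which(grp == g)
            if (length(idx) < 3) next
            for (i in idx) {
                rest <- info$pct[setdiff(idx, i)]
                s0 <- sd(rest)
                if (!is.na(s0) && s0 > 0 &&
                    abs(info$pct[i] - mean(rest)) > k_sd * s0)
                    out[i] <- TRUE
            }
        }
        if (any(out)) {
            bad <- info[out, c("analyte_id", "slice", "replicate")]
            bad$reason <- "bs_percentage_outlier"
            log <- rbind(log, bad)
            drop <- paste(activity$analyte_id, activity$slice,
                          activity$replicate) %in%
                    paste(bad$analyte_id, bad$slice, bad$replicate)
            activity <- activity[!drop, , drop = FALSE]
        }
    }
    rownames(log) <- NULL
    list(table = activity, log = log)
}
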