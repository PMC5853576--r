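#' @importFrom utils read.delim read.csv write.table write.csv head
#' @importFrom rtracklayer import export
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

## All tabular outputs: TSV/CSV with header, "." as the NA token, decimal
## point, no quoting, no row names.
.writeTable <- function(x, path, sep = "\t") {
    write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE,
                na = ".")
    invisible(path)
}

.noDup <- function(ids, what) {
    d <- duplicated(ids)
    if (any(d)) {
        i <- which(d)[1]
        stop("duplicated ", what, " '", ids[i], "' (line ", i + 1L, ")")
    }
}

#' Read / write a counts table
#'
#' TSV with a `gene_id` column followed by one integer column per sample.
#'
#' @param path File path.
#' @return `readCounts`: list(`counts` = integer matrix, `gene_ids`,
#'   `sample_ids`).
#' @export
readCounts <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(df)[1] != "gene_id") stop("first column must be 'gene_id'")
    .noDup(df$gene_id, "gene id")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
        bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
        stop("non-numeric counts in column '", colnames(df)[-1][bad], "'")
    }
    if (any(m < 0)) stop("negative counts")
    rownames(m) <- df$gene_id
    list(counts = m, gene_ids = df$gene_id, sample_ids = colnames(m))
}

#' @rdname readCounts
#' @param counts Matrix with gene rownames.
#' @export
writeCounts <- function(counts, path) {
    .writeTable(data.frame(gene_id = rownames(counts), counts,
                           check.names = FALSE), path)
}

#' Read / write a gene-length table (TSV: gene_id, length)
#' @param path File path.
#' @return Named integer vector of lengths.
#' @export
readGeneLengths <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "length") %in% colnames(df)))
    .noDup(df$gene_id, "gene id")
    if (any(df$length < 1)) stop("lengths must be >= 1")
    setNames(as.integer(df$length), df$gene_id)
}

#' @rdname readGeneLengths
#' @param lengths Named integer vector.
#' @export
writeGeneLengths <- function(lengths, path) {
    .writeTable(data.frame(gene_id = names(lengths),
                           length = as.integer(lengths)), path)
}

#' Read / write a sample sheet (CSV)
#'
#' Columns: `sample_id`, `study_id`, `slice`, `label`, `purity_bs`,
#' `deg_severity`, `lib_size`. Labels are validated against the supported
#' enrichment/tissue labels.
#' @param path File path.
#' @return data.frame of sample specifications.
#' @export
readSampleSheet <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "study_id", "slice", "label", "purity_bs",
              "deg_severity", "lib_size")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("sample sheet lacks: ", paste(miss, collapse = ", "))
    .noDup(df$sample_id, "sample id")
    bad <- !df$label %in% .SAMPLE_LABELS
    if (any(bad))
        stop("unknown fraction label '", df$label[bad][1], "' (line ",
             which(bad)[1] + 1L, ")")
    df
}

#' @rdname readSampleSheet
#' @param samples data.frame of sample specifications.
#' @export
writeSampleSheet <- function(samples, path) {
    write.csv(samples, path, row.names = FALSE, quote = FALSE, na = ".")
    invisible(path)
}

#' Read / write an activity/abundance table (CSV)
#'
#' Columns: `analyte_id`, `slice`, `fraction`, `replicate`, `value`.
#' @param path File path.
#' @return data.frame.
#' @export
readActivity <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("analyte_id", "slice", "fraction", "replicate", "value")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("activity table lacks: ", paste(miss, collapse = ", "))
    if (!is.numeric(df$value)) stop("non-numeric 'value' column")
    df
}

#' @rdname readActivity
#' @param activity data.frame.
#' @export
writeActivity <- function(activity, path) {
    write.csv(activity, path, row.names = FALSE, quote = FALSE, na = ".")
    invisible(path)
}

#' Read / write long-form coverage (TSV: gene_id, pos, depth; pos 0-based 5'->3')
#' @param path File path.
#' @param sample_id Sample the file belongs to (recorded in the result).
#' @return Long coverage data.frame (`gene_id`, `sample_id`, `pos`, `depth`).
#' @export
readCoverageTSV <- function(path, sample_id = NA_character_) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "pos", "depth") %in% colnames(df)))
    if (any(df$depth < 0)) stop("negative depth")
    data.frame(gene_id = df$gene_id, sample_id = sample_id, pos = df$pos,
               depth = df$depth, stringsAsFactors = FALSE)
}

#' @rdname readCoverageTSV
#' @param coverage Long coverage data.frame.
#' @export
writeCoverageTSV <- function(coverage, path) {
    .writeTable(coverage[, c("gene_id", "pos", "depth")], path)
}

#' Write coverage profiles as bedGraph
#'
#' One synthetic "chromosome" per gene (named by the gene id); 0-based
#' half-open intervals; consecutive equal depths are collapsed into runs.
#' Profiles are stored 5' to 3'; minus-strand genes are written reversed so
#' the file is in genomic orientation, and flipped back on reading.
#'
#' @param profiles Named list of coverage vectors (one per gene), 5' to 3'.
#' @param path Output path.
#' @param strand Named character vector ("+"/"-") per gene; default all "+".
#' @return The path, invisibly.
#' @export
writeBedGraphCoverage <- function(profiles, path, strand = NULL) {
    rows <- lapply(names(profiles), function(g) {
        cov <- profiles[[g]]
        if (!is.null(strand) && strand[[g]] == "-") cov <- rev(cov)
        r <- rle(cov)
        ends <- cumsum(r$lengths)
        data.frame(chrom = g, start = ends - r$lengths, end = ends,
                   depth = r$values, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read bedGraph coverage into per-gene 5'->3' profiles
#'
#' Uses the standard bedGraph importer; intervals are expanded to per-base
#' depth. A per-gene strand map orients each profile 5' to 3' (minus-strand
#' genes are reversed). Positions not covered by any interval get depth 0,
#' out to `lengths[gene]` when provided.
#'
#' @param path bedGraph file (chrom = gene id, 0-based half-open).
#' @param strand Named character vector ("+"/"-") per gene; default "+".
#' @param lengths Optional named gene lengths (otherwise the max end seen).
#' @return Named list of numeric coverage vectors, 5' to 3'.
#' @export
readBedGraphCoverage <- function(path, strand = NULL, lengths = NULL) {
    gr <- import(path, format = "bedGraph")
    genes <- unique(as.character(seqnames(gr)))
    out <- lapply(genes, function(g) {
        x <- gr[as.character(seqnames(gr)) == g]
        L <- if (!is.null(lengths)) lengths[[g]] else max(end(x))
        cov <- numeric(L)
        for (i in seq_along(x)) {
            cov[(start(x)[i]):(end(x)[i])] <- x$score[i]
        }
        if (!is.null(strand) && strand[[g]] == "-") cov <- rev(cov)
        cov
    })
    names(out) <- genes
    out
}

#' Read a category map (TSV: gene_id, category dot-path; multiple rows per
#' gene allowed)
#' @param path File path.
#' @return data.frame(`gene_id`, `category`).
#' @export
readCategoryMap <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "category") %in% colnames(df)))
    df[, c("gene_id", "category")]
}

#' Read an ortholog map (TSV: source_id, target_id; one-to-one)
#' @param path File path.
#' @return Named character vector source -> target.
#' @export
readOrthologMap <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("source_id", "target_id") %in% colnames(df)))
    .noDup(df$source_id, "source gene id")
    setNames(df$target_id, df$source_id)
}

#' Read / write a StudyResult table (TSV)
#' @param path File path.
#' @return data.frame (see [studyResult()]).
#' @export
readStudyResult <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
    .checkStudyResult(df)
}

#' @rdname readStudyResult
#' @param res StudyResult data.frame.
#' @export
writeStudyResult <- function(res, path) {
    .writeTable(.checkStudyResult(res), path)
}
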