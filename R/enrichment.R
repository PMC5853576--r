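#' @importFrom stats fisher.test p.adjust
NULL

#' Expand dot-path categories to include all ancestors
#'
#' MapMan-style category paths are dot separated
#' (`protein.synthesis.ribosomal protein`); a gene annotated to a category
#' belongs to that category and every parental category.
#'
#' @param categories Character vector of dot-path categories.
#' @return Character vector of unique categories including all ancestors.
#' @export
expandCategoryPaths <- function(categories) {
    unique(unlist(lapply(categories, function(p) {
        parts <- strsplit(p, ".", fixed = TRUE)[[1]]
        vapply(seq_along(parts), function(i)
            paste(parts[seq_len(i)], collapse = "."), character(1))
    })))
}

#' Fisher exact functional category enrichment
#'
#' Tests each category of a gene->category map for over/under
#' representation in a query set against a universe, with a two-sided
#' Fisher exact test and BH FDR across all tested categories of the query.
#' Genes annotated to several categories count in each; with
#' `hierarchical = TRUE` (default) every gene also counts towards all
#' parental categories of its annotations.
#'
#' @param gene_set Query gene ids (subset of `universe`).
#' @param category_map data.frame with columns `gene_id`, `category`
#'   (dot-path; multiple rows per gene allowed).
#' @param universe Universe gene ids (typically the detected genes).
#' @param min_category Minimum category size in the universe (smaller
#'   categories are skipped).
#' @param hierarchical Propagate annotations to parental categories.
#' @return data.frame with one row per tested category: `category`, `k`
#'   (set members in category), `K` (category size in universe), `n` (set
#'   size), `N` (universe size), `odds_ratio`, `p_value`, `fdr`.
#' @export
fisherEnrichment <- function(gene_set, category_map, universe,
                             min_category = 1L, hierarchical = TRUE) {
    if (length(universe) == 0) stop("empty universe")
    universe <- unique(universe)
    gene_set <- unique(gene_set)
    stopifnot(all(gene_set %in% universe))
    map <- category_map[category_map$gene_id %in% universe, ]
    if (hierarchical) {
        by_gene <- split(map$category, map$gene_id)
        expanded <- lapply(by_gene, expandCategoryPaths)
        map <- data.frame(
            gene_id = rep(names(expanded), lengths(expanded)),
            category = unlist(expanded, use.names = FALSE),
            stringsAsFactors = FALSE)
    }
    map <- unique(map[, c("gene_id", "category")])
    N <- length(universe); n <- length(gene_set)
    sizes <- table(map$category)
    cats <- names(sizes)[sizes >= min_category]
    in_set <- map$gene_id %in% gene_set
    k_tab <- table(factor(map$category[in_set], levels = cats))
    rows <- lapply(cats, function(cat) {
        K <- as.integer(sizes[[cat]])
        k <- as.integer(k_tab[[cat]])
        tab <- matrix(c(k, n - k, K - k, N - n - K + k), 2, 2)
        ft <- fisher.test(tab, alternative = "two.sided")
        data.frame(category = cat, k = k, K = K, n = n, N = N,
                   odds_ratio = unname(ft$estimate), p_value = ft$p.value,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(category = character(), k = integer(),
                          K = integer(), n = integer(), N = integer(),
                          odds_ratio = numeric(), p_value = numeric(),
                          fdr = numeric(), stringsAsFactors = FALSE))
    out$fdr <- p.adjust(out$p_value, method = "BH")
    out <- out[order(out$p_value), ]
    rownames(out) <- NULL
    out
}
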