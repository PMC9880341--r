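## Over-representation analysis of predicted partner-gene sets against a
## GMT collection, via the hypergeometric upper tail with BH correction.

#' Hypergeometric gene-set enrichment of a query gene set
#'
#' For each set in the collection, computes the upper-tail hypergeometric
#' p-value of the overlap between \code{query} and the set, both restricted
#' to \code{universe}, then Benjamini-Hochberg-adjusts across sets. The
#' universe should be the gene space the screen actually tested (the
#' sampling frame of the query set), not the whole genome.
#'
#' @param query character vector of genes of interest (e.g. predicted
#'   synthetic-lethal partners). Genes outside the universe are dropped
#'   with a reported count.
#' @param collection gene-set collection from [readGeneSets()], or a named
#'   list of character vectors.
#' @param universe character vector of all genes that could have been
#'   selected.
#' @return data.frame with one row per set: \code{set_name}, overlap
#'   \code{k}, set size \code{K} (within the universe), query size
#'   \code{n}, universe size \code{N}, \code{p_value}, \code{q_value},
#'   \code{overlap_genes}; sorted by q then p then set name.
#' @examples
#' sets <- list(repair = list(description = "", genes = c("BRCA1", "BRCA2")))
#' enrichGeneSets(c("BRCA2", "TP53"), sets,
#'                universe = c("BRCA1", "BRCA2", "TP53", "EGFR"))
#' @export
enrichGeneSets <- function(query, collection, universe) {
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("enrichGeneSets: empty universe")
    query <- unique(as.character(query))
    outside <- setdiff(query, universe)
    if (length(outside))
        message("enrichGeneSets: dropped ", length(outside),
                " query gene(s) outside the universe")
    query <- intersect(query, universe)
    if (!length(query))
        stop("enrichGeneSets: no query genes left after restricting to ",
             "the universe")
    N <- length(universe); n <- length(query)
    rows <- lapply(names(collection), function(nm) {
        members <- collection[[nm]]
        if (is.list(members)) members <- members$genes
        members <- intersect(unique(members), universe)
        hits <- intersect(members, query)
        data.frame(set_name = nm, k = length(hits), K = length(members),
            n = n, N = N,
            p_value = hypergeomTail(N, length(members), n, length(hits)),
            q_value = NA_real_,
            overlap_genes = paste(sort(hits), collapse = ";"),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q_value <- bhAdjust(out$p_value)
    out <- out[order(out$q_value, out$p_value, out$set_name), , drop = FALSE]
    rownames(out) <- NULL
    out
}
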