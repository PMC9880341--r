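## CGI: conserved-genetic-interaction workflow. Negative genetic
## interactions (double-mutant fitness below the multiplicative single-
## mutant expectation) are called from a yeast SGA pairwise table and
## transferred to human candidate pairs through a yeast-to-human ortholog
## map.

.unorderedKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Filter a yeast SGA table down to negative genetic interactions
#'
#' Keeps records with epsilon at or below \code{epsMax} and p-value at or
#' below \code{pMax}. When an unordered yeast pair (after strain-suffix
#' stripping) appears more than once, the record with the most negative
#' epsilon is kept.
#'
#' @param table yeast-interaction data.frame
#'   (see [readYeastInteractions()]).
#' @param epsMax epsilon cutoff, must be negative (default -0.12, the
#'   stringent SGA negative-interaction convention).
#' @param pMax p-value cutoff (default 0.05).
#' @return Filtered, deduplicated yeast-interaction data.frame.
#' @export
filterNegativeInteractions <- function(table, epsMax = -0.12, pMax = 0.05) {
    if (!is.finite(epsMax) || epsMax >= 0)
        stop("epsMax must be negative: a non-negative cutoff contradicts ",
             "a negative genetic interaction")
    if (!is.finite(pMax)) stop("pMax must be finite")
    table <- validateYeastInteractions(table)
    keep <- table$epsilon <= epsMax & table$p_value <= pMax
    out <- table[keep, , drop = FALSE]
    if (!nrow(out)) return(out)
    key <- .unorderedKey(stripStrainSuffix(out$query_gene),
                         stripStrainSuffix(out$array_gene))
    ord <- order(key, out$epsilon)   # most negative epsilon first per pair
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(key[ord]), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Map yeast interaction pairs to human candidate pairs
#'
#' Strips strain/allele suffixes, expands each yeast pair to the cross
#' product of its members' ortholog sets, drops pairs with an unmapped
#' member (count reported) and self-pairs arising after mapping, and
#' deduplicates unordered human pairs while merging source-pair provenance.
#'
#' @param pairs yeast-interaction data.frame (typically the output of
#'   [filterNegativeInteractions()]).
#' @param orthologs named list, yeast symbol -> character vector of human
#'   symbols (see [readOrthologMap()]).
#' @return data.frame with columns \code{gene_a}, \code{gene_b}
#'   (canonicalized \code{gene_a < gene_b}), \code{n_source_pairs},
#'   \code{min_epsilon}, \code{min_p}, \code{source_pairs} (collapsed
#'   \code{query|array|epsilon|p} strings), sorted canonically.
#' @export
mapToHuman <- function(pairs, orthologs) {
    empty <- data.frame(gene_a = character(), gene_b = character(),
        n_source_pairs = integer(), min_epsilon = numeric(),
        min_p = numeric(), source_pairs = character(),
        stringsAsFactors = FALSE)
    if (!nrow(pairs)) return(empty)
    q <- stripStrainSuffix(pairs$query_gene)
    a <- stripStrainSuffix(pairs$array_gene)
    unmapped <- 0L
    recs <- list()
    for (i in seq_len(nrow(pairs))) {
        hq <- orthologs[[q[i]]]; ha <- orthologs[[a[i]]]
        if (is.null(hq) || is.null(ha) || !length(hq) || !length(ha)) {
            unmapped <- unmapped + 1L
            next
        }
        grid <- expand.grid(h1 = hq, h2 = ha, stringsAsFactors = FALSE)
        grid <- grid[grid$h1 != grid$h2, , drop = FALSE]  # drop self-pairs
        if (!nrow(grid)) next
        recs[[length(recs) + 1L]] <- data.frame(
            gene_a = pmin(grid$h1, grid$h2),
            gene_b = pmax(grid$h1, grid$h2),
            epsilon = pairs$epsilon[i], p = pairs$p_value[i],
            src = sprintf("%s|%s|%.6g|%.6g", pairs$query_gene[i],
                pairs$array_gene[i], pairs$epsilon[i], pairs$p_value[i]),
            stringsAsFactors = FALSE)
    }
    if (unmapped)
        message("mapToHuman: dropped ", unmapped,
                " pair(s) with an unmapped member")
    if (!length(recs)) return(empty)
    all <- do.call(rbind, recs)
    key <- paste(all$gene_a, all$gene_b, sep = "\r")
    agg <- lapply(split(seq_len(nrow(all)), key), function(idx) {
        src <- unique(all$src[idx])
        data.frame(gene_a = all$gene_a[idx[1L]], gene_b = all$gene_b[idx[1L]],
            n_source_pairs = length(src),
            min_epsilon = min(all$epsilon[idx]), min_p = min(all$p[idx]),
            source_pairs = paste(sort(src), collapse = ";"),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' CGI prediction: filter negative interactions, then map to human
#'
#' @inheritParams filterNegativeInteractions
#' @inheritParams mapToHuman
#' @return Canonically sorted human candidate-pair data.frame, see
#'   [mapToHuman()].
#' @export
cgiPredict <- function(table, orthologs, epsMax = -0.12, pMax = 0.05) {
    mapToHuman(filterNegativeInteractions(table, epsMax, pMax), orthologs)
}
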