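## Binary molecular-state calling: functional-mutation masks from MAF-like
## records, and inactivation / overactivation calls from expression + copy
## number. These masks condition every DAISY and MDSLP test.

#' Default set of damaging (functional) variant classes
#'
#' Variant classifications presumed to alter protein expression or
#' structure. Silent, UTR, intronic and intergenic classes are excluded.
#' Fully overridable wherever a damaging set is accepted.
#'
#' @return Character vector of MAF variant-classification tokens.
#' @export
damagingClasses <- function() {
    c("Nonsense_Mutation", "Missense_Mutation", "Frame_Shift_Del",
      "Frame_Shift_Ins", "Splice_Site", "Nonstop_Mutation",
      "Start_Codon_SNP", "Start_Codon_Del", "Start_Codon_Ins",
      "De_novo_Start_OutOfFrame")
}

#' Functional-mutation mask
#'
#' Marks (sample, gene) TRUE when the mutation table holds at least one
#' record for that cell whose classification is in \code{damaging}.
#' Duplicate records collapse to one event; records outside the given
#' sample/gene universe are ignored (count reported via \code{message()}).
#'
#' @param mutations data.frame with columns \code{sample}, \code{gene},
#'   \code{classification} (see [readMutationTable()]).
#' @param samples,genes the cohort universe the mask is defined over.
#' @param damaging classification tokens that count as functional; defaults
#'   to [damagingClasses()].
#' @return A [StateMatrix-class] of kind \code{"functional_mutation"}.
#' @export
functionalMutationMask <- function(mutations, samples, genes,
                                   damaging = damagingClasses()) {
    if (!length(damaging))
        stop("functionalMutationMask: 'damaging' must be non-empty")
    samples <- as.character(samples); genes <- as.character(genes)
    m <- matrix(FALSE, length(samples), length(genes),
                dimnames = list(samples, genes))
    if (nrow(mutations)) {
        hit <- mutations$classification %in% damaging
        rec <- mutations[hit, , drop = FALSE]
        inside <- rec$sample %in% samples & rec$gene %in% genes
        if (any(!inside))
            message("functionalMutationMask: ignored ", sum(!inside),
                    " record(s) outside the sample/gene universe")
        rec <- rec[inside, , drop = FALSE]
        m[cbind(rec$sample, rec$gene)] <- TRUE
    }
    StateMatrix(m, "functional_mutation",
        provenance = list(damaging = damaging))
}

.sharedUniverse <- function(layers) {
    samples <- Reduce(intersect, lapply(layers, sampleNames))
    genes <- Reduce(intersect, lapply(layers, geneNames))
    if (!length(samples))
        stop("empty sample intersection across input layers")
    if (!length(genes))
        stop("empty gene intersection across input layers")
    list(samples = samples, genes = genes)
}

## Per-gene percentile cutoffs (linear-interpolation quantiles, computed on
## the analyzed sample subset so tissue-restricted runs are self-contained).
.geneQuantiles <- function(values, prob) {
    apply(values, 2L, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) return(NA_real_)
        unname(stats::quantile(col, prob, type = 7))
    })
}

#' Gene-inactivation mask
#'
#' A gene is called inactive in a sample when it carries a functional
#' mutation, or when its expression falls strictly below the gene's
#' \code{exprPercentile} quantile across the analyzed samples while its copy
#' number lies below \code{cnMax}. Missing omics values never satisfy a
#' clause.
#'
#' @param expr expression [OmicsMatrix-class].
#' @param cn copy-number [OmicsMatrix-class].
#' @param mut optional [StateMatrix-class] of functional mutations; NULL if
#'   no mutation data are available.
#' @param exprPercentile percentile (0-100) defining "low expression";
#'   default 10.
#' @param cnMax copy-number (log2 ratio) upper bound for the loss clause;
#'   default -0.3.
#' @return A [StateMatrix-class] of kind \code{"inactive"}; provenance
#'   records the thresholds.
#' @export
inactivationMask <- function(expr, cn, mut = NULL, exprPercentile = 10,
                             cnMax = -0.3) {
    stopifnot(is(expr, "OmicsMatrix"), is(cn, "OmicsMatrix"))
    layers <- list(expr, cn)
    if (!is.null(mut)) layers <- c(layers, list(mut))
    uni <- .sharedUniverse(layers)
    e <- omicsValues(expr)[uni$samples, uni$genes, drop = FALSE]
    c2 <- omicsValues(cn)[uni$samples, uni$genes, drop = FALSE]
    cut <- .geneQuantiles(e, exprPercentile / 100)
    lowExpr <- sweep(e, 2L, cut, `<`)
    lowExpr[is.na(lowExpr)] <- FALSE
    lowCn <- c2 < cnMax
    lowCn[is.na(lowCn)] <- FALSE
    calls <- lowExpr & lowCn
    if (!is.null(mut))
        calls <- calls | stateValues(mut)[uni$samples, uni$genes, drop = FALSE]
    StateMatrix(calls, "inactive",
        provenance = list(exprPercentile = exprPercentile, cnMax = cnMax,
                          withMutations = !is.null(mut),
                          nSamples = length(uni$samples)))
}

#' Gene-overactivation mask
#'
#' The synthetic-dosage-lethality counterpart of [inactivationMask()]: a
#' gene is overactive in a sample when its expression lies strictly above
#' the gene's \code{100 - exprPercentile} quantile and its copy number is
#' above \code{cnMin}.
#'
#' @inheritParams inactivationMask
#' @param cnMin copy-number lower bound for the gain clause; default +0.3.
#' @return A [StateMatrix-class] of kind \code{"overactive"}.
#' @export
overactivationMask <- function(expr, cn, exprPercentile = 10, cnMin = 0.3) {
    stopifnot(is(expr, "OmicsMatrix"), is(cn, "OmicsMatrix"))
    uni <- .sharedUniverse(list(expr, cn))
    e <- omicsValues(expr)[uni$samples, uni$genes, drop = FALSE]
    c2 <- omicsValues(cn)[uni$samples, uni$genes, drop = FALSE]
    cut <- .geneQuantiles(e, 1 - exprPercentile / 100)
    hiExpr <- sweep(e, 2L, cut, `>`)
    hiExpr[is.na(hiExpr)] <- FALSE
    hiCn <- c2 > cnMin
    hiCn[is.na(hiCn)] <- FALSE
    StateMatrix(hiExpr & hiCn, "overactive",
        provenance = list(exprPercentile = exprPercentile, cnMin = cnMin,
                          nSamples = length(uni$samples)))
}
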