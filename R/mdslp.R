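## MDSLP: mutation-dependent synthetic lethality prediction. For a mutated
## query gene, test whether knockout/knockdown of a partner gene is more
## deleterious in functionally mutated cell lines than in wild-type lines
## (two-sided Welch t-test; a negative delta supports synthetic lethality).

.mdslpRow <- function(mutGene, partner, context, dataset, res = NULL,
                      nMut = NA_integer_, nWT = NA_integer_, note = "") {
    if (is.null(res)) {
        data.frame(mutated_gene = mutGene, partner_gene = partner,
            context = context, dataset = dataset, t_statistic = NA_real_,
            delta = NA_real_, p_value = NA_real_, q_value = NA_real_,
            n_mutant = nMut, n_wildtype = nWT, testable = FALSE,
            significant = FALSE, note = note, stringsAsFactors = FALSE)
    } else {
        data.frame(mutated_gene = mutGene, partner_gene = partner,
            context = context, dataset = dataset,
            t_statistic = res$statistic, delta = res$estimate,
            p_value = res$p.value, q_value = NA_real_,
            n_mutant = res$n.a, n_wildtype = res$n.b, testable = TRUE,
            significant = FALSE,
            note = if (isTRUE(res$degenerate)) "degenerate variances" else note,
            stringsAsFactors = FALSE)
    }
}

#' Mutation-conditional dependency test for one pair
#'
#' Welch two-sided t-test of the partner gene's dependency score between
#' cell lines carrying a functional mutation of \code{mutGene} and
#' wild-type lines. \code{delta = mean(mutant) - mean(wild-type)}; a
#' negative delta means the partner is more essential in the mutated
#' background, the direction that supports synthetic lethality.
#'
#' @param mutGene the mutated query gene.
#' @param partner the partner gene scored in the dependency screen.
#' @param mutMask [StateMatrix-class] of functional-mutation calls.
#' @param effect gene-effect [OmicsMatrix-class] (CRISPR or shRNA).
#' @param annotation optional named character vector sample -> cancer type;
#'   required when \code{context} is given.
#' @param context optional cancer-type label restricting the cohort;
#'   NULL = pan-cancer.
#' @param dataset dataset label carried into the result.
#' @param minMut,minWT minimum mutant / wild-type group sizes (default 3);
#'   smaller groups yield an untestable row.
#' @return One-row data.frame (pair, context, t, delta, p, group sizes,
#'   testable flag).
#' @export
mdslpTest <- function(mutGene, partner, mutMask, effect, annotation = NULL,
                      context = NULL, dataset = "gene_effect",
                      minMut = 3L, minWT = 3L) {
    ctxLabel <- if (is.null(context)) "pan-cancer" else context
    v <- omicsValues(effect)
    if (!partner %in% colnames(v) || !mutGene %in% geneNames(mutMask))
        return(.mdslpRow(mutGene, partner, ctxLabel, dataset,
            note = "gene absent from inputs"))
    shared <- intersect(rownames(v), sampleNames(mutMask))
    if (!is.null(context)) {
        if (is.null(annotation))
            stop("mdslpTest: a sample annotation is required for ",
                 "context-restricted tests")
        shared <- shared[shared %in%
            names(annotation)[annotation == context]]
    }
    if (!length(shared))
        return(.mdslpRow(mutGene, partner, ctxLabel, dataset,
            nMut = 0L, nWT = 0L, note = "no samples in context"))
    flag <- stateValues(mutMask)[shared, mutGene]
    vals <- v[shared, partner]
    keep <- !is.na(vals)
    mutVals <- vals[keep & flag]; wtVals <- vals[keep & !flag]
    if (length(mutVals) < minMut || length(wtVals) < minWT)
        return(.mdslpRow(mutGene, partner, ctxLabel, dataset,
            nMut = length(mutVals), nWT = length(wtVals),
            note = sprintf("group sizes %d/%d below minima %d/%d",
                length(mutVals), length(wtVals), minMut, minWT)))
    res <- welchTTest(mutVals, wtVals, "two.sided")
    .mdslpRow(mutGene, partner, ctxLabel, dataset, res)
}

#' MDSLP screen over mutated genes, partners, datasets and contexts
#'
#' Runs [mdslpTest()] for every combination of mutated gene, candidate
#' partner, gene-effect dataset and context, then applies Benjamini-
#' Hochberg correction within each (context, dataset) family and flags
#' results with q at or below \code{qThreshold} as significant.
#'
#' @param mutGenes character vector of mutated query genes.
#' @param partners candidate partner genes (self-pairs are skipped).
#' @param mutMask [StateMatrix-class] of functional-mutation calls.
#' @param effects named list of gene-effect [OmicsMatrix-class] objects
#'   (e.g. \code{list(CRISPR = ..., shRNA = ...)}); a bare OmicsMatrix is
#'   accepted.
#' @param annotation optional named sample -> cancer-type vector.
#' @param contexts character vector of contexts; \code{"pan-cancer"} (the
#'   default) uses all samples. Unknown labels raise an error listing the
#'   known ones.
#' @param qThreshold significance cutoff on q (default 0.05).
#' @param minMut,minWT group-size minima.
#' @return data.frame of per-pair results, one row per
#'   (pair, context, dataset), with q-values and significance flags.
#' @export
mdslpScreen <- function(mutGenes, partners, mutMask, effects,
                        annotation = NULL, contexts = "pan-cancer",
                        qThreshold = 0.05, minMut = 3L, minWT = 3L) {
    if (is(effects, "OmicsMatrix"))
        effects <- list(gene_effect = effects)
    stopifnot(is.list(effects), length(effects) >= 1L)
    if (is.null(names(effects)) || any(!nzchar(names(effects))))
        stop("mdslpScreen: 'effects' must be a named list of datasets")
    known <- if (is.null(annotation)) character() else unique(annotation)
    bad <- setdiff(contexts, c("pan-cancer", known))
    if (length(bad))
        stop("unknown context(s) ", paste(bad, collapse = ", "),
             "; known: ", paste(sort(known), collapse = ", "))
    rows <- list()
    for (ctx in contexts) {
        ctxArg <- if (identical(ctx, "pan-cancer")) NULL else ctx
        for (label in names(effects)) {
            for (mg in mutGenes) {
                for (pt in setdiff(partners, mg)) {
                    rows[[length(rows) + 1L]] <- mdslpTest(mg, pt, mutMask,
                        effects[[label]], annotation, ctxArg, label,
                        minMut, minWT)
                }
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    for (fam in split(seq_len(nrow(out)),
                      list(out$context, out$dataset), drop = TRUE)) {
        idx <- fam[out$testable[fam]]
        if (length(idx)) out$q_value[idx] <- bhAdjust(out$p_value[idx])
    }
    out$significant <- out$testable & !is.na(out$q_value) &
        out$q_value <= qThreshold
    out
}
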