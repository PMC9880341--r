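## DAISY: three inference procedures and their intersection.
##   SoF  - partner copy number shifted up in query-inactivated samples
##          (co-loss depleted in surviving populations)
##   FunEx - partner gene-effect shifted down (more essential) in
##          query-inactivated cell lines
##   Co-expression - positive Spearman correlation of the pair
## SL mode conditions on inactivation; SDL mode on overactivation (and the
## SoF alternative flips, since co-gain with an overactive partner killer
## is what gets depleted).

.evidenceRow <- function(query, partner, module, dataset, res = NULL,
                         note = "") {
    if (is.null(res)) {
        data.frame(query_gene = query, partner_gene = partner,
            module = module, dataset = dataset, statistic = NA_real_,
            effect_size = NA_real_, p_value = NA_real_, q_value = NA_real_,
            n_a = NA_integer_, n_b = NA_integer_, testable = FALSE,
            note = note, stringsAsFactors = FALSE)
    } else {
        data.frame(query_gene = query, partner_gene = partner,
            module = module, dataset = dataset, statistic = res$statistic,
            effect_size = res$estimate, p_value = res$p.value,
            q_value = NA_real_, n_a = res$n.a, n_b = res$n.b,
            testable = TRUE, note = note, stringsAsFactors = FALSE)
    }
}

.conditionGroups <- function(state, omics, query, partner) {
    ## values of 'partner' split by the query's state call; NULL if either
    ## gene is absent from the needed matrices
    v <- omicsValues(omics)
    if (!partner %in% colnames(v) || !query %in% geneNames(state))
        return(NULL)
    shared <- intersect(rownames(v), sampleNames(state))
    if (!length(shared)) return(NULL)
    flag <- stateValues(state)[shared, query]
    vals <- v[shared, partner]
    keep <- !is.na(vals)
    list(inGroup = vals[keep & flag], outGroup = vals[keep & !flag])
}

#' Survival-of-the-fittest (SoF) test for one pair
#'
#' Rank-sum test of the partner gene's copy number in query-inactivated
#' samples versus the remaining samples. Under synthetic lethality,
#' co-inactivated pairs are depleted in surviving tumor populations, so the
#' partner's copy number is expected to be *higher* when the query is lost
#' (alternative \code{"greater"}). SDL screens condition on overactivation
#' and expect the opposite shift (\code{"less"}).
#'
#' @param query,partner gene symbols.
#' @param state [StateMatrix-class] conditioning the test (inactivation for
#'   SL, overactivation for SDL).
#' @param cn copy-number [OmicsMatrix-class].
#' @param alternative one-sided direction for the conditioned group
#'   (default \code{"greater"}).
#' @param dataset dataset label carried into the evidence row.
#' @param minGroup minimum size of each group (default 3); smaller groups
#'   yield an untestable evidence row, not an error.
#' @return One-row evidence data.frame (pair, module, statistic, rank-
#'   biserial effect size, p, group sizes, testable flag).
#' @export
sofTest <- function(query, partner, state, cn, alternative = "greater",
                    dataset = "cohort", minGroup = 3L) {
    g <- .conditionGroups(state, cn, query, partner)
    if (is.null(g))
        return(.evidenceRow(query, partner, "sof", dataset,
            note = "gene absent from inputs"))
    if (length(g$inGroup) < minGroup || length(g$outGroup) < minGroup)
        return(.evidenceRow(query, partner, "sof", dataset,
            note = sprintf("group sizes %d/%d below minimum %d",
                length(g$inGroup), length(g$outGroup), minGroup)))
    res <- rankSumTest(g$inGroup, g$outGroup, alternative)
    .evidenceRow(query, partner, "sof", dataset, res)
}

#' Functional-examination (FunEx) test for one pair
#'
#' Rank-sum test of the partner gene's dependency score in
#' query-inactivated (SL) or query-overactivated (SDL) cell lines versus
#' the rest, one-sided \code{"less"}: a lower gene-effect score means the
#' partner is more essential when the query is lost.
#'
#' @inheritParams sofTest
#' @param effect gene-effect [OmicsMatrix-class] (CRISPR or shRNA).
#' @return One-row evidence data.frame as in [sofTest()].
#' @export
funexTest <- function(query, partner, state, effect, alternative = "less",
                      dataset = "cohort", minGroup = 3L) {
    g <- .conditionGroups(state, effect, query, partner)
    if (is.null(g))
        return(.evidenceRow(query, partner, "funex", dataset,
            note = "gene absent from inputs"))
    if (length(g$inGroup) < minGroup || length(g$outGroup) < minGroup)
        return(.evidenceRow(query, partner, "funex", dataset,
            note = sprintf("group sizes %d/%d below minimum %d",
                length(g$inGroup), length(g$outGroup), minGroup)))
    res <- rankSumTest(g$inGroup, g$outGroup, alternative)
    .evidenceRow(query, partner, "funex", dataset, res)
}

#' Pairwise co-expression test
#'
#' One-sided Spearman test for positive correlation of the pair's
#' expression; pairs with missing members are dropped first.
#'
#' @inheritParams sofTest
#' @param expr expression [OmicsMatrix-class].
#' @param minPairs minimum number of complete sample pairs (default 10).
#' @return One-row evidence data.frame; the effect size is rho.
#' @export
coexpressionTest <- function(query, partner, expr, dataset = "cohort",
                             minPairs = 10L) {
    v <- omicsValues(expr)
    if (!query %in% colnames(v) || !partner %in% colnames(v))
        return(.evidenceRow(query, partner, "coexpression", dataset,
            note = "gene absent from expression matrix"))
    x <- v[, query]; y <- v[, partner]
    ok <- !(is.na(x) | is.na(y))
    if (sum(ok) < minPairs)
        return(.evidenceRow(query, partner, "coexpression", dataset,
            note = sprintf("%d complete pairs below minimum %d",
                sum(ok), minPairs)))
    res <- spearmanTest(x[ok], y[ok], "greater")
    if (isTRUE(res$degenerate))
        return(.evidenceRow(query, partner, "coexpression", dataset,
            note = "zero expression variance"))
    .evidenceRow(query, partner, "coexpression", dataset, res)
}

.daisyModules <- c("sof", "funex", "coexpression")

#' DAISY screen: run all three modules over pairs, datasets and contexts
#'
#' For every (query, partner) pair and every cohort, runs the SoF, FunEx and
#' co-expression modules that the cohort's layers support, corrects p-values
#' by Benjamini-Hochberg within each (module, dataset) family, and combines:
#' a pair's module passes when any dataset reaches that module's q cutoff,
#' and the pair is a DAISY prediction when all three modules pass. In strict
#' mode (default) a module with no testable dataset fails the combination;
#' lenient mode skips untestable modules and flags the prediction.
#'
#' @param cohorts an [SLCohort-class] or named list of them (each becomes a
#'   dataset family).
#' @param queryGenes character vector of query genes.
#' @param partnerGenes candidate partners; defaults to all genes of each
#'   cohort other than the query.
#' @param mode \code{"SL"} (inactivation conditioning) or \code{"SDL"}
#'   (overactivation; SoF alternative flips to \code{"less"}).
#' @param context optional cancer-type label; samples are filtered via the
#'   cohort annotation before state calling.
#' @param qCutoffs named numeric vector of per-module q cutoffs
#'   (default 0.05 each).
#' @param minGroup,minPairs group-size minima passed to the module tests.
#' @param exprPercentile,cnMax,cnMin state-calling thresholds, see
#'   [inactivationMask()] and [overactivationMask()].
#' @param strict untestable-module handling (see above).
#' @param damaging damaging classes for the mutation mask.
#' @return List with \code{evidence} (one row per pair x module x dataset)
#'   and \code{predictions} (one row per pair with pass flags and the
#'   combined call).
#' @export
daisyScreen <- function(cohorts, queryGenes, partnerGenes = NULL,
        mode = c("SL", "SDL"), context = NULL,
        qCutoffs = c(sof = 0.05, funex = 0.05, coexpression = 0.05),
        minGroup = 3L, minPairs = 10L, exprPercentile = 10,
        cnMax = -0.3, cnMin = 0.3, strict = TRUE,
        damaging = damagingClasses()) {
    mode <- match.arg(mode)
    if (is(cohorts, "SLCohort")) {
        cohorts <- stats::setNames(list(cohorts), cohortLabel(cohorts))
    }
    stopifnot(is.list(cohorts), length(cohorts) >= 1L)
    if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
        names(cohorts) <- paste0("dataset", seq_along(cohorts))
    qCutoffs <- qCutoffs[.daisyModules]
    if (anyNA(qCutoffs))
        stop("qCutoffs must name all of: ",
             paste(.daisyModules, collapse = ", "))

    evidence <- list()
    for (label in names(cohorts)) {
        ch <- cohorts[[label]]
        stopifnot(is(ch, "SLCohort"))
        if (!is.null(context)) {
            ann <- sampleAnnotation(ch)
            known <- unique(ann)
            if (!context %in% known)
                stop("unknown context '", context, "'; known: ",
                     paste(sort(known), collapse = ", "))
            ch <- subsetSamples(ch, names(ann)[ann == context])
        }
        expr <- exprLayer(ch); cn <- cnLayer(ch); eff <- effectLayer(ch)
        state <- NULL
        if (!is.null(expr) && !is.null(cn)) {
            if (mode == "SL") {
                mut <- NULL
                if (nrow(mutationTable(ch)))
                    mut <- functionalMutationMask(mutationTable(ch),
                        sampleNames(expr), geneNames(expr), damaging)
                state <- inactivationMask(expr, cn, mut, exprPercentile, cnMax)
            } else {
                state <- overactivationMask(expr, cn, exprPercentile, cnMin)
            }
        }
        sofAlt <- if (mode == "SL") "greater" else "less"
        for (q in queryGenes) {
            partners <- partnerGenes
            if (is.null(partners)) partners <- setdiff(geneNames(ch), q)
            partners <- setdiff(partners, q)
            for (p in partners) {
                if (!is.null(state) && !is.null(cn))
                    evidence[[length(evidence) + 1L]] <-
                        sofTest(q, p, state, cn, sofAlt, label, minGroup)
                if (!is.null(state) && !is.null(eff))
                    evidence[[length(evidence) + 1L]] <-
                        funexTest(q, p, state, eff, "less", label, minGroup)
                if (!is.null(expr))
                    evidence[[length(evidence) + 1L]] <-
                        coexpressionTest(q, p, expr, label, minPairs)
            }
        }
    }
    if (!length(evidence)) {
        warning("daisyScreen: no testable pair")
        return(list(evidence = .evidenceRow("x", "y", "sof", "d")[0, ],
                    predictions = data.frame()))
    }
    ev <- do.call(rbind, evidence)
    rownames(ev) <- NULL
    ## BH within each (module, dataset) family over testable rows
    for (fam in split(seq_len(nrow(ev)),
                      list(ev$module, ev$dataset), drop = TRUE)) {
        idx <- fam[ev$testable[fam]]
        if (length(idx)) ev$q_value[idx] <- bhAdjust(ev$p_value[idx])
    }

    pairKey <- paste(ev$query_gene, ev$partner_gene, sep = "\r")
    pairs <- unique(data.frame(query_gene = ev$query_gene,
        partner_gene = ev$partner_gene, stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs$query_gene, pairs$partner_gene), , drop = FALSE]
    rownames(pairs) <- NULL
    pred <- pairs
    pred$mode <- mode
    for (m in .daisyModules) {
        sel <- ev$module == m
        passKeys <- unique(pairKey[sel & ev$testable &
            !is.na(ev$q_value) & ev$q_value <= qCutoffs[[m]]])
        testKeys <- unique(pairKey[sel & ev$testable])
        key <- paste(pred$query_gene, pred$partner_gene, sep = "\r")
        pred[[paste0("pass_", m)]] <- key %in% passKeys
        pred[[paste0("testable_", m)]] <- key %in% testKeys
    }
    passM <- as.matrix(pred[, paste0("pass_", .daisyModules)])
    testM <- as.matrix(pred[, paste0("testable_", .daisyModules)])
    if (strict) {
        pred$combined <- rowSums(passM) == length(.daisyModules)
    } else {
        ## lenient: untestable modules are skipped, but at least one module
        ## must have been tested and passed
        pred$combined <- rowSums(testM) > 0L &
            rowSums(passM | !testM) == length(.daisyModules)
    }
    pred$lenient <- !strict
    list(evidence = ev, predictions = pred)
}
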