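## Seeded generators for synthetic cohorts and yeast screens with planted
## ground-truth synthetic-lethal pairs. The cohort generator plants, for
## each pair (A, B): (i) a gene-effect depression of B in A-inactivated
## lines, (ii) positive co-expression of A and B through a shared latent
## factor, and (iii) depletion of joint A-and-B copy loss. All randomness
## comes from one seeded Mersenne-Twister stream with fixed normal/sample
## kinds, so cohorts are reproducible across platforms.

## Seed the RNG with fixed generator kinds; returns a function restoring
## the caller's RNG state (use with on.exit).
.seedRNG <- function(seed) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", globalenv()) else NULL
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    function() {
        if (had) assign(".Random.seed", old, globalenv())
        else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    }
}

#' Parameters of the synthetic-cohort generator
#'
#' Defaults describe a mid-sized cell-line panel with clearly detectable
#' planted signal: 200 lines, 50 genes, 5 planted pairs, 20% functional-
#' mutation rate on query genes, a gene-effect shift of -1.0 against a
#' noise SD of 0.3, pair co-expression of rho = 0.7, and 90% depletion of
#' joint copy loss.
#'
#' @param nSamples number of cell lines / tumors.
#' @param nGenes number of genes.
#' @param nPlantedPairs number of planted SL pairs (at most nGenes / 2).
#' @param mutationRate per-sample probability that a planted query gene
#'   carries a functional mutation.
#' @param dependencyShift gene-effect shift (subtracted from the partner in
#'   query-inactivated samples; positive values plant SL signal).
#' @param noiseSd SD of the gene-effect noise.
#' @param coexpressionRho target Spearman-scale co-expression of planted
#'   pairs, induced by a shared latent factor.
#' @param coLossDepletion fraction by which the partner's copy-loss
#'   probability is reduced in query-inactivated samples (0 = none,
#'   1 = never co-lost).
#' @param nContexts number of cancer-type labels, assigned round-robin.
#' @param lossRate background per-gene copy-loss probability. The default
#'   (0.5) emulates frequently lost loci of the kind synthetic-lethality
#'   screens target; co-loss depletion is only observable where the partner
#'   is commonly lost in the first place.
#' @param backgroundMutationRate per-cell probability of a functional
#'   mutation in any gene (keeps non-planted query genes testable).
#' @param silentDecoyRate fraction of samples receiving a Silent decoy
#'   record, exercising the functional-mutation filter.
#' @param seed integer seed.
#' @return Validated parameter list of class \code{CohortParams}.
#' @export
cohortParams <- function(nSamples = 200L, nGenes = 50L, nPlantedPairs = 5L,
        mutationRate = 0.2, dependencyShift = 1.0, noiseSd = 0.3,
        coexpressionRho = 0.7, coLossDepletion = 0.9, nContexts = 4L,
        lossRate = 0.5, backgroundMutationRate = 0.05,
        silentDecoyRate = 0.05, seed = 1L) {
    p <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
        nPlantedPairs = as.integer(nPlantedPairs),
        mutationRate = mutationRate, dependencyShift = dependencyShift,
        noiseSd = noiseSd, coexpressionRho = coexpressionRho,
        coLossDepletion = coLossDepletion, nContexts = as.integer(nContexts),
        lossRate = lossRate,
        backgroundMutationRate = backgroundMutationRate,
        silentDecoyRate = silentDecoyRate, seed = as.integer(seed))
    chk <- function(cond, field) if (!cond) stop("cohortParams: invalid '",
        field, "'")
    chk(p$nSamples >= 2L, "nSamples")
    chk(p$nGenes >= 2L, "nGenes")
    chk(p$nPlantedPairs >= 0L && p$nPlantedPairs <= p$nGenes %/% 2L,
        "nPlantedPairs")
    for (f in c("mutationRate", "coLossDepletion", "lossRate",
                "backgroundMutationRate", "silentDecoyRate"))
        chk(p[[f]] >= 0 && p[[f]] <= 1, f)
    chk(p$coexpressionRho >= 0 && p$coexpressionRho < 1, "coexpressionRho")
    chk(p$noiseSd > 0, "noiseSd")
    chk(p$nContexts >= 1L, "nContexts")
    structure(p, class = "CohortParams")
}

## Fixed background scales, documented rather than tunable: expression is
## log2-like with per-gene means ~ N(7, 1) and unit noise; copy number is
## centred at 0 with SD 0.15 and a -0.8 shift on loss; lost genes lose 1.5
## expression units (dosage effect); gene effect is centred at 0.
.EXPR_MEAN_SD <- c(7, 1)
.EXPR_NOISE_SD <- 1
.CN_NOISE_SD <- 0.15
.CN_LOSS_SHIFT <- -0.8
.EXPR_LOSS_SHIFT <- -1.5

#' Generate a synthetic multi-omics cohort with planted SL pairs
#'
#' Planted pairs are the first \code{2 * nPlantedPairs} genes, taken in
#' order: (G001, G002), (G003, G004), ... with the odd gene as the mutated
#' query. In samples where the query carries a functional mutation, the
#' partner's gene effect is shifted by \code{-dependencyShift} and its
#' copy-loss probability is multiplied by \code{1 - coLossDepletion}. Pair
#' expression shares a latent factor yielding correlation
#' \code{coexpressionRho}, and lost genes carry reduced expression and
#' copy-number, so query inactivation is visible to mutation-, expression-
#' and copy-number-based state calling alike.
#'
#' @param params a [cohortParams()] list.
#' @return An [SLCohort-class] carrying expression, copy-number and
#'   gene-effect layers, a mutation table, a round-robin cancer-type
#'   annotation, the planted truth table and the generating parameters.
#' @examples
#' ch <- generateCohort(cohortParams(nSamples = 50, nGenes = 10,
#'     nPlantedPairs = 1, seed = 7))
#' plantedTruth(ch)
#' @export
generateCohort <- function(params = cohortParams()) {
    stopifnot(inherits(params, "CohortParams"))
    restoreRNG <- .seedRNG(params$seed)
    on.exit(restoreRNG())
    n <- params$nSamples; g <- params$nGenes
    genes <- sprintf("G%03d", seq_len(g))
    samples <- sprintf("CL%04d", seq_len(n))
    npairs <- params$nPlantedPairs
    truth <- data.frame(query_gene = character(), partner_gene = character(),
        stringsAsFactors = FALSE)
    if (npairs)
        truth <- data.frame(query_gene = genes[2L * seq_len(npairs) - 1L],
            partner_gene = genes[2L * seq_len(npairs)],
            dependency_shift = params$dependencyShift,
            coexpression_rho = params$coexpressionRho,
            co_loss_depletion = params$coLossDepletion,
            mutation_rate = params$mutationRate, stringsAsFactors = FALSE)

    ## functional-mutation indicators: background everywhere, boosted rate
    ## on planted query genes
    mutInd <- matrix(stats::runif(n * g) < params$backgroundMutationRate,
        n, g, dimnames = list(samples, genes))
    for (qg in truth$query_gene)
        mutInd[, qg] <- mutInd[, qg] | (stats::runif(n) < params$mutationRate)

    ## copy-loss indicators; the partner's loss probability is thinned in
    ## samples where the query carries a functional mutation (the planted
    ## inactivation event) -> co-loss depletion
    loss <- matrix(stats::runif(n * g) < params$lossRate, n, g,
        dimnames = list(samples, genes))
    queryMutated <- matrix(FALSE, n, 0)
    if (npairs) {
        queryMutated <- vapply(seq_len(npairs), function(i)
            mutInd[, truth$query_gene[i]], logical(n))
        colnames(queryMutated) <- truth$partner_gene
        for (i in seq_len(npairs)) {
            pg <- truth$partner_gene[i]
            cond <- queryMutated[, pg]
            thin <- stats::runif(n) < params$lossRate *
                (1 - params$coLossDepletion)
            loss[cond, pg] <- thin[cond]
        }
    }

    cn <- matrix(stats::rnorm(n * g, 0, .CN_NOISE_SD), n, g,
        dimnames = list(samples, genes)) + .CN_LOSS_SHIFT * loss

    geneMeans <- stats::rnorm(g, .EXPR_MEAN_SD[1L], .EXPR_MEAN_SD[2L])
    expr <- matrix(stats::rnorm(n * g, 0, .EXPR_NOISE_SD), n, g,
        dimnames = list(samples, genes))
    if (npairs) {
        rho <- params$coexpressionRho
        for (i in seq_len(npairs)) {
            z <- stats::rnorm(n)
            for (gn in c(truth$query_gene[i], truth$partner_gene[i]))
                expr[, gn] <- sqrt(rho) * z + sqrt(1 - rho) * expr[, gn]
        }
    }
    expr <- sweep(expr, 2L, geneMeans, `+`) + .EXPR_LOSS_SHIFT * loss

    eff <- matrix(stats::rnorm(n * g, 0, params$noiseSd), n, g,
        dimnames = list(samples, genes))
    if (npairs) {
        for (i in seq_len(npairs)) {
            pg <- truth$partner_gene[i]
            eff[queryMutated[, pg], pg] <-
                eff[queryMutated[, pg], pg] - params$dependencyShift
        }
    }

    ## long-form mutation records with damaging classes, plus Silent decoys
    idx <- which(mutInd, arr.ind = TRUE)
    classes <- damagingClasses()
    mut <- data.frame(sample = samples[idx[, 1L]], gene = genes[idx[, 2L]],
        classification = classes[sample.int(length(classes), nrow(idx),
            replace = TRUE)], stringsAsFactors = FALSE)
    decoy <- which(stats::runif(n) < params$silentDecoyRate)
    if (length(decoy)) {
        mut <- rbind(mut, data.frame(sample = samples[decoy],
            gene = genes[sample.int(g, length(decoy), replace = TRUE)],
            classification = "Silent", stringsAsFactors = FALSE))
    }
    mut <- mut[order(mut$sample, mut$gene, mut$classification), , drop = FALSE]
    rownames(mut) <- NULL

    ann <- stats::setNames(rep(sprintf("CT%d", seq_len(params$nContexts)),
        length.out = n), samples)

    SLCohort(expression = OmicsMatrix(expr, "expression"),
             copyNumber = OmicsMatrix(cn, "copy_number"),
             geneEffect = OmicsMatrix(eff, "gene_effect"),
             mutations = mut, annotation = ann, truth = truth,
             params = unclass(params), label = "synthetic")
}

.truncatedNormal <- function(n, mean, sd, upper = Inf, lower = -Inf) {
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out >= upper | out <= lower)
    while (length(bad)) {
        out[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[out[bad] >= upper | out[bad] <= lower]
    }
    out
}

#' Generate a synthetic yeast SGA screen with planted negative interactions
#'
#' Emits one record per unordered gene pair in TheCellMap pairwise layout.
#' Planted pairs draw epsilon from Normal(\code{epsNegativeMean}, 0.03)
#' truncated below -0.12 with p < 0.05, so they pass the default CGI
#' filters by construction; background pairs draw epsilon from
#' Normal(0, 0.05) truncated above -0.12 with uniform p, so they never do.
#' Query identifiers carry \code{_sn} and array identifiers \code{_dma}
#' allele suffixes, exercising suffix stripping.
#'
#' @param nGenes number of yeast genes.
#' @param nNegative number of planted negative-interaction pairs.
#' @param epsNegativeMean mean planted epsilon (must be < -0.12).
#' @param seed integer seed.
#' @return Yeast-interaction data.frame (query_gene, array_gene, epsilon,
#'   p_value) with the planted pairs attached as attribute
#'   \code{"planted"} (canonical gene_a/gene_b columns).
#' @export
generateYeastScreen <- function(nGenes = 100L, nNegative = 20L,
                                epsNegativeMean = -0.25, seed = 1L) {
    nGenes <- as.integer(nGenes); nNegative <- as.integer(nNegative)
    nPairs <- (nGenes * (nGenes - 1L)) %/% 2L
    if (nNegative < 0L || nNegative > nPairs)
        stop("generateYeastScreen: nNegative must lie in [0, ",
             nPairs, "]")
    if (epsNegativeMean >= -0.12)
        stop("generateYeastScreen: epsNegativeMean must be below -0.12")
    restoreRNG <- .seedRNG(seed)
    on.exit(restoreRNG())
    genes <- sprintf("YG%03d", seq_len(nGenes))
    pairs <- t(utils::combn(nGenes, 2L))
    plantedIdx <- sort(sample.int(nrow(pairs), nNegative))
    eps <- .truncatedNormal(nrow(pairs), 0, 0.05, lower = -0.12)
    p <- stats::runif(nrow(pairs))
    eps[plantedIdx] <- .truncatedNormal(nNegative, epsNegativeMean, 0.03,
        upper = -0.12)
    p[plantedIdx] <- stats::runif(nNegative, 0, 0.049)
    out <- data.frame(
        query_gene = paste0(genes[pairs[, 1L]], "_sn1"),
        array_gene = paste0(genes[pairs[, 2L]], "_dma1"),
        epsilon = eps, p_value = p, stringsAsFactors = FALSE)
    planted <- data.frame(
        gene_a = pmin(genes[pairs[plantedIdx, 1L]],
                      genes[pairs[plantedIdx, 2L]]),
        gene_b = pmax(genes[pairs[plantedIdx, 1L]],
                      genes[pairs[plantedIdx, 2L]]),
        stringsAsFactors = FALSE)
    planted <- planted[order(planted$gene_a, planted$gene_b), , drop = FALSE]
    rownames(planted) <- NULL
    attr(out, "planted") <- planted
    out
}

#' Write every layer of a cohort to a directory of delimited files
#'
#' Produces \code{expression.tsv}, \code{copy_number.tsv},
#' \code{gene_effect.tsv}, \code{mutations.tsv}, \code{annotation.tsv} and,
#' for synthetic cohorts, \code{truth.tsv}.
#'
#' @param cohort an [SLCohort-class].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "SLCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    put <- function(nm, path) { files[[nm]] <<- path; path }
    if (!is.null(exprLayer(cohort)))
        writeOmicsMatrix(exprLayer(cohort),
            put("expression", file.path(dir, "expression.tsv")))
    if (!is.null(cnLayer(cohort)))
        writeOmicsMatrix(cnLayer(cohort),
            put("copy_number", file.path(dir, "copy_number.tsv")))
    if (!is.null(effectLayer(cohort)))
        writeOmicsMatrix(effectLayer(cohort),
            put("gene_effect", file.path(dir, "gene_effect.tsv")))
    writeMutationTable(mutationTable(cohort),
        put("mutations", file.path(dir, "mutations.tsv")))
    if (length(sampleAnnotation(cohort)))
        writeSampleAnnotation(sampleAnnotation(cohort),
            put("annotation", file.path(dir, "annotation.tsv")))
    if (nrow(plantedTruth(cohort)))
        .writeTable(plantedTruth(cohort),
            put("truth", file.path(dir, "truth.tsv")))
    files
}
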