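mkState <- function(flags, samples, gene, kind = "inactive") {
    StateMatrix(matrix(flags, length(samples), 1L,
        dimnames = list(samples, gene)), kind)
}

test_that("SoF detects depleted co-loss as a copy-number shift", {
    samples <- paste0("S", 1:4)
    state <- mkState(c(TRUE, TRUE, FALSE, FALSE), samples, "Q")
    cn <- OmicsMatrix(matrix(c(0, 0, 0, 0, 0.1, 0.2, -0.5, -0.6), 4, 2,
        dimnames = list(samples, c("Q", "P"))), "copy_number")
    ev <- sofTest("Q", "P", state, cn, minGroup = 2L)
    expect_equal(ev$p_value, 1 / 6)     # inactive samples hold the top ranks
    expect_true(ev$testable)

    flat <- OmicsMatrix(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 4, 2,
        dimnames = list(samples, c("Q", "P"))), "copy_number")
    expect_equal(sofTest("Q", "P", state, flat, minGroup = 2L)$p_value, 1)

    tiny <- mkState(c(TRUE, FALSE, FALSE, FALSE), samples, "Q")
    ev2 <- sofTest("Q", "P", tiny, cn, minGroup = 3L)
    expect_false(ev2$testable)
    expect_match(ev2$note, "below minimum")
})

test_that("FunEx detects induced essentiality in the dependency scores", {
    samples <- paste0("S", 1:4)
    state <- mkState(c(TRUE, TRUE, FALSE, FALSE), samples, "Q")
    eff <- OmicsMatrix(matrix(c(0, 0, 0, 0, -2.0, -1.9, 0.0, 0.1), 4, 2,
        dimnames = list(samples, c("Q", "P"))), "gene_effect")
    ev <- funexTest("Q", "P", state, eff, minGroup = 2L)
    expect_equal(ev$p_value, 1 / 6)
    expect_lt(ev$effect_size, 0)        # partner more essential -> negative

    ## swapped direction: partner LESS essential when query is inactive;
    ## the one-sided "less" p is the oracle-enumerated value
    swapped <- mkState(c(FALSE, FALSE, TRUE, TRUE), samples, "Q")
    ev2 <- funexTest("Q", "P", swapped, eff, minGroup = 2L)
    expect_equal(ev2$p_value,
        oracleRankSumP(c(0.0, 0.1), c(-2.0, -1.9), "less"))
    expect_gt(ev2$p_value, 0.5)

    gone <- funexTest("Q", "ABSENT", state, eff, minGroup = 2L)
    expect_false(gone$testable)
})

test_that("co-expression only rewards positive correlation", {
    samples <- paste0("S", 1:10)
    x <- 1:10
    perfect <- OmicsMatrix(matrix(c(x, 2 * x + 1), 10, 2,
        dimnames = list(samples, c("Q", "P"))), "expression")
    ev <- coexpressionTest("Q", "P", perfect)
    expect_equal(ev$effect_size, 1)
    expect_lt(ev$p_value, 0.01)

    anti <- OmicsMatrix(matrix(c(x, rev(x)), 10, 2,
        dimnames = list(samples, c("Q", "P"))), "expression")
    expect_gte(coexpressionTest("Q", "P", anti)$p_value, 0.5)

    few <- OmicsMatrix(matrix(rnorm(8), 4, 2,
        dimnames = list(paste0("S", 1:4), c("Q", "P"))), "expression")
    expect_false(coexpressionTest("Q", "P", few)$testable)

    ## n = 5 exact permutation path
    five <- OmicsMatrix(matrix(c(1:5, 1, 3, 2, 4, 5), 5, 2,
        dimnames = list(paste0("S", 1:5), c("Q", "P"))), "expression")
    expect_equal(coexpressionTest("Q", "P", five, minPairs = 5L)$p_value,
        5 / 120)
})

test_that("a planted pair is the unique combined prediction in a small cohort", {
    ch <- generateCohort(cohortParams(nSamples = 100, nGenes = 50,
        nPlantedPairs = 1, seed = 7))
    res <- daisyScreen(ch, "G001")
    comb <- res$predictions[res$predictions$combined, ]
    expect_equal(nrow(comb), 1L)
    expect_equal(comb$partner_gene, "G002")
    ## intersection rule: combined = all three pass flags
    expect_identical(res$predictions$combined,
        res$predictions$pass_sof & res$predictions$pass_funex &
        res$predictions$pass_coexpression)
})

test_that("module q-values at the cutoff drive the intersection", {
    ch <- generateCohort(cohortParams(nSamples = 100, nGenes = 50,
        nPlantedPairs = 1, seed = 7))
    ## an impossible funex cutoff kills every combined call but leaves the
    ## other modules untouched
    res <- daisyScreen(ch, "G001",
        qCutoffs = c(sof = 0.05, funex = 1e-30, coexpression = 0.05))
    pl <- res$predictions[res$predictions$partner_gene == "G002", ]
    expect_true(pl$pass_sof && pl$pass_coexpression)
    expect_false(pl$pass_funex)
    expect_false(pl$combined)
})

test_that("screens are invariant to query/partner ordering", {
    ch <- generateCohort(cohortParams(nSamples = 80, nGenes = 12,
        nPlantedPairs = 2, seed = 5))
    genes <- geneNames(ch)
    a <- daisyScreen(ch, c("G001", "G003"), genes)
    b <- daisyScreen(ch, c("G003", "G001"), rev(genes))
    key <- function(r) {
        ev <- r$evidence[order(r$evidence$query_gene, r$evidence$partner_gene,
                               r$evidence$module), ]
        rownames(ev) <- NULL
        ev
    }
    expect_equal(key(a), key(b))
    expect_equal(a$predictions[order(a$predictions$partner_gene), ],
                 b$predictions[order(b$predictions$partner_gene), ],
                 ignore_attr = TRUE)
})

test_that("tissue-restricted screening equals a pre-filtered pan-cancer run", {
    ch <- generateCohort(cohortParams(nSamples = 120, nGenes = 16,
        nPlantedPairs = 2, nContexts = 3, seed = 9))
    ann <- sampleAnnotation(ch)
    restricted <- daisyScreen(ch, "G001", context = "CT2")
    pre <- subsetSamples(ch, names(ann)[ann == "CT2"])
    manual <- daisyScreen(pre, "G001")
    expect_equal(restricted$evidence, manual$evidence)
    expect_error(daisyScreen(ch, "G001", context = "NOPE"),
        "unknown context")
})

test_that("strict and lenient modes differ only on untestable modules", {
    ## cohort without a gene-effect layer: funex is never testable
    full <- generateCohort(cohortParams(nSamples = 150, nGenes = 20,
        nPlantedPairs = 1, seed = 13))
    noEff <- SLCohort(expression = exprLayer(full), copyNumber = cnLayer(full),
        mutations = mutationTable(full),
        annotation = sampleAnnotation(full), label = "noeffect")
    strict <- daisyScreen(noEff, "G001")
    lenient <- daisyScreen(noEff, "G001", strict = FALSE)
    expect_false(any(strict$predictions$combined))
    planted <- lenient$predictions[lenient$predictions$partner_gene == "G002", ]
    expect_false(planted$testable_funex)
    expect_true(planted$combined)       # passes the two testable modules
})

test_that("SDL mode conditions on overactivation", {
    ## build a cohort where the partner is more essential when the query is
    ## overexpressed and amplified
    set.seed(31)
    n <- 60; samples <- sprintf("S%02d", 1:n)
    over <- c(rep(TRUE, 15), rep(FALSE, 45))
    expr <- cbind(Q = ifelse(over, 9, 5) + rnorm(n, 0, 0.2),
                  P = rnorm(n, 5, 1))
    cn <- cbind(Q = ifelse(over, 0.8, 0) + rnorm(n, 0, 0.05),
                P = rnorm(n, 0, 0.05))
    eff <- cbind(Q = rnorm(n, 0, 0.2),
                 P = ifelse(over, -1.2, 0) + rnorm(n, 0, 0.2))
    rownames(expr) <- rownames(cn) <- rownames(eff) <- samples
    ch <- SLCohort(expression = OmicsMatrix(expr, "expression"),
        copyNumber = OmicsMatrix(cn, "copy_number"),
        geneEffect = OmicsMatrix(eff, "gene_effect"), label = "sdl")
    res <- daisyScreen(ch, "Q", "P", mode = "SDL")
    ev <- res$evidence
    expect_lt(ev$p_value[ev$module == "funex"], 0.01)
    ## the conditioning group is capped by the 90th-percentile clause
    expect_lte(ev$n_a[ev$module == "funex"], ceiling(0.1 * n))
    expect_gte(ev$n_a[ev$module == "funex"], 3L)
})
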