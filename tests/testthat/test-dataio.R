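writeLinesTo <- function(lines, name) {
    path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                      name)
    writeLines(lines, path)
    path
}

test_that("omics matrices parse, preserve missingness and validate", {
    p <- writeLinesTo(c("sample\tBRCA2\tPARP1",
                        "S1\t1.5\t2.5", "S2\tNA\t3.5", "S3\t2.0\t4.0"),
                      "m.tsv")
    m <- readOmicsMatrix(p, "expression")
    expect_s4_class(m, "OmicsMatrix")
    expect_equal(dim(omicsValues(m)), c(3L, 2L))
    expect_equal(omicsRole(m), "expression")
    expect_true(is.na(omicsValues(m)["S2", "BRCA2"]))
    expect_equal(omicsValues(m)["S3", "PARP1"], 4.0)

    ## non-numeric cells become missing
    p2 <- writeLinesTo(c("sample\tG1", "S1\tlow", "S2\t2"), "m2.tsv")
    expect_true(is.na(omicsValues(readOmicsMatrix(p2, "expression"))["S1", "G1"]))

    dup <- writeLinesTo(c("sample\tG1", "S1\t1", "S1\t2"), "dup.tsv")
    expect_error(readOmicsMatrix(dup, "expression"), "duplicate.*S1")
    empty <- writeLinesTo("sample\tG1", "empty.tsv")
    expect_error(readOmicsMatrix(empty, "expression"), "empty")
})

test_that("genes-in-rows parsing is the transpose of samples-in-rows", {
    d <- withr::local_tempdir()
    m <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
        dimnames = list(paste0("S", 1:3), c("G1", "G2")))
    byS <- file.path(d, "byS.tsv"); byG <- file.path(d, "byG.tsv")
    writeOmicsMatrix(OmicsMatrix(m, "copy_number"), byS)
    tdf <- data.frame(gene = colnames(m), t(m), check.names = FALSE)
    utils::write.table(tdf, byG, sep = "\t", quote = FALSE,
        row.names = FALSE, na = "")
    a <- readOmicsMatrix(byS, "copy_number", "samples_in_rows")
    b <- readOmicsMatrix(byG, "copy_number", "genes_in_rows")
    expect_identical(omicsValues(a), omicsValues(b))
})

test_that("omics matrices round-trip losslessly, including missing values", {
    d <- withr::local_tempdir()
    set.seed(1)
    m <- matrix(rnorm(12), 4, 3,
        dimnames = list(paste0("S", 1:4), paste0("G", 1:3)))
    m[2, 3] <- NA
    for (ext in c("tsv", "csv")) {
        path <- file.path(d, paste0("m.", ext))
        writeOmicsMatrix(OmicsMatrix(m, "gene_effect"), path)
        back <- readOmicsMatrix(path, "gene_effect")
        expect_identical(omicsValues(back), m)
    }
})

test_that("mutation tables validate columns and drop incomplete rows", {
    p <- writeLinesTo(c("DepMap_ID\tHugo_Symbol\tVariant_Classification",
        "S1\tBRCA2\tNonsense_Mutation", "S2\tBRCA2\tSilent",
        "S3\t\tMissense_Mutation", "S4\tTP53\tMissense_Mutation"), "mut.tsv")
    expect_message(cat <- readMutationTable(p), "dropped 1")
    expect_equal(nrow(cat), 3L)
    expect_named(cat, c("sample", "gene", "classification"))
    expect_error(readMutationTable(p, geneCol = "Gene"), "Gene")

    d <- withr::local_tempdir()
    out <- file.path(d, "mut2.tsv")
    writeMutationTable(cat, out)
    expect_identical(readMutationTable(out), cat)
})

test_that("sample annotations enforce one non-empty label per sample", {
    p <- writeLinesTo(c("DepMap_ID\tprimary_disease",
        "S1\tBreast", "S2\tLung"), "ann.tsv")
    ann <- readSampleAnnotation(p)
    expect_identical(ann, c(S1 = "Breast", S2 = "Lung"))
    dup <- writeLinesTo(c("DepMap_ID\tprimary_disease",
        "S1\tBreast", "S1\tLung"), "anndup.tsv")
    expect_error(readSampleAnnotation(dup), "duplicate")
    blank <- writeLinesTo(c("DepMap_ID\tprimary_disease", "S1\t"),
        "annblank.tsv")
    expect_error(readSampleAnnotation(blank), "non-empty")
})

test_that("GMT collections parse, deduplicate members and report bad lines", {
    p <- writeLinesTo(c("SET1\tdesc one\tA\tB\tC\tD\tE",
                        "SET2\tdesc two\tATM\tX\tATM\tY"), "sets.gmt")
    gs <- readGeneSets(p)
    expect_equal(lengths(lapply(gs, `[[`, "genes")),
                 c(SET1 = 5L, SET2 = 3L))
    bad <- writeLinesTo(c("SET1\tdesc\tA", "NAME\tDESC"), "bad.gmt")
    expect_error(readGeneSets(bad), "line 2")
})

test_that("ortholog maps aggregate one-to-many rows", {
    p <- writeLinesTo(c("yeast\thuman", "RAD51\tRAD51", "MRE11\tMRE11A",
                        "RAD51\tRAD51B"), "orth.tsv")
    orth <- readOrthologMap(p)
    expect_setequal(orth$RAD51, c("RAD51", "RAD51B"))
    expect_equal(orth$MRE11, "MRE11A")
})

test_that("yeast interaction tables validate and drop self-pairs", {
    p <- writeLinesTo(c("query_gene\tarray_gene\tepsilon\tp_value",
        "YA_sn1\tYB_dma1\t-0.2\t0.01", "YA_sn1\tYA_dma2\t-0.3\t0.01"),
        "sga.tsv")
    expect_message(tab <- readYeastInteractions(p), "1 self-pair")
    expect_equal(nrow(tab), 1L)
    bad <- data.frame(query_gene = "a", array_gene = "b",
        epsilon = -0.1, p_value = 1.5)
    expect_error(validateYeastInteractions(bad), "\\[0, 1\\]")
})

test_that("prediction tables sort deterministically and round-trip", {
    d <- withr::local_tempdir()
    x <- data.frame(query_gene = c("g3", "g1", "g2"),
        partner_gene = c("p3", "p1", "p2"),
        p_value = c(0.15, 0.009, 0.01), q_value = c(0.2, 0.01, 0.01),
        stringsAsFactors = FALSE)
    path <- file.path(d, "pred.tsv")
    writePredictions(x, path)
    back <- readPredictions(path)
    expect_equal(back$query_gene, c("g1", "g2", "g3"))  # q, then p, breaks tie
    expect_equal(back[order(back$query_gene), ]$p_value,
                 x[order(x$query_gene), ]$p_value)
    writePredictions(x[0, ], path)
    expect_equal(nrow(readPredictions(path)), 0L)
    expect_error(writePredictions(data.frame(a = 1), path), "p_value")
})
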