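test_that("exact rank-sum p-values match enumeration on worked examples", {
    expect_equal(rankSumTest(c(1, 2), c(3, 4), "less")$p.value, 1 / 6)
    expect_equal(rankSumTest(1:3, 4:6, "less")$p.value, 1 / 20)
    expect_equal(rankSumTest(c(0, 0), c(0, 0), "two.sided")$p.value, 1)
    ## statistic is the rank sum of the first group
    expect_equal(rankSumTest(c(1, 2), c(3, 4), "less")$statistic, 3)
    expect_error(rankSumTest(numeric(), 1:3), "non-empty")
    expect_error(rankSumTest(c(1, Inf), 1:3), "finite")
})

test_that("exact rank-sum p equals brute-force enumeration, ties included", {
    set.seed(42)
    for (nA in 1:4) {
        for (nB in 1:(8 - nA)) {
            for (rep in 1:3) {
                a <- sample(1:4, nA, replace = TRUE)   # heavy ties
                b <- sample(1:4, nB, replace = TRUE)
                a2 <- rnorm(nA); b2 <- rnorm(nB)       # untied
                for (alt in c("less", "greater", "two.sided")) {
                    expect_equal(rankSumTest(a, b, alt)$p.value,
                        oracleRankSumP(a, b, alt),
                        info = sprintf("tied nA=%d nB=%d %s", nA, nB, alt))
                    expect_equal(rankSumTest(a2, b2, alt)$p.value,
                        oracleRankSumP(a2, b2, alt),
                        info = sprintf("untied nA=%d nB=%d %s", nA, nB, alt))
                }
            }
        }
    }
})

test_that("normal-approximation rank-sum p is close to the exact p", {
    set.seed(7)
    worst <- 0
    for (i in 1:300) {
        nA <- sample(5:10, 1); nB <- sample(5:10, 1)
        a <- rnorm(nA); b <- rnorm(nB)          # continuous, no ties
        approx <- rankSumTest(a, b, "less", exactLimit = 0L)$p.value
        U <- sum(rank(c(a, b))[seq_len(nA)]) - nA * (nA + 1) / 2
        exact <- pwilcox(U, nA, nB)             # classical exact, untied
        worst <- max(worst, abs(approx - exact))
    }
    expect_lt(worst, 0.02)
})

test_that("Welch t-test matches the closed form and flags degeneracies", {
    res <- welchTTest(1:4, 5:8)
    ref <- oracleWelch(1:4, 5:8)
    expect_equal(res$statistic, ref$t, tolerance = 1e-12)
    expect_equal(res$df, ref$df, tolerance = 1e-12)
    expect_equal(res$p.value, ref$p, tolerance = 1e-12)
    expect_lt(abs(res$statistic - (-4.3818)), 1e-3)

    same <- welchTTest(1:3, 1:3)
    expect_equal(same$statistic, 0)
    expect_equal(same$p.value, 1)

    degen <- welchTTest(c(1, 1, 1), c(2, 2, 2))
    expect_true(degen$degenerate)
    expect_equal(degen$p.value, 0)
    expect_error(welchTTest(1, 1:3), "at least 2")
})

test_that("Welch test holds its nominal size under the null", {
    set.seed(11)
    hits <- mean(replicate(1000,
        welchTTest(rnorm(20), rnorm(20))$p.value < 0.05))
    expect_gte(hits, 0.03)
    expect_lte(hits, 0.07)
})

test_that("Spearman statistic and exact permutation p are correct", {
    expect_equal(spearmanTest(1:3, 1:3)$statistic, 1)
    s <- spearmanTest(1:5, c(1, 3, 2, 4, 5), "greater")
    expect_equal(s$statistic, 0.9)               # 1 - 6*2/(5*24)
    expect_equal(s$p.value, 5 / 120)             # 1 rho=1 + 4 rho=0.9 perms
    expect_equal(s$method, "spearman_exact")
    set.seed(3)
    for (n in 4:6) {
        x <- rnorm(n); y <- rnorm(n)
        for (alt in c("less", "greater", "two.sided"))
            expect_equal(spearmanTest(x, y, alt)$p.value,
                oracleSpearmanP(x, y, alt), info = paste(n, alt))
    }
    expect_error(spearmanTest(1:2, 2:1), "at least 3")
    flat <- spearmanTest(c(1, 1, 1), 1:3)
    expect_true(flat$degenerate)
})

test_that("Spearman t-approximation is used for larger n and tracks cor.test", {
    set.seed(5)
    x <- rnorm(30); y <- x + rnorm(30)
    mine <- spearmanTest(x, y, "greater")
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
        alternative = "greater", exact = FALSE))
    expect_equal(mine$method, "spearman_approx")
    expect_equal(unname(mine$statistic), unname(ref$estimate))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("hypergeometric tail matches direct summation", {
    expect_equal(hypergeomTail(20, 5, 5, 5), 1 / choose(20, 5))
    expect_equal(hypergeomTail(10, 5, 5, 4), 26 / 252)
    expect_equal(hypergeomTail(37, 12, 9, 0), 1)
    set.seed(9)
    for (i in 1:200) {
        N <- sample(2:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
        k <- sample(0:min(K, n), 1)
        expect_equal(hypergeomTail(N, K, n, k), oracleHyperTail(N, K, n, k),
            info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
    expect_error(hypergeomTail(10, 5, 5, 6), "k <= min")
    expect_error(hypergeomTail(10, 11, 5, 2), "exceed")
})

test_that("BH adjustment reproduces step-up q-values and propagates NA", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.5), 0.5)
    expect_equal(bhAdjust(c(0.005, 0.5)), c(0.01, 0.5))
    expect_equal(bhAdjust(c(0.01, NA, 0.05)), c(0.02, NA, 0.05))
    set.seed(13)
    p <- runif(200)
    expect_equal(bhAdjust(p), oracleBH(p))
    expect_true(all(bhAdjust(p) >= p))
    expect_true(all(bhAdjust(p) <= 1))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH at level 0.1 controls the false-discovery proportion on nulls", {
    set.seed(17)
    fdp <- replicate(500, {
        q <- bhAdjust(runif(100))
        if (any(q <= 0.1)) 1 else 0   # every discovery on a null is false
    })
    expect_lte(mean(fdp), 0.15)
})
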