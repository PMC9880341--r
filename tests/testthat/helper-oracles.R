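## Independent brute-force oracles used to verify the statistical kernels.
## These deliberately share no code with the package: enumeration is done
## from first principles.

## Exact rank-sum p by enumerating every assignment of group-A positions
## among the pooled observations (average ranks, so ties are exact).
oracleRankSumP <- function(a, b, alternative) {
    pooled <- c(a, b)
    r <- rank(pooled)
    nA <- length(a)
    W <- sum(r[seq_along(a)])
    picks <- utils::combn(length(pooled), nA)
    sums <- apply(picks, 2L, function(idx) sum(r[idx]))
    eps <- 1e-9
    pl <- mean(sums <= W + eps)
    pg <- mean(sums >= W - eps)
    switch(alternative,
        less = pl, greater = pg,
        two.sided = min(1, 2 * min(pl, pg)))
}

## All permutations of 1..n, built iteratively (package uses recursion).
oraclePermutations <- function(n) {
    out <- matrix(1L, 1L, 1L)
    for (k in 2:n) {
        out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
            t(vapply(seq_len(k), function(pos)
                append(out[i, ], k, after = pos - 1L), integer(k)))
        }))
    }
    out
}

## Exact Spearman p by full enumeration of orderings of y.
oracleSpearmanP <- function(x, y, alternative) {
    rx <- rank(x); ry <- rank(y)
    rho <- cor(rx, ry)
    perms <- oraclePermutations(length(x))
    rhos <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    eps <- 1e-9
    pg <- mean(rhos >= rho - eps)
    pl <- mean(rhos <= rho + eps)
    switch(alternative,
        greater = pg, less = pl,
        two.sided = min(1, 2 * min(pl, pg)))
}

## Hypergeometric upper tail by direct summation of binomial coefficients.
oracleHyperTail <- function(N, K, n, k) {
    if (k == 0) return(1)
    j <- k:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## BH step-up computed literally: q_(i) = min over j >= i of p_(j) * m / j.
oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    running <- Inf
    for (i in m:1) {
        running <- min(running, p[ord[i]] * m / i)
        q[ord[i]] <- min(1, running)
    }
    q
}

## Welch t-test from the closed-form formulas.
oracleWelch <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
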