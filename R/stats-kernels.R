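## Statistical kernels shared by every inference workflow. Each kernel has a
## small-sample exact path (enumeration) and a large-sample approximation,
## so results can be checked against brute-force oracles.

.newTestResult <- function(statistic, p, method, alternative, nA, nB,
                           estimate = NA_real_, degenerate = FALSE) {
    structure(list(statistic = statistic, p.value = p, method = method,
                   alternative = alternative, n.a = nA, n.b = nB,
                   estimate = estimate, degenerate = degenerate),
              class = "slTestResult")
}

#' @export
print.slTestResult <- function(x, ...) {
    cat(sprintf("%s (%s): statistic = %.6g, p = %.6g, n = (%d, %d)%s\n",
        x$method, x$alternative, x$statistic, x$p.value, x$n.a, x$n.b,
        if (isTRUE(x$degenerate)) " [degenerate]" else ""))
    invisible(x)
}

## All size-nA subsets of seq_len(n), as a matrix with one subset per column.
.sizedSubsets <- function(n, nA) utils::combn(n, nA)

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-group rank-sum test. For small pooled sizes
#' (\code{length(a) + length(b) <= exactLimit}) the null distribution of the
#' rank sum is enumerated over every assignment of ranks to the first group,
#' using average ranks so ties are handled exactly. Larger samples use the
#' tie-corrected normal approximation with continuity correction. The
#' statistic is the rank sum of \code{a} in the pooled sample; one-sided
#' alternatives refer to the location of \code{a} relative to \code{b}.
#'
#' @param a,b numeric vectors of finite values (each non-empty).
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}.
#' @param exactLimit pooled-size cutoff for enumeration (default 10, which
#'   bounds the enumeration at choose(10, 5) = 252 assignments).
#' @return An \code{slTestResult} list: statistic (rank sum of \code{a}),
#'   p.value, method, alternative, group sizes.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4), "less")$p.value   # 1/6 by enumeration
#' @export
rankSumTest <- function(a, b, alternative = c("two.sided", "less", "greater"),
                        exactLimit = 10L) {
    alternative <- match.arg(alternative)
    a <- as.numeric(a); b <- as.numeric(b)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b))
        stop("rankSumTest: both groups must be non-empty")
    if (any(!is.finite(a)) || any(!is.finite(b)))
        stop("rankSumTest: values must be finite")
    nA <- length(a); nB <- length(b); n <- nA + nB
    pooled <- c(a, b)
    r <- rank(pooled)             # average ranks for ties
    W <- sum(r[seq_len(nA)])
    eps <- 1e-9
    if (n <= exactLimit) {
        ## exact: enumerate every assignment of nA of the pooled ranks
        sums <- colSums(matrix(r[.sizedSubsets(n, nA)], nrow = nA))
        pLess <- mean(sums <= W + eps)
        pGreater <- mean(sums >= W - eps)
        p <- switch(alternative,
            less = pLess, greater = pGreater,
            two.sided = min(1, 2 * min(pLess, pGreater)))
        method <- "rank_sum_exact"
    } else {
        mu <- nA * (n + 1) / 2
        ties <- table(r)
        sigma2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        if (sigma2 <= 0) {        # all values identical
            p <- 1
        } else {
            sigma <- sqrt(sigma2)
            ## continuity-corrected z in each direction
            zLess <- (W - mu + 0.5) / sigma
            zGreater <- (W - mu - 0.5) / sigma
            p <- switch(alternative,
                less = stats::pnorm(zLess),
                greater = stats::pnorm(zGreater, lower.tail = FALSE),
                two.sided = min(1, 2 * min(stats::pnorm(zLess),
                    stats::pnorm(zGreater, lower.tail = FALSE))))
        }
        method <- "rank_sum_normal"
    }
    .newTestResult(W, p, method, alternative, nA, nB,
        estimate = 2 * (W - nA * (nA + 1) / 2) / (nA * nB) - 1)  # rank-biserial
}

#' Welch two-sample t-test with degenerate-variance handling
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom;
#' the statistic's sign follows \code{mean(a) - mean(b)}. Zero variance in
#' both groups is not an error: equal means give t = 0, p = 1, while
#' unequal means are reported as a degenerate result with p = 0 and the
#' \code{degenerate} flag set.
#'
#' @inheritParams rankSumTest
#' @return An \code{slTestResult}; \code{estimate} holds
#'   \code{mean(a) - mean(b)} and \code{df} the Welch degrees of freedom.
#' @examples
#' welchTTest(1:4, 5:8)$p.value
#' @export
welchTTest <- function(a, b, alternative = c("two.sided", "less", "greater")) {
    alternative <- match.arg(alternative)
    a <- as.numeric(a); b <- as.numeric(b)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("welchTTest: each group needs at least 2 observations")
    va <- stats::var(a); vb <- stats::var(b)
    delta <- mean(a) - mean(b)
    if (va == 0 && vb == 0) {
        if (delta == 0) {
            res <- .newTestResult(0, 1, "welch_t", alternative,
                length(a), length(b), estimate = 0)
            res$df <- NA_real_
            return(res)
        }
        res <- .newTestResult(sign(delta) * Inf, 0, "welch_t", alternative,
            length(a), length(b), estimate = delta, degenerate = TRUE)
        res$df <- NA_real_
        return(res)
    }
    tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
    res <- .newTestResult(unname(tt$statistic), tt$p.value, "welch_t",
        alternative, length(a), length(b), estimate = delta)
    res$df <- unname(tt$parameter)
    res
}

## All permutations of seq_len(n), one per row. n <= 7 in practice (5040).
.allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPermutations(n - 1L)
    ## insert n at every position of every (n-1)-permutation
    do.call(rbind, lapply(seq_len(n), function(pos) {
        left <- sub[, seq_len(pos - 1L), drop = FALSE]
        right <- if (pos <= n - 1L) sub[, pos:(n - 1L), drop = FALSE]
                 else sub[, 0L, drop = FALSE]
        cbind(left, n, right, deparse.level = 0L)
    }))
}

#' Spearman rank-correlation test
#'
#' Spearman's rho on average-ranked data. For \code{n <= exactN} complete
#' pairs with no ties in either vector, the p-value is exact by full
#' enumeration of the n! orderings; otherwise the t approximation with
#' n - 2 degrees of freedom is used. Pairs with a missing member are dropped
#' first. Zero variance in either vector yields an undefined-correlation
#' result (rho and p are NA, \code{degenerate} flag set).
#'
#' @param x,y paired numeric vectors.
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}
#'   (one-sided alternatives are on the sign of rho).
#' @param exactN permutation-enumeration cutoff (default 7).
#' @return An \code{slTestResult}; \code{statistic} and \code{estimate}
#'   both hold rho.
#' @examples
#' spearmanTest(1:5, c(1, 3, 2, 4, 5), "greater")$p.value  # 5/120 exact
#' @export
spearmanTest <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exactN = 7L) {
    alternative <- match.arg(alternative)
    ok <- !(is.na(x) | is.na(y))
    x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
    n <- length(x)
    if (n < 3L)
        stop("spearmanTest: need at least 3 complete pairs")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        return(.newTestResult(NA_real_, NA_real_, "spearman_undefined",
            alternative, n, n, estimate = NA_real_, degenerate = TRUE))
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    eps <- 1e-9
    noTies <- !anyDuplicated(x) && !anyDuplicated(y)
    if (n <= exactN && noTies) {
        perms <- .allPermutations(n)
        ## rho for every ordering of y against fixed x
        rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
        pGreater <- mean(rhos >= rho - eps)
        pLess <- mean(rhos <= rho + eps)
        p <- switch(alternative,
            greater = pGreater, less = pLess,
            two.sided = min(1, 2 * min(pLess, pGreater)))
        method <- "spearman_exact"
    } else {
        if (abs(rho) >= 1) {
            tstat <- sign(rho) * Inf
        } else {
            tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        }
        p <- switch(alternative,
            greater = stats::pt(tstat, n - 2, lower.tail = FALSE),
            less = stats::pt(tstat, n - 2),
            two.sided = min(1, 2 * stats::pt(abs(tstat), n - 2,
                lower.tail = FALSE)))
        method <- "spearman_approx"
    }
    .newTestResult(rho, p, method, alternative, n, n, estimate = rho)
}

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= k) when drawing \code{n} items without replacement from a universe
#' of \code{N} items of which \code{K} are annotated. The standard one-sided
#' over-representation p-value of a gene-set enrichment test.
#'
#' @param N universe size.
#' @param K number of annotated items in the universe.
#' @param n number of items drawn.
#' @param k observed overlap.
#' @return The tail probability, a scalar in [0, 1].
#' @examples
#' hypergeomTail(20, 5, 5, 5)  # 1 / choose(20, 5)
#' @export
hypergeomTail <- function(N, K, n, k) {
    if (length(N) != 1L || length(K) != 1L || length(n) != 1L || length(k) != 1L)
        stop("hypergeomTail: scalar arguments required")
    if (K > N || n > N)
        stop("hypergeomTail: K and n cannot exceed N")
    if (k > K || k > n || k < 0)
        stop("hypergeomTail: need 0 <= k <= min(K, n)")
    if (k == 0) return(1)
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#' Missing p-values propagate as missing and do not count toward the number
#' of tests.
#'
#' @param p numeric vector of p-values in [0, 1]; NAs allowed.
#' @return q-values, same length and order as \code{p}.
#' @examples
#' bhAdjust(c(0.005, 0.5))  # c(0.01, 0.5)
#' @export
bhAdjust <- function(p) {
    p <- as.numeric(p)
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("bhAdjust: p-values must lie in [0, 1]")
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}
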