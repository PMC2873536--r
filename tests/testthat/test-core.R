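test_that("standardization centers and scales with the population convention", {
    m <- matrix(c(1, 2, 3), 1, 3,
                dimnames = list("v1", paste0("s", 1:3)))
    std <- standardizeOmics(PairedOmicsMatrix(m))
    expect_equal(unname(omicsValues(std$data)[1, ]),
                 c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
    expect_equal(sum(omicsValues(std$data)^2), 3)

    ## random matrix: every retained row has mean ~0 and sum of squares ~N
    set.seed(7)
    pom <- randomOmics(4, 10)
    std <- standardizeOmics(pom)$data
    expect_true(all(abs(rowMeans(omicsValues(std))) < 1e-12))
    expect_true(all(abs(rowSums(omicsValues(std)^2) - 10) < 1e-9))

    ## sample-SD convention: sum of squares N - 1
    std <- standardizeOmics(pom, convention = "sample")$data
    expect_true(all(abs(rowSums(omicsValues(std)^2) - 9) < 1e-9))
})

test_that("zero-variance variables are dropped and recorded", {
    m <- rbind(v1 = c(1, 2, 3, 4), v2 = c(5, 5, 5, 5))
    colnames(m) <- paste0("s", 1:4)
    model <- fitStandardization(PairedOmicsMatrix(m))
    expect_identical(model@dropped, "v2")
    expect_identical(names(model@means), "v1")
    expect_error(fitStandardization(PairedOmicsMatrix(m[, 1:2, drop = FALSE])),
                 "at least 3")
    expect_error(
        fitStandardization(PairedOmicsMatrix(m[2, , drop = FALSE])),
        "zero variance")
})

test_that("applying a model to its training data reproduces fit-time output", {
    pom <- randomOmics(5, 8, seed = 3)
    std <- standardizeOmics(pom)
    again <- applyStandardization(std$model, pom)
    expect_equal(omicsValues(again), omicsValues(std$data))

    ## train statistics applied to new values: (6 - 2) / 2 = 2
    model <- new("StandardizationModel", means = c(v1 = 2), sds = c(v1 = 2),
                 dropped = character(0), convention = "population")
    test <- PairedOmicsMatrix(matrix(6, 1, 3,
        dimnames = list("v1", paste0("t", 1:3))))
    expect_equal(unname(omicsValues(applyStandardization(model, test))[1, ]),
                 rep(2, 3))

    ## unknown extra variables ignored with a warning; known rows match
    ## manual subsetting
    extra <- PairedOmicsMatrix(rbind(v1 = c(0, 2, 4), zz = c(9, 9, 1)),
                               sampleIds = paste0("t", 1:3))
    expect_warning(out <- applyStandardization(model, extra), "ignored")
    expect_identical(variableIds(out), "v1")
    expect_equal(unname(omicsValues(out)[1, ]), (c(0, 2, 4) - 2) / 2)

    ## missing required variable is a schema error
    bad <- PairedOmicsMatrix(rbind(other = c(1, 2, 3)),
                             sampleIds = paste0("t", 1:3))
    expect_error(applyStandardization(model, bad), "missing")
})

test_that("gramMatrix equals the dense primal product", {
    m <- matrix(c(1, -1), 1, 2, dimnames = list("v1", c("a", "b")))
    K <- gramMatrix(PairedOmicsMatrix(m))
    expect_equal(unname(K), rbind(c(1, -1), c(-1, 1)))

    set.seed(11)
    pom <- randomOmics(500, 20)
    K <- gramMatrix(pom)
    v <- omicsValues(pom)
    expect_lt(max(abs(K - t(v) %*% v)), 1e-10)
    expect_equal(max(abs(K - t(K))), 0)
    expect_equal(sum(diag(K)), sum(v^2))
    pom@values[1, 1] <- NA
    expect_error(gramMatrix(pom), "non-finite")
})

test_that("dual solver recovers perfect self-correlation and rejects bad d", {
    pom <- randomOmics(6, 10, seed = 21)
    std <- standardizeOmics(pom)$data
    K <- gramMatrix(std)
    sol <- suppressWarnings(solveRccaDual(K, K, regPair(0, 0), d = 1))
    expect_equal(sol@rho[1], 1, tolerance = 1e-8)
    expect_error(solveRccaDual(K, K, regPair(0, 0), d = 10), "N - 1")
})

test_that("dual solution matches the primal oracle on random instances", {
    set.seed(99)
    taus <- c(0, 0.25, 0.5, 0.75, 1)
    for (r in 1:12) {
        n <- sample(2:10, 1); m <- sample(2:10, 1); N <- sample(5:25, 1)
        reg <- regPair(sample(taus, 1), sample(taus, 1))
        p <- stdPair(randomOmics(n, N, "x"), randomOmics(m, N, "y"))
        d <- min(2L, n, m, N - 1L)
        sol <- suppressWarnings(
            solveRccaDual(gramMatrix(p$X), gramMatrix(p$Y), reg, d))
        orc <- suppressWarnings(primalRccaOracle(p$X, p$Y, reg, d))
        dd <- min(length(sol@rho), length(orc@penalizedCorrelations))
        expect_lt(max(abs(sol@rho[seq_len(dd)] -
                          orc@penalizedCorrelations[seq_len(dd)])), 1e-8)
        mod <- weightsFromDual(p$X, p$Y, sol, p$mx, p$my)
        for (j in seq_len(dd)) {
            ## only compare directions for well-separated eigenvalues
            gap <- if (dd > 1) min(abs(diff(sol@rho))) else 1
            if (gap > 1e-6) {
                expect_gt(absCosine(mod@Wx[, j], orc@Wx[, j]), 1 - 1e-8)
                expect_gt(absCosine(mod@Wy[, j], orc@Wy[, j]), 1 - 1e-8)
            }
        }
    }
})

test_that("1-D unregularized CCA is the absolute Pearson correlation", {
    set.seed(5)
    p <- stdPair(randomOmics(1, 20, "x"), randomOmics(1, 20, "y"))
    orc <- suppressWarnings(primalRccaOracle(p$X, p$Y, regPair(0, 0), d = 1))
    expect_equal(orc@penalizedCorrelations[1],
                 abs(cor(omicsValues(p$X)[1, ], omicsValues(p$Y)[1, ])),
                 tolerance = 1e-10)
})

test_that("swapping X and Y swaps the weight sets and keeps rho", {
    set.seed(13)
    X <- randomOmics(5, 15, "x"); Y <- randomOmics(7, 15, "y")
    reg <- regPair(0.3, 0.6); regSwap <- regPair(0.6, 0.3)
    a <- fitRcca(X, Y, reg, d = 2)
    b <- fitRcca(Y, X, regSwap, d = 2)
    expect_equal(a@penalizedCorrelations, b@penalizedCorrelations,
                 tolerance = 1e-8)
    expect_equal(trainCorrelations(a), trainCorrelations(b),
                 tolerance = 1e-8)
    for (j in 1:2) {
        expect_gt(absCosine(a@Wx[, j], b@Wy[, j]), 1 - 1e-8)
        expect_gt(absCosine(a@Wy[, j], b@Wx[, j]), 1 - 1e-8)
    }
})

test_that("weight recovery normalizes, sign-fixes, and reproduces rho from scores", {
    set.seed(31)
    p <- stdPair(randomOmics(6, 14, "x"), randomOmics(4, 14, "y"))
    reg <- regPair(0.5, 0.2)
    sol <- solveRccaDual(gramMatrix(p$X), gramMatrix(p$Y), reg, d = 2)
    mod <- weightsFromDual(p$X, p$Y, sol, p$mx, p$my)
    ## sign convention
    for (j in 1:2)
        expect_gt(mod@Wx[which.max(abs(mod@Wx[, j])), j], 0)
    ## penalized denominator of each column is 1
    N <- 14
    for (j in 1:2) {
        w <- mod@Wx[, j]
        den <- (1 - reg@tauX) * sum(crossprod(omicsValues(p$X), w)^2) +
            reg@tauX * N * sum(w^2)
        expect_equal(den, 1, tolerance = 1e-10)
    }
    ## empirical training correlation of projections reproduces rho at tau = 0
    sol0 <- suppressWarnings(
        solveRccaDual(gramMatrix(p$X), gramMatrix(p$Y), regPair(0, 0), 2))
    mod0 <- weightsFromDual(p$X, p$Y, sol0, p$mx, p$my)
    sx <- projectSamples(mod0, p$X, "x", standardize = FALSE)
    sy <- projectSamples(mod0, p$Y, "y", standardize = FALSE)
    expect_equal(unname(canonicalCorrelation(sx, sy)), sol0@rho,
                 tolerance = 1e-8)
    ## zero dual vector is rejected
    solBad <- sol
    solBad@alphaX[, 1] <- 0
    expect_error(weightsFromDual(p$X, p$Y, solBad, p$mx, p$my), "zero dual")
})

test_that("projection preserves sample order and duplicates map identically", {
    set.seed(41)
    X <- randomOmics(5, 12, "x"); Y <- randomOmics(5, 12, "y")
    fit <- fitRcca(X, Y, regPair(0.4, 0.4), d = 2)
    sx <- projectSamples(fit, X, "x")
    expect_identical(rownames(sx), sampleIds(X))
    ## training projections reproduce the training correlations
    sy <- projectSamples(fit, Y, "y")
    expect_equal(unname(canonicalCorrelation(sx, sy)),
                 trainCorrelations(fit), tolerance = 1e-8)
    ## duplicated sample values give identical score rows
    v <- omicsValues(X)[, c("s1", "s1", "s3")]
    colnames(v) <- c("a", "b", "c")
    sd2 <- projectSamples(fit, PairedOmicsMatrix(v), "x")
    expect_equal(sd2["a", ], sd2["b", ])
})

test_that("canonicalCorrelation uses absolute values and flags zero variance", {
    expect_equal(canonicalCorrelation(cbind(1:3), cbind(3:1)), 1)
    expect_equal(canonicalCorrelation(cbind(1:4), cbind(c(1, -1, -1, 1))), 0)
    set.seed(2)
    a <- matrix(rnorm(20), 10, 2); b <- matrix(rnorm(20), 10, 2)
    expect_equal(canonicalCorrelation(a, b),
                 abs(c(cor(a[, 1], b[, 1]), cor(a[, 2], b[, 2]))),
                 tolerance = 1e-12)
    expect_warning(z <- canonicalCorrelation(cbind(rep(1, 5)), cbind(1:5)),
                   "zero-variance")
    expect_equal(z, 0)
})

test_that("overfitting: tau = 0 interpolates in high dimension but does not generalize", {
    set.seed(77)
    X <- randomOmics(1000, 30, "x")
    Y <- randomOmics(1000, 30, "y")
    fit <- suppressWarnings(fitRcca(X, Y, regPair(0, 0), d = 1))
    expect_gte(trainCorrelations(fit)[1], 0.999)
    Xf <- randomOmics(1000, 30, "x"); Yf <- randomOmics(1000, 30, "y")
    vc <- canonicalCorrelation(projectSamples(fit, Xf, "x"),
                               projectSamples(fit, Yf, "y"))
    ## null spread of |cor| at N = 30: mean sqrt(2 / (pi 30)), sd ~ 0.11
    expect_lt(vc, sqrt(2 / (pi * 30)) + 4 * 0.11)
})
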