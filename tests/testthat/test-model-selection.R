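test_that("stratified split hits exact per-label proportions and is deterministic", {
    ids <- paste0("s", 1:12)
    labels <- setNames(rep(c("a", "b", "c"), c(6, 3, 3)), ids)
    plan <- makeSplit(ids, labels, tuningFraction = 2 / 3, k = 3, seed = 5)
    tunLab <- table(labels[plan@tuningIds])
    expect_equal(as.integer(tunLab[c("a", "b", "c")]), c(4, 2, 2))
    plan2 <- makeSplit(ids, labels, tuningFraction = 2 / 3, k = 3, seed = 5)
    expect_identical(plan@tuningIds, plan2@tuningIds)
    expect_identical(plan@folds, plan2@folds)
    ## different seed gives a different plan
    plan3 <- makeSplit(ids, labels, tuningFraction = 2 / 3, k = 3, seed = 6)
    expect_false(identical(plan@tuningIds, plan3@tuningIds))
})

test_that("unlabeled folds are balanced and k is validated", {
    plan <- makeSplit(paste0("s", 1:30), seed = 1)
    sizes <- lengths(plan@folds)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_length(plan@tuningIds, 20L)
    expect_error(makeSplit(paste0("s", 1:4), k = 3), "at least 2k")
})

test_that("cv correlation is 1 for an exact copy and the guard matches a manual loop", {
    p <- identicalPair(N = 18)
    plan <- makeSplit(sampleIds(p$X), seed = 3, tuningFraction = 1)
    rho <- cvCanonicalCorrelation(p$X, p$Y, regPair(0.5, 0.5), plan)
    expect_equal(rho, 1, tolerance = 1e-10)

    ## the estimator equals a manual fold loop standardizing with
    ## training-fold statistics only, and differs from a leaky variant that
    ## standardizes on all tuning samples
    set.seed(9)
    X <- randomOmics(20, 24, "x"); Y <- randomOmics(15, 24, "y")
    plan <- makeSplit(sampleIds(X), seed = 2, tuningFraction = 1)
    reg <- regPair(0.4, 0.4)
    rho <- cvCanonicalCorrelation(X, Y, reg, plan)
    manual <- function(leaky) {
        mean(sapply(plan@folds, function(te) {
            tr <- setdiff(plan@tuningIds, te)
            base <- if (leaky) plan@tuningIds else tr
            mx <- fitStandardization(subsetOmics(X, samples = base))
            my <- fitStandardization(subsetOmics(Y, samples = base))
            Xtr <- applyStandardization(mx, subsetOmics(X, samples = tr))
            Ytr <- applyStandardization(my, subsetOmics(Y, samples = tr))
            sol <- solveRccaDual(gramMatrix(Xtr), gramMatrix(Ytr), reg, 1)
            mod <- weightsFromDual(Xtr, Ytr, sol, mx, my)
            sx <- crossprod(omicsValues(applyStandardization(
                mx, subsetOmics(X, samples = te))), mod@Wx)
            sy <- crossprod(omicsValues(applyStandardization(
                my, subsetOmics(Y, samples = te))), mod@Wy)
            canonicalCorrelation(sx, sy)
        }))
    }
    expect_equal(rho, manual(leaky = FALSE), tolerance = 1e-12)
    expect_false(isTRUE(all.equal(rho, manual(leaky = TRUE),
                                  tolerance = 1e-6)))
})

test_that("cv correlation on independent noise stays small", {
    rhos <- vapply(1:15, function(s) {
        X <- randomOmics(200, 60, "x", seed = s)
        Y <- randomOmics(200, 60, "y", seed = s + 500)
        plan <- makeSplit(sampleIds(X), seed = s, tuningFraction = 1)
        cvCanonicalCorrelation(X, Y, regPair(0.9, 0.5), plan)
    }, numeric(1))
    expect_lt(mean(rhos), 0.3)
    expect_true(all(rhos >= 0 & rhos <= 1))
})

test_that("grid search covers the grid, reuses one plan, and tie-breaks upward", {
    ## exact-copy pair: every grid point gives rho_cv 1, the tie-break picks
    ## the strongest regularization
    p <- identicalPair(N = 18)
    plan <- makeSplit(sampleIds(p$X), seed = 4, tuningFraction = 1)
    res <- gridSearch(p$X, p$Y, plan, taus = c(0.5, 1))
    expect_equal(nrow(cvGrid(res)), 4L)
    expect_true(all(abs(cvGrid(res)$rho_cv_1 - 1) < 1e-10))
    expect_equal(bestRegularization(res)@tauX, 1)
    expect_equal(bestRegularization(res)@tauY, 1)
    ## the default grid contains the resolution the optimum needs
    taus <- seq(0, 1, by = 0.1)
    expect_true(any(abs(taus - 0.9) < 1e-12) && any(abs(taus - 0.3) < 1e-12))
    expect_equal(length(taus)^2, 121L)
})

test_that("grid search result agrees with cvCanonicalCorrelation pointwise", {
    sim <- generatePaired(syntheticPreset("collinear_blocks", N = 60),
                          seed = 12)
    plan <- makeSplit(sampleIds(sim$X), seed = 12, tuningFraction = 1)
    res <- gridSearch(sim$X, sim$Y, plan, taus = c(0.2, 0.8))
    g <- cvGrid(res)
    for (i in seq_len(nrow(g))) {
        direct <- cvCanonicalCorrelation(
            sim$X, sim$Y, regPair(g$tau_x[i], g$tau_y[i]), plan)
        expect_equal(g$rho_cv_1[i], direct, tolerance = 1e-8)
    }
})

test_that("permutation null is reproducible, bounded, and excludes identity", {
    sim <- generatePaired(syntheticPreset("collinear_blocks", N = 45),
                          seed = 6)
    plan <- makeSplit(sampleIds(sim$X), seed = 6, tuningFraction = 1)
    reg <- regPair(0.9, 0.5)
    a <- permutationNull(sim$X, sim$Y, reg, plan, B = 5, seed = 8)
    b <- permutationNull(sim$X, sim$Y, reg, plan, B = 5, seed = 8)
    expect_identical(a@values, b@values)
    expect_true(all(a@values >= 0 & a@values <= 1))
    expect_equal(a@B, 5L)
    ## a genuine permutation destroys the strong correlation: every null
    ## value sits well below the unpermuted estimate
    rho <- cvCanonicalCorrelation(sim$X, sim$Y, reg, plan)
    expect_true(all(a@values < rho))
    expect_error(permutationNull(sim$X, sim$Y, reg, plan, B = 1), "at least 2")
})

test_that("null and unpermuted rho_cv distributions overlap on independent data", {
    unperm <- numeric(10); nulls <- numeric(10)
    for (s in 1:10) {
        X <- randomOmics(40, 30, "x", seed = s)
        Y <- randomOmics(40, 30, "y", seed = s + 900)
        plan <- makeSplit(sampleIds(X), seed = s, tuningFraction = 1)
        reg <- regPair(0.5, 0.5)
        unperm[s] <- cvCanonicalCorrelation(X, Y, reg, plan)
        nulls[s] <- permutationNull(X, Y, reg, plan, B = 2,
                                    seed = s)@values[1]
    }
    expect_gt(t.test(unperm, nulls)$p.value, 0.05)
})
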