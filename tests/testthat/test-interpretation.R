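test_that("cross-loadings are correlations with the expected equivariances", {
    set.seed(3)
    N <- 20
    scores <- cbind(f1 = rnorm(N), f2 = rnorm(N))
    m <- rbind(v1 = scores[, 1], v2 = rnorm(N), v3 = c(1, -1, -1, 1,
               rnorm(N - 4)))
    colnames(m) <- paste0("s", 1:N)
    pom <- PairedOmicsMatrix(m)
    cl <- crossLoadings(pom, scores)
    expect_equal(unname(cl@values["v1", "f1"]), 1)
    expect_equal(unname(cl@values), unname(cor(t(m), scores)),
                 tolerance = 1e-12)
    ## scale/sign equivariance in the scores
    up <- crossLoadings(pom, scores * 5)
    dn <- crossLoadings(pom, scores * -5)
    expect_equal(up@values, cl@values, tolerance = 1e-12)
    expect_equal(dn@values, -cl@values, tolerance = 1e-12)
    ## symmetric orthogonal contrast
    v <- PairedOmicsMatrix(matrix(1:4, 1, 4,
        dimnames = list("v1", paste0("s", 1:4))))
    s <- cbind(f1 = c(1, -1, -1, 1))
    expect_equal(unname(crossLoadings(v, s)@values[1, 1]), 0)
})

test_that("redundancy is the mean squared loading with hand-checked values", {
    mk <- function(vals) new("CrossLoadingMatrix",
        values = matrix(vals, ncol = 1,
                        dimnames = list(paste0("v", seq_along(vals)), "f1")),
        featureSource = "y", basis = "cross")
    expect_equal(unname(redundancy(mk(c(0.6, 0.8)))), 0.5)
    expect_equal(unname(redundancy(mk(c(1, 1, 1)))), 1)
    expect_equal(unname(redundancy(mk(c(0, 0)))), 0)
    ## bounds under fuzzing
    set.seed(17)
    for (r in 1:25) {
        vals <- runif(sample(2:40, 1), -1, 1)
        R <- redundancy(mk(vals))
        expect_true(R >= 0 && R <= 1)
        expect_equal(unname(R), mean(vals^2))
    }
    ## all-duplicated variable set equals the single variable's squared
    ## loading
    expect_equal(unname(redundancy(mk(rep(0.7, 9)))), 0.49)
})

test_that("top variables rank by |loading| with lexicographic ties", {
    vals <- c(a2 = 0.5, a1 = -0.5, b = 0.9, c = -0.2, d = 0.1)
    cl <- new("CrossLoadingMatrix",
              values = matrix(vals, ncol = 1,
                              dimnames = list(names(vals), "f1")),
              featureSource = "y", basis = "cross")
    top <- topVariables(cl, j = 1, k = 3)
    expect_identical(top$variable_id, c("b", "a1", "a2"))
    expect_error(topVariables(cl, j = 1, k = 10), "exceeds")
})

test_that("genome ordering follows karyotype order and flags unplaced variables", {
    ann <- data.frame(
        variable_id = c("v1", "v2", "v3", "v4"),
        chromosome = c("10", "2", "2", "X"),
        position = c(100L, 900L, 500L, 50L))
    vals <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5), ncol = 1,
                   dimnames = list(c("v1", "v2", "v3", "v4", "v5"), "f1"))
    cl <- new("CrossLoadingMatrix", values = vals, featureSource = "y",
              basis = "cross")
    res <- genomeOrderedLoadings(cl, ann)
    expect_identical(res$table$variable_id,
                     c("v3", "v2", "v1", "v4", "v5"))
    expect_false(res$table$placed[5])
    expect_equal(unname(res$boundaries[c("2", "10", "X")]), c(2L, 3L, 4L))
    annBad <- ann; annBad$chromosome[1] <- "chr99"
    expect_error(genomeOrderedLoadings(cl, annBad), "malformed")
})

test_that("sample coordinates are standardized, scale-invariant, and coincide at rho 1", {
    p <- identicalPair(N = 16)
    ## add a second independent variable so d = 2 exists
    set.seed(4)
    addRow <- function(pom, id) {
        v <- rbind(omicsValues(pom), rnorm(16))
        rownames(v) <- c(rownames(omicsValues(pom)), id)
        PairedOmicsMatrix(v)
    }
    X <- addRow(p$X, "x2"); Y <- addRow(p$Y, "y2")
    fit <- suppressWarnings(fitRcca(X, Y, regPair(0, 0), d = 2))
    co <- sampleCoordinates(fit, X, Y)
    cx <- co[co$side == "x", ]; cy <- co[co$side == "y", ]
    expect_equal(sd(cx$f1), 1, tolerance = 1e-8)
    expect_equal(sd(cy$f2), 1, tolerance = 1e-8)
    ## first pair has training correlation 1 (shared variable): the x and y
    ## points coincide on f1
    expect_equal(trainCorrelations(fit)[1], 1, tolerance = 1e-8)
    expect_lt(max(abs(cx$f1 - cy$f1)), 1e-6)
    ## doubling all weights changes nothing after standardization
    fit2 <- fit
    fit2@Wx <- fit@Wx * 2; fit2@Wy <- fit@Wy * 2
    co2 <- sampleCoordinates(fit2, X, Y)
    expect_equal(co2$f1, co$f1, tolerance = 1e-10)
    expect_equal(co2$f2, co$f2, tolerance = 1e-10)
})

test_that("cross-loadings equal own-loadings when the canonical correlation is 1", {
    p <- identicalPair(N = 20)
    fit <- suppressWarnings(fitRcca(p$X, p$Y, regPair(0, 0), d = 1))
    Xs <- applyStandardization(fit@stdX, p$X)
    sx <- projectSamples(fit, p$X, "x")
    sy <- projectSamples(fit, p$Y, "y")
    crossL <- crossLoadings(Xs, sy, "y", "cross")
    ownL <- crossLoadings(Xs, sx, "x", "own")
    expect_equal(crossL@values, ownL@values, tolerance = 1e-8)
})

test_that("redundancyTable produces the four summaries within bounds", {
    sim <- generatePaired(syntheticPreset("collinear_blocks", N = 50),
                          seed = 9)
    fit <- fitRcca(sim$X, sim$Y, regPair(0.5, 0.5), d = 2)
    tab <- redundancyTable(fit, sim$X, sim$Y)
    expect_identical(colnames(tab), c("feature", "R_x_given_y",
                                      "R_y_given_x", "R_x_given_x",
                                      "R_y_given_y"))
    nums <- unlist(tab[, -1])
    expect_true(all(nums >= 0 & nums <= 1))
})
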