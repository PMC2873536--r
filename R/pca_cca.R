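#' Dual principal component analysis of one variable set
#'
#' Computes the top-s principal components through the eigendecomposition of
#' the N x N Gram matrix K = X'X (the variables x variables covariance is
#' never formed). Loadings are the orthonormal columns of
#' Pi = X V Lambda^{-1/2}; sample scores are X'Pi = V Lambda^{1/2} and are
#' mean-centered because the rows of X are.
#'
#' @param standardized a standardized \linkS4class{PairedOmicsMatrix}.
#' @param s number of components, at most min(N - 1, number of variables).
#' @return list with elements \code{basis} (a \linkS4class{PcaBasis}) and
#'   \code{scores} (samples x s matrix).
#' @export
dualPca <- function(standardized, s = 12L) {
    v <- omicsValues(standardized)
    N <- ncol(v); n <- nrow(v)
    s <- as.integer(s)
    if (s < 1L || s > min(N - 1L, n))
        stop("s must lie in [1, min(N - 1, n)] = [1, ", min(N - 1L, n), "]")
    K <- gramMatrix(standardized)
    eig <- eigen(K, symmetric = TRUE)
    lam <- pmax(eig$values, 0)
    if (lam[s] <= max(lam) * 1e-12)
        stop("requested s exceeds the numerical rank of the matrix")
    tot <- sum(lam)
    V <- eig$vectors[, seq_len(s), drop = FALSE]
    ls <- lam[seq_len(s)]
    Pi <- v %*% V %*% diag(1 / sqrt(ls), s)
    rownames(Pi) <- variableIds(standardized)
    colnames(Pi) <- paste0("PC", seq_len(s))
    scores <- V %*% diag(sqrt(ls), s)
    dimnames(scores) <- list(sampleIds(standardized), colnames(Pi))
    basis <- new("PcaBasis", components = Pi,
                 explainedVarianceFraction = ls / tot, s = s)
    list(basis = basis, scores = scores)
}

#' Classical (unregularized) CCA on low-dimensional score tables
#'
#' Runs textbook CCA on two samples x s score representations (the component
#' scores of a per-side PCA). Scores enter unscaled: classical CCA is
#' equivariant to the scale of individual variables.
#'
#' @param scoresX,scoresY samples x s numeric matrices over the same samples.
#' @param d number of canonical pairs, at most min(sx, sy).
#' @return list with \code{wX} (sx x d), \code{wY} (sy x d) and
#'   \code{correlations} (absolute training canonical correlations).
#' @export
classicalCca <- function(scoresX, scoresY, d = 2L) {
    scoresX <- as.matrix(scoresX); scoresY <- as.matrix(scoresY)
    N <- nrow(scoresX)
    if (nrow(scoresY) != N)
        stop("score tables must share the sample set")
    if (min(ncol(scoresX), ncol(scoresY)) >= N)
        stop("score dimension must be below the sample count; reduce s")
    Xc <- t(scoresX) - rowMeans(t(scoresX))
    Yc <- t(scoresY) - rowMeans(t(scoresY))
    rk <- function(M) qr(M)$rank
    if (rk(Xc) < nrow(Xc) || rk(Yc) < nrow(Yc))
        stop("singular score covariance; use a smaller s")
    res <- .penalizedPrimal(Xc, Yc, 0, 0, d, warnSingular = FALSE)
    corr <- canonicalCorrelation(crossprod(Xc, res$Wx), crossprod(Yc, res$Wy))
    list(wX = res$Wx, wY = res$Wy, correlations = corr)
}

#' Fit the PCA+CCA model
#'
#' Standardizes both variable sets, reduces each side separately to s
#' principal components via [dualPca()], runs classical CCA on the component
#' scores, and combines the two weight layers into total per-variable weights
#' W = Pi w-hat. Because highly correlated variables receive similar loadings
#' in each principal component, they also receive similar total weights --
#' the characteristic (and deliberately less flexible) behavior of this
#' variant compared to regularized dual CCA.
#'
#' @param X,Y \linkS4class{PairedOmicsMatrix} objects sharing sample order.
#' @param s retained components per side (default 12); either one value for
#'   both sides or a length-2 vector c(sX, sY).
#' @param d number of canonical pairs.
#' @param convention standardization convention.
#' @return A \linkS4class{PcaCcaModel}; its \code{totalModel} slot is a
#'   \linkS4class{CanonicalModel} projectable onto new data exactly like an
#'   rcca model.
#' @examples
#' sim <- generatePaired(syntheticPreset("collinear_blocks", N = 60), seed = 1)
#' fit <- fitPcaCca(sim$X, sim$Y, s = 5, d = 2)
#' trainCorrelations(fit@totalModel)
#' @export
fitPcaCca <- function(X, Y, s = 12L, d = 2L, convention = "population") {
    if (!identical(sampleIds(X), sampleIds(Y)))
        stop("X and Y must share the same samples in the same order; ",
             "see alignPair()")
    s <- rep(as.integer(s), length.out = 2L)
    sx <- standardizeOmics(X, convention)
    sy <- standardizeOmics(Y, convention)
    px <- dualPca(sx$data, s[1L])
    py <- dualPca(sy$data, s[2L])
    cca <- classicalCca(px$scores, py$scores, d)
    Wx <- px$basis@components %*% cca$wX
    Wy <- py$basis@components %*% cca$wY
    ## flip score-level and total weights together so W = Pi w-hat stays exact
    wX <- cca$wX; wY <- cca$wY
    for (j in seq_len(ncol(Wx))) {
        i <- which.max(abs(Wx[, j]))
        if (Wx[i, j] < 0) {
            Wx[, j] <- -Wx[, j]; Wy[, j] <- -Wy[, j]
            wX[, j] <- -wX[, j]; wY[, j] <- -wY[, j]
        }
    }
    rownames(Wx) <- variableIds(sx$data)
    rownames(Wy) <- variableIds(sy$data)
    total <- new("CanonicalModel", Wx = Wx, Wy = Wy,
                 correlationsTrain = cca$correlations,
                 penalizedCorrelations = cca$correlations,
                 method = "pca_cca", regularization = NULL,
                 stdX = sx$model, stdY = sy$model)
    new("PcaCcaModel", basisX = px$basis, basisY = py$basis,
        ccaWeightsX = wX, ccaWeightsY = wY, totalModel = total)
}
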