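#' Gram matrix of a standardized variable set
#'
#' Computes the N x N matrix of inner products between sample columns,
#' K = X'X. All dual computations work with K instead of the (potentially
#' enormous) variables x variables covariance matrix XX', so cost scales with
#' the number of samples.
#'
#' @param standardized a standardized \linkS4class{PairedOmicsMatrix}.
#' @return symmetric N x N numeric matrix with sample ids as dimnames.
#' @export
gramMatrix <- function(standardized) {
    v <- omicsValues(standardized)
    if (any(!is.finite(v)))
        stop("non-finite entries in standardized matrix")
    K <- crossprod(v)
    (K + t(K)) / 2
}

## Symmetric whitening of a PSD matrix restricted to its numerical range:
## returns B with B' A B = I on the retained eigenspace. Directions with
## eigenvalue below floorRel * max are truncated -- for row-centered data the
## ones-vector always lies in the null space of the Gram matrix, so truncation
## (rather than additive jitter, which preserves that null space) is the exact
## resolution of the singular denominator.
.whitenPSD <- function(A, floorRel = 1e-10) {
    eig <- eigen(A, symmetric = TRUE)
    lam <- eig$values
    top <- max(lam, 0)
    if (top <= 0)
        stop("penalized denominator matrix is numerically zero")
    keep <- lam > top * floorRel
    list(B = eig$vectors[, keep, drop = FALSE] %*%
             diag(1 / sqrt(lam[keep]), sum(keep)),
         rank = sum(keep))
}

## Penalized denominator matrix of the dual problem for one side:
## (1 - tau) K^2 + tau * N * K.
.dualDenominator <- function(K, tau, N) {
    A <- (1 - tau) * (K %*% K) + tau * N * K
    (A + t(A)) / 2
}

#' Solve regularized CCA in the dual formulation
#'
#' Substituting w_x = X alpha_x, w_y = Y alpha_y into the penalized
#' correlation turns the problem into a generalized eigenproblem on the two
#' N x N Gram matrices: maximize alpha_x' K_X K_Y alpha_y subject to
#' alpha' ((1 - tau) K^2 + tau N K) alpha = 1 per side. It is solved by
#' whitening each penalized denominator on its numerical range and taking the
#' top-d singular triplets of the whitened numerator, which yields components
#' ordered by nonincreasing penalized objective and mutually orthogonal in
#' the penalized metric.
#'
#' At tau = 0 with a rank-deficient Gram matrix the denominator is singular;
#' the solver restricts to the range space and emits a warning (the
#' unregularized fit is then an overfit interpolator and should be read with
#' caution).
#'
#' @param Kx,Ky symmetric N x N Gram matrices (from [gramMatrix()]).
#' @param reg a \linkS4class{RegularizationPair}.
#' @param d number of component pairs, at most N - 1.
#' @param floorRel relative eigenvalue floor for the range restriction.
#' @return A \linkS4class{DualSolution}.
#' @export
solveRccaDual <- function(Kx, Ky, reg, d = 2L, floorRel = 1e-10) {
    stopifnot(is(reg, "RegularizationPair"))
    N <- nrow(Kx)
    if (!all(dim(Kx) == N) || !all(dim(Ky) == N))
        stop("Gram matrices must be square with identical dimension")
    if (any(!is.finite(Kx)) || any(!is.finite(Ky)))
        stop("non-finite entries in Gram matrices")
    if (d > N - 1L)
        stop("d must be at most N - 1 = ", N - 1L)
    Ax <- .dualDenominator(Kx, reg@tauX, N)
    Ay <- .dualDenominator(Ky, reg@tauY, N)
    wx <- .whitenPSD(Ax, floorRel)
    wy <- .whitenPSD(Ay, floorRel)
    ## at tau = 0 a full-rank Gram (more variables than samples) means the
    ## primal covariance is singular: the fit interpolates the training
    ## samples and the range restriction resolves the ambiguity
    if (reg@tauX == 0 && wx$rank >= N - 1L)
        warning("full-rank Gram matrix at tau_x = 0: the unregularized ",
                "fit interpolates the training samples (likely overfit)")
    if (reg@tauY == 0 && wy$rank >= N - 1L)
        warning("full-rank Gram matrix at tau_y = 0: the unregularized ",
                "fit interpolates the training samples (likely overfit)")
    M <- t(wx$B) %*% Kx %*% Ky %*% wy$B
    sv <- svd(M)
    avail <- min(d, length(sv$d))
    rho <- sv$d[seq_len(avail)]
    keep <- rho >= 1e-10
    if (!all(keep)) {
        warning("dropping ", sum(!keep),
                " degenerate component(s) with penalized objective < 1e-10")
        avail <- sum(keep)
        rho <- rho[seq_len(avail)]
    }
    if (avail < d)
        warning("only ", avail, " of ", d, " requested components available")
    if (avail == 0L)
        stop("no non-degenerate components found")
    idx <- seq_len(avail)
    new("DualSolution",
        alphaX = wx$B %*% sv$u[, idx, drop = FALSE],
        alphaY = wy$B %*% sv$v[, idx, drop = FALSE],
        rho = rho, regularization = reg)
}

## Sign convention: per component, flip both sides so the entry of Wx with
## the largest absolute value is positive (there is no canonical sign for a
## canonical feature pair).
.applySignConvention <- function(Wx, Wy) {
    for (j in seq_len(ncol(Wx))) {
        i <- which.max(abs(Wx[, j]))
        if (Wx[i, j] < 0) {
            Wx[, j] <- -Wx[, j]
            Wy[, j] <- -Wy[, j]
        }
    }
    list(Wx = Wx, Wy = Wy)
}

## Rescale weight columns to unit penalized denominator
## (1 - tau) |X'w|^2 + tau * N * |w|^2 = 1, computed in the primal.
.normalizeWeights <- function(W, Xv, tau, N) {
    for (j in seq_len(ncol(W))) {
        w <- W[, j]
        den <- (1 - tau) * sum((crossprod(Xv, w))^2) + tau * N * sum(w^2)
        if (den <= 0)
            stop("zero weight vector is not a valid component")
        W[, j] <- w / sqrt(den)
    }
    W
}

#' Recover primal weights from a dual solution
#'
#' The canonical weight vectors are linear combinations of the (standardized)
#' sample columns: w_x = X alpha_x, w_y = Y alpha_y. Columns are rescaled to
#' unit penalized denominator and sign-fixed (largest-|entry| of Wx positive
#' per component, the same flip applied to Wy).
#'
#' @param Xstd,Ystd the standardized training matrices the Gram matrices were
#'   built from.
#' @param solution a \linkS4class{DualSolution}.
#' @param stdX,stdY the \linkS4class{StandardizationModel}s used (stored in
#'   the returned model so new data can be projected).
#' @return A \linkS4class{CanonicalModel} with method \code{"rcca_dual"}.
#' @export
weightsFromDual <- function(Xstd, Ystd, solution, stdX, stdY) {
    Xv <- omicsValues(Xstd); Yv <- omicsValues(Ystd)
    N <- ncol(Xv)
    if (nrow(solution@alphaX) != N || ncol(Yv) != N)
        stop("dual solution dimension does not match the training matrices")
    if (any(colSums(abs(solution@alphaX)) == 0) ||
        any(colSums(abs(solution@alphaY)) == 0))
        stop("zero dual coefficient vector is not a valid component")
    reg <- solution@regularization
    Wx <- .normalizeWeights(Xv %*% solution@alphaX, Xv, reg@tauX, N)
    Wy <- .normalizeWeights(Yv %*% solution@alphaY, Yv, reg@tauY, N)
    sgn <- .applySignConvention(Wx, Wy)
    rownames(sgn$Wx) <- variableIds(Xstd)
    rownames(sgn$Wy) <- variableIds(Ystd)
    corr <- canonicalCorrelation(crossprod(Xv, sgn$Wx), crossprod(Yv, sgn$Wy))
    new("CanonicalModel", Wx = sgn$Wx, Wy = sgn$Wy,
        correlationsTrain = corr, penalizedCorrelations = solution@rho,
        method = "rcca_dual", regularization = reg, stdX = stdX, stdY = stdY)
}

#' Fit regularized dual CCA on a paired training set
#'
#' Convenience wrapper: standardizes both sides (population-SD convention by
#' default), builds the Gram matrices, solves the dual generalized
#' eigenproblem and recovers the primal weights.
#'
#' @param X,Y \linkS4class{PairedOmicsMatrix} objects sharing the same sample
#'   order (see [alignPair()]).
#' @param reg a \linkS4class{RegularizationPair}.
#' @param d number of component pairs.
#' @param convention standardization convention, see [fitStandardization()].
#' @param floorRel relative eigenvalue floor, see [solveRccaDual()].
#' @return A \linkS4class{CanonicalModel}.
#' @examples
#' sim <- generatePaired(syntheticPreset("collinear_blocks", N = 60), seed = 1)
#' fit <- fitRcca(sim$X, sim$Y, regPair(0.5, 0.5), d = 2)
#' trainCorrelations(fit)
#' @export
fitRcca <- function(X, Y, reg, d = 2L, convention = "population",
                    floorRel = 1e-10) {
    if (!identical(sampleIds(X), sampleIds(Y)))
        stop("X and Y must share the same samples in the same order; ",
             "see alignPair()")
    sx <- standardizeOmics(X, convention)
    sy <- standardizeOmics(Y, convention)
    sol <- solveRccaDual(gramMatrix(sx$data), gramMatrix(sy$data),
                         reg, d, floorRel)
    weightsFromDual(sx$data, sy$data, sol, sx$model, sy$model)
}

## Penalized primal CCA on centered matrices (variables x samples), forming
## the dense covariance matrices. Shared by the oracle and classical CCA.
.penalizedPrimal <- function(Xc, Yc, tauX, tauY, d, floorRel = 1e-10,
                             warnSingular = TRUE) {
    N <- ncol(Xc)
    Cxx <- tcrossprod(Xc); Cyy <- tcrossprod(Yc); Cxy <- Xc %*% t(Yc)
    Ax <- (1 - tauX) * Cxx + tauX * N * diag(nrow(Cxx))
    Ay <- (1 - tauY) * Cyy + tauY * N * diag(nrow(Cyy))
    wx <- .whitenPSD((Ax + t(Ax)) / 2, floorRel)
    wy <- .whitenPSD((Ay + t(Ay)) / 2, floorRel)
    if (warnSingular && tauX == 0 && wx$rank < nrow(Cxx))
        warning("singular covariance at tau_x = 0; ",
                "restricted to the range space")
    if (warnSingular && tauY == 0 && wy$rank < nrow(Cyy))
        warning("singular covariance at tau_y = 0; ",
                "restricted to the range space")
    M <- t(wx$B) %*% Cxy %*% wy$B
    sv <- svd(M)
    avail <- min(d, sum(sv$d >= 1e-10))
    if (avail == 0L)
        stop("no non-degenerate components found")
    idx <- seq_len(avail)
    list(Wx = wx$B %*% sv$u[, idx, drop = FALSE],
         Wy = wy$B %*% sv$v[, idx, drop = FALSE],
         rho = sv$d[idx])
}

#' Primal brute-force oracle for regularized CCA
#'
#' Solves the penalized correlation problem directly in variable space,
#' forming the dense covariance matrices XX', YY', XY' and whitening the
#' penalized denominators (1 - tau) C + tau N I. Intended as an independent
#' correctness oracle for [solveRccaDual()] on problems small enough to form
#' the covariance matrices (n, m <= 2000).
#'
#' @param Xstd,Ystd standardized \linkS4class{PairedOmicsMatrix} objects.
#' @param reg a \linkS4class{RegularizationPair}.
#' @param d number of component pairs.
#' @param stdX,stdY optional standardization models to store in the result.
#' @param floorRel relative eigenvalue floor.
#' @return A \linkS4class{CanonicalModel} with method
#'   \code{"primal_oracle"}; its \code{penalizedCorrelations} slot holds the
#'   penalized objective values.
#' @export
primalRccaOracle <- function(Xstd, Ystd, reg, d = 2L, stdX = NULL,
                             stdY = NULL, floorRel = 1e-10) {
    Xv <- omicsValues(Xstd); Yv <- omicsValues(Ystd)
    if (nrow(Xv) > 2000L || nrow(Yv) > 2000L)
        stop("primal oracle is restricted to n, m <= 2000")
    if (ncol(Xv) != ncol(Yv))
        stop("X and Y must share the sample set")
    res <- .penalizedPrimal(Xv, Yv, reg@tauX, reg@tauY, d, floorRel)
    sgn <- .applySignConvention(res$Wx, res$Wy)
    rownames(sgn$Wx) <- variableIds(Xstd)
    rownames(sgn$Wy) <- variableIds(Ystd)
    if (is.null(stdX)) stdX <- .identityStd(Xstd)
    if (is.null(stdY)) stdY <- .identityStd(Ystd)
    corr <- canonicalCorrelation(crossprod(Xv, sgn$Wx), crossprod(Yv, sgn$Wy))
    new("CanonicalModel", Wx = sgn$Wx, Wy = sgn$Wy,
        correlationsTrain = corr, penalizedCorrelations = res$rho,
        method = "primal_oracle", regularization = reg,
        stdX = stdX, stdY = stdY)
}

## Identity standardization model (mean 0, sd 1 for every variable) used when
## a model is fitted directly on externally standardized data.
.identityStd <- function(pom) {
    ids <- variableIds(pom)
    new("StandardizationModel",
        means = stats::setNames(rep(0, length(ids)), ids),
        sds = stats::setNames(rep(1, length(ids)), ids),
        dropped = character(0), convention = "population")
}

#' Project samples onto canonical features
#'
#' Standardizes the data with the model's stored per-side standardization
#' statistics (training statistics, never the new data's own) and computes
#' sample scores X' W for the requested side.
#'
#' @param model a \linkS4class{CanonicalModel}.
#' @param data a \linkS4class{PairedOmicsMatrix} (raw values by default).
#' @param side \code{"x"} or \code{"y"}.
#' @param standardize apply the stored standardization (set to FALSE when
#'   the data are already standardized with the model's statistics).
#' @return samples x d numeric score matrix (rownames are sample ids).
#' @export
projectSamples <- function(model, data, side = c("x", "y"),
                           standardize = TRUE) {
    side <- match.arg(side)
    W <- canonicalWeights(model, side)
    std <- if (side == "x") model@stdX else model@stdY
    if (standardize)
        data <- applyStandardization(std, data)
    v <- omicsValues(data)
    if (!identical(rownames(v), rownames(W))) {
        if (!all(rownames(W) %in% rownames(v)))
            stop("data are missing variables required by the model")
        v <- v[rownames(W), , drop = FALSE]
    }
    crossprod(v, W)
}

#' Per-component absolute canonical correlation of paired score tables
#'
#' Returns the absolute Pearson correlation per component pair. Absolute
#' values are used throughout because the sign of a canonical feature pair is
#' arbitrary. A zero-variance score column yields 0 with a warning.
#'
#' @param scoresX,scoresY samples x d score matrices over the same samples.
#' @return numeric vector of d values in [0, 1].
#' @export
canonicalCorrelation <- function(scoresX, scoresY) {
    scoresX <- as.matrix(scoresX); scoresY <- as.matrix(scoresY)
    if (nrow(scoresX) != nrow(scoresY) || ncol(scoresX) != ncol(scoresY))
        stop("score tables must have identical dimensions")
    vapply(seq_len(ncol(scoresX)), function(j) {
        sx <- scoresX[, j]; sy <- scoresY[, j]
        if (stats::sd(sx) == 0 || stats::sd(sy) == 0) {
            warning("zero-variance score column; correlation set to 0")
            return(0)
        }
        min(abs(stats::cor(sx, sy)), 1)
    }, numeric(1))
}
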