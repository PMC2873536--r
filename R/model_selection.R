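## Evaluate an expression with a fixed RNG seed, restoring the caller's RNG
## state afterwards, so every randomized operation is deterministic given its
## seed argument and leaves the global stream untouched.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Stratified tuning/validation split with cross-validation folds
#'
#' Splits the samples into a tuning set (default two thirds, used for
#' parameter selection and feature extraction) and a validation set (the
#' remaining third, used only to assess generalization), then partitions the
#' tuning set into k cross-validation folds. When labels are given, each
#' part receives approximately the global label proportions (within one
#' rounding unit); otherwise the partition is uniformly random. Deterministic
#' given the seed.
#'
#' @param sampleIds character vector of sample ids.
#' @param labels optional per-sample labels (named by sample id, or in the
#'   order of \code{sampleIds}) for stratification.
#' @param tuningFraction fraction of samples assigned to the tuning set.
#' @param k fold count (default 3).
#' @param seed integer seed.
#' @return A \linkS4class{SplitPlan}.
#' @export
makeSplit <- function(sampleIds, labels = NULL, tuningFraction = 2 / 3,
                      k = 3L, seed = 1L) {
    n <- length(sampleIds)
    if (anyDuplicated(sampleIds)) stop("sample ids must be unique")
    if (n < 2L * k) stop("need at least 2k samples")
    if (!is.null(labels)) {
        if (is.null(names(labels))) {
            if (length(labels) != n) stop("labels must cover every sample")
            names(labels) <- sampleIds
        }
        if (!all(sampleIds %in% names(labels)))
            stop("labels must cover every sample id")
        labels <- labels[sampleIds]
    }
    strata <- if (is.null(labels)) rep("all", n) else as.character(labels)
    plan <- .withSeed(seed, {
        tuning <- character(0)
        for (lab in unique(strata)) {
            ids <- sample(sampleIds[strata == lab])
            ntune <- round(tuningFraction * length(ids))
            ntune <- max(0L, min(length(ids), ntune))
            tuning <- c(tuning, ids[seq_len(ntune)])
        }
        validation <- setdiff(sampleIds, tuning)
        if (length(tuning) < k)
            stop("k exceeds the tuning set size")
        folds <- vector("list", k)
        sizes <- integer(k)
        for (lab in unique(strata)) {
            ids <- sample(intersect(tuning, sampleIds[strata == lab]))
            for (id in ids) {
                f <- which.min(sizes)
                folds[[f]] <- c(folds[[f]], id)
                sizes[f] <- sizes[f] + 1L
            }
        }
        list(tuning = tuning, validation = validation, folds = folds)
    })
    lab_store <- if (is.null(labels)) character(0) else
        stats::setNames(as.character(labels), sampleIds)
    new("SplitPlan", tuningIds = plan$tuning,
        validationIds = plan$validation, folds = plan$folds,
        stratifyLabels = lab_store, seed = as.integer(seed))
}

## Per-fold training/test preparation: standardize on the training samples of
## the fold only (training-fold statistics, never the test fold's -- the
## leakage guard the cross-validated correlation depends on).
.foldData <- function(X, Y, trainIds, testIds, convention) {
    Xtr <- subsetOmics(X, samples = trainIds)
    Ytr <- subsetOmics(Y, samples = trainIds)
    mx <- fitStandardization(Xtr, convention)
    my <- fitStandardization(Ytr, convention)
    list(Xtr = applyStandardization(mx, Xtr),
         Ytr = applyStandardization(my, Ytr),
         Xte = applyStandardization(mx, subsetOmics(X, samples = testIds)),
         Yte = applyStandardization(my, subsetOmics(Y, samples = testIds)),
         mx = mx, my = my)
}

#' Cross-validated test-set canonical correlation
#'
#' For each fold: standardize using the other folds' samples only, fit the
#' model on them, project the held-out fold onto the j-th feature pair and
#' take the absolute Pearson correlation; the estimate is the mean over the
#' k folds. Absolute values are averaged because the sign of a canonical
#' feature pair is arbitrary.
#'
#' @param X,Y \linkS4class{PairedOmicsMatrix} objects covering at least the
#'   tuning samples of the plan.
#' @param reg a \linkS4class{RegularizationPair} (ignored for
#'   \code{method = "pca_cca"}).
#' @param plan a \linkS4class{SplitPlan}.
#' @param j component index (1 or 2); the model is fitted with d = j.
#' @param method \code{"rcca_dual"} or \code{"pca_cca"}.
#' @param s retained PCA components for \code{"pca_cca"}.
#' @param convention standardization convention.
#' @return scalar rho_cv in [0, 1].
#' @export
cvCanonicalCorrelation <- function(X, Y, reg, plan, j = 1L,
                                   method = c("rcca_dual", "pca_cca"),
                                   s = 12L, convention = "population") {
    method <- match.arg(method)
    vals <- vapply(seq_along(plan@folds), function(i) {
        testIds <- plan@folds[[i]]
        if (length(testIds) < 3L)
            stop("fold ", i, " has fewer than 3 test samples")
        trainIds <- setdiff(plan@tuningIds, testIds)
        fd <- .foldData(X, Y, trainIds, testIds, convention)
        if (method == "rcca_dual") {
            sol <- solveRccaDual(gramMatrix(fd$Xtr), gramMatrix(fd$Ytr),
                                 reg, d = j)
            model <- weightsFromDual(fd$Xtr, fd$Ytr, sol, fd$mx, fd$my)
        } else {
            sUse <- min(s, length(trainIds) - 1L,
                        nrow(omicsValues(fd$Xtr)), nrow(omicsValues(fd$Ytr)))
            px <- dualPca(fd$Xtr, sUse)
            py <- dualPca(fd$Ytr, sUse)
            cca <- classicalCca(px$scores, py$scores, d = j)
            model <- list(Wx = px$basis@components %*% cca$wX,
                          Wy = py$basis@components %*% cca$wY)
        }
        Wx <- if (is(model, "CanonicalModel")) model@Wx else model$Wx
        Wy <- if (is(model, "CanonicalModel")) model@Wy else model$Wy
        if (ncol(Wx) < j) return(NA_real_)
        sxte <- crossprod(omicsValues(fd$Xte), Wx[, j, drop = FALSE])
        syte <- crossprod(omicsValues(fd$Yte), Wy[, j, drop = FALSE])
        suppressWarnings(canonicalCorrelation(sxte, syte))
    }, numeric(1))
    if (anyNA(vals))
        stop("component ", j, " unavailable in at least one fold")
    mean(vals)
}

## Precomputed per-fold Grams and cross-Grams for the grid search: the
## standardized fold data do not depend on tau, so they are shared across all
## grid points. Test scores are computed through the cross-Gram
## X_test' X_train alpha = (X_test' X_train) alpha without forming weights.
.foldCache <- function(X, Y, plan, convention) {
    lapply(seq_along(plan@folds), function(i) {
        testIds <- plan@folds[[i]]
        if (length(testIds) < 3L)
            stop("fold ", i, " has fewer than 3 test samples")
        trainIds <- setdiff(plan@tuningIds, testIds)
        fd <- .foldData(X, Y, trainIds, testIds, convention)
        Xtr <- omicsValues(fd$Xtr); Ytr <- omicsValues(fd$Ytr)
        list(Kx = gramMatrix(fd$Xtr), Ky = gramMatrix(fd$Ytr),
             CxTest = crossprod(omicsValues(fd$Xte), Xtr),
             CyTest = crossprod(omicsValues(fd$Yte), Ytr))
    })
}

.gridRhoCv <- function(cache, reg, j) {
    vals <- vapply(cache, function(fc) {
        sol <- suppressWarnings(
            solveRccaDual(fc$Kx, fc$Ky, reg, d = j))
        if (length(sol@rho) < j) return(NA_real_)
        sx <- fc$CxTest %*% sol@alphaX[, j, drop = FALSE]
        sy <- fc$CyTest %*% sol@alphaY[, j, drop = FALSE]
        suppressWarnings(canonicalCorrelation(sx, sy))
    }, numeric(1))
    mean(vals)
}

#' Grid search for the ridge parameters by cross-validated correlation
#'
#' Computes the first-component cross-validated canonical correlation for
#' every (tau_x, tau_y) pair on the grid and selects the maximizer. Ties are
#' broken toward stronger regularization (larger tau_x + tau_y, then larger
#' tau_x), a stability preference. The second-component rho_cv is computed at
#' the selected pair only.
#'
#' @param X,Y \linkS4class{PairedOmicsMatrix} objects.
#' @param plan a \linkS4class{SplitPlan} (one fold assignment is reused
#'   across the whole grid so grid points differ only through tau).
#' @param taus numeric grid values for both axes (default 0, 0.1, ..., 1).
#' @param convention standardization convention.
#' @return A \linkS4class{CVResult}.
#' @export
gridSearch <- function(X, Y, plan, taus = seq(0, 1, by = 0.1),
                       convention = "population") {
    if (!length(taus)) stop("empty grid")
    cache <- .foldCache(X, Y, plan, convention)
    grid <- expand.grid(tau_x = taus, tau_y = taus,
                        KEEP.OUT.ATTRS = FALSE)
    grid$rho_cv_1 <- vapply(seq_len(nrow(grid)), function(i) {
        .gridRhoCv(cache, regPair(grid$tau_x[i], grid$tau_y[i]), 1L)
    }, numeric(1))
    top <- max(grid$rho_cv_1)
    cand <- grid[grid$rho_cv_1 >= top - 1e-12, , drop = FALSE]
    cand <- cand[order(-(cand$tau_x + cand$tau_y), -cand$tau_x), ,
                 drop = FALSE]
    best <- regPair(cand$tau_x[1L], cand$tau_y[1L])
    rho2 <- .gridRhoCv(cache, best, 2L)
    new("CVResult", grid = grid, best = best, rhoCv2 = rho2,
        k = length(plan@folds), seed = plan@seed)
}

#' Permutation null for the cross-validated canonical correlation
#'
#' Destroys the pairing by permuting the sample order of Y within the tuning
#' set (X untouched) -- once per instance, before the cross-validation loop,
#' so all folds of an instance share one permutation -- and recomputes rho_cv
#' with the fixed regularization. The identity permutation is excluded from
#' the draw. The resulting distribution estimates what rho_cv looks like when
#' there is no true correlation between the two sets.
#'
#' @param X,Y \linkS4class{PairedOmicsMatrix} objects.
#' @param reg the fixed \linkS4class{RegularizationPair} (typically the
#'   grid-search optimum).
#' @param plan a \linkS4class{SplitPlan}.
#' @param B number of permutation instances (default 50).
#' @param j component index.
#' @param seed integer seed for the permutation draws.
#' @param method,s,convention passed to [cvCanonicalCorrelation()].
#' @return A \linkS4class{PermutationNull}.
#' @export
permutationNull <- function(X, Y, reg, plan, B = 50L, j = 1L, seed = 1L,
                            method = "rcca_dual", s = 12L,
                            convention = "population") {
    B <- as.integer(B)
    if (B < 2L) stop("B must be at least 2")
    tun <- plan@tuningIds
    nt <- length(tun)
    vals <- .withSeed(seed, vapply(seq_len(B), function(b) {
        repeat {
            perm <- sample(nt)
            if (!all(perm == seq_len(nt))) break
        }
        Yp <- Y
        Yp@values[, tun] <- Y@values[, tun[perm]]
        cvCanonicalCorrelation(X, Yp, reg, plan, j = j, method = method,
                               s = s, convention = convention)
    }, numeric(1)))
    new("PermutationNull", B = B, values = vals, mean = mean(vals),
        sd = stats::sd(vals), seed = as.integer(seed))
}
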