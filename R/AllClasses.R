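#' @import methods
NULL

#' PairedOmicsMatrix: one variable set of a paired design
#'
#' Container for a variables x samples numeric matrix with unique variable and
#' sample identifiers and an optional per-variable genome annotation
#' (chromosome, 1-based position). Two such objects with a shared sample set
#' form the input of the canonical correlation machinery.
#'
#' @slot values numeric matrix, variables in rows, samples in columns;
#'   rownames are the variable ids, colnames the sample ids.
#' @slot annotation data.frame with columns \code{variable_id},
#'   \code{chromosome}, \code{position} covering every variable exactly once,
#'   or a zero-row data.frame when no annotation is attached.
#'
#' @export
setClass("PairedOmicsMatrix",
    representation(values = "matrix", annotation = "data.frame"),
    prototype(annotation = data.frame(variable_id = character(0),
                                      chromosome = character(0),
                                      position = integer(0))))

setValidity("PairedOmicsMatrix", function(object) {
    v <- object@values
    msg <- character(0)
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("'values' must carry variable ids as rownames and sample ids as colnames")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, "variable ids must be unique")
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, "sample ids must be unique")
    ann <- object@annotation
    if (nrow(ann) > 0L) {
        need <- c("variable_id", "chromosome", "position")
        if (!all(need %in% colnames(ann)))
            msg <- c(msg, "annotation needs columns variable_id, chromosome, position")
        else if (!setequal(ann$variable_id, rownames(v)) ||
                 anyDuplicated(ann$variable_id))
            msg <- c(msg, "annotation must cover every variable id exactly once")
    }
    if (length(msg)) msg else TRUE
})

#' Per-variable standardization model fitted on training samples
#'
#' Stores training means and standard deviations so that held-out data can be
#' standardized with the training statistics. Variables with zero training
#' variance are dropped and recorded.
#'
#' @slot means named numeric, training mean per retained variable.
#' @slot sds named numeric, training SD per retained variable (strictly
#'   positive).
#' @slot dropped character, ids of zero-variance variables excluded downstream.
#' @slot convention either \code{"population"} (divide by N; a standardized
#'   row has sum of squares exactly N) or \code{"sample"} (divide by N-1).
#'
#' @export
setClass("StandardizationModel",
    representation(means = "numeric", sds = "numeric",
                   dropped = "character", convention = "character"))

setValidity("StandardizationModel", function(object) {
    msg <- character(0)
    if (length(object@means) != length(object@sds))
        msg <- c(msg, "means and sds must have equal length")
    if (any(object@sds <= 0))
        msg <- c(msg, "retained variables must have strictly positive sd")
    if (!object@convention %in% c("population", "sample"))
        msg <- c(msg, "convention must be 'population' or 'sample'")
    if (length(msg)) msg else TRUE
})

#' Ridge regularization pair (tau_x, tau_y)
#'
#' tau = 0 gives classical CCA (pure correlation), tau = 1 the PLS limit
#' (pure covariance); intermediate values trade correlation against variance
#' of the extracted features.
#'
#' @slot tauX,tauY numeric scalars in the closed unit interval.
#' @export
setClass("RegularizationPair",
    representation(tauX = "numeric", tauY = "numeric"))

setValidity("RegularizationPair", function(object) {
    ok <- function(t) length(t) == 1L && is.finite(t) && t >= 0 && t <= 1
    if (!ok(object@tauX) || !ok(object@tauY))
        "tauX and tauY must be scalars in [0, 1]" else TRUE
})

setClassUnion("RegularizationPairOrNULL", c("RegularizationPair", "NULL"))

#' Dual coefficients of the regularized CCA eigenproblem
#'
#' Columns of \code{alphaX}/\code{alphaY} are dual coefficient vectors
#' (weights are recovered as w = X alpha), normalized so each column's
#' penalized denominator equals one; \code{rho} holds the penalized objective
#' values in nonincreasing order.
#'
#' @slot alphaX,alphaY N x d numeric matrices.
#' @slot rho numeric, penalized objective value per component, nonincreasing.
#' @slot regularization the \linkS4class{RegularizationPair} used.
#' @export
setClass("DualSolution",
    representation(alphaX = "matrix", alphaY = "matrix", rho = "numeric",
                   regularization = "RegularizationPair"))

setValidity("DualSolution", function(object) {
    msg <- character(0)
    d <- length(object@rho)
    if (ncol(object@alphaX) != d || ncol(object@alphaY) != d)
        msg <- c(msg, "alpha column count must equal length(rho)")
    if (nrow(object@alphaX) != nrow(object@alphaY))
        msg <- c(msg, "alphaX and alphaY must have the same number of rows")
    if (any(!is.finite(object@rho)))
        msg <- c(msg, "rho must be finite")
    if (d > 1L && any(diff(object@rho) > 1e-8))
        msg <- c(msg, "rho must be nonincreasing")
    if (length(msg)) msg else TRUE
})

#' Fitted canonical model in primal (variable) space
#'
#' Primal weight matrices for both variable sets, the training canonical
#' correlations (absolute Pearson correlation of the projected training
#' scores), and the standardization models needed to project new samples.
#'
#' @slot Wx,Wy variables x d weight matrices (rownames are variable ids).
#' @slot correlationsTrain numeric in [0, 1], one value per component.
#' @slot penalizedCorrelations numeric, the penalized objective per component
#'   (equals \code{correlationsTrain} at tau = 0; may exceed 1 for tau > 0).
#' @slot method one of \code{"rcca_dual"}, \code{"pca_cca"},
#'   \code{"primal_oracle"}.
#' @slot regularization a \linkS4class{RegularizationPair}, or NULL for
#'   pca_cca.
#' @slot stdX,stdY the \linkS4class{StandardizationModel} per side.
#' @export
setClass("CanonicalModel",
    representation(Wx = "matrix", Wy = "matrix",
                   correlationsTrain = "numeric",
                   penalizedCorrelations = "numeric",
                   method = "character",
                   regularization = "RegularizationPairOrNULL",
                   stdX = "StandardizationModel",
                   stdY = "StandardizationModel"))

setValidity("CanonicalModel", function(object) {
    msg <- character(0)
    d <- length(object@correlationsTrain)
    if (ncol(object@Wx) != d || ncol(object@Wy) != d)
        msg <- c(msg, "weight column counts must equal length(correlationsTrain)")
    if (any(object@correlationsTrain < -1e-12 | object@correlationsTrain > 1 + 1e-8))
        msg <- c(msg, "training correlations must lie in [0, 1]")
    if (!object@method %in% c("rcca_dual", "pca_cca", "primal_oracle"))
        msg <- c(msg, "unknown method")
    for (j in seq_len(d)) {
        wj <- object@Wx[, j]
        if (wj[which.max(abs(wj))] < 0) {
            msg <- c(msg, "sign convention violated: largest |entry| of Wx must be positive")
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' Orthonormal principal-component basis of one variable set
#'
#' @slot components variables x s matrix with orthonormal columns (loadings).
#' @slot explainedVarianceFraction numeric, nonincreasing fractions in [0, 1].
#' @slot s integer, retained component count.
#' @export
setClass("PcaBasis",
    representation(components = "matrix",
                   explainedVarianceFraction = "numeric", s = "integer"))

setValidity("PcaBasis", function(object) {
    msg <- character(0)
    if (ncol(object@components) != object@s)
        msg <- c(msg, "component count must equal s")
    evf <- object@explainedVarianceFraction
    if (length(evf) != object@s || any(evf < -1e-12 | evf > 1 + 1e-12) ||
        sum(evf) > 1 + 1e-8)
        msg <- c(msg, "explained variance fractions must lie in [0,1] and sum to at most 1")
    if (length(evf) > 1L && any(diff(evf) > 1e-10))
        msg <- c(msg, "explained variance fractions must be nonincreasing")
    G <- crossprod(object@components)
    if (max(abs(G - diag(nrow(G)))) > 1e-8)
        msg <- c(msg, "components must be orthonormal")
    if (length(msg)) msg else TRUE
})

#' PCA+CCA model: per-side PCA bases, score-level CCA weights, total model
#'
#' @slot basisX,basisY \linkS4class{PcaBasis} per side.
#' @slot ccaWeightsX,ccaWeightsY s x d weight matrices on component scores.
#' @slot totalModel \linkS4class{CanonicalModel} with total weights
#'   W = components %*% ccaWeights.
#' @export
setClass("PcaCcaModel",
    representation(basisX = "PcaBasis", basisY = "PcaBasis",
                   ccaWeightsX = "matrix", ccaWeightsY = "matrix",
                   totalModel = "CanonicalModel"))

setValidity("PcaCcaModel", function(object) {
    m <- object@totalModel
    dx <- max(abs(m@Wx - object@basisX@components %*% object@ccaWeightsX))
    dy <- max(abs(m@Wy - object@basisY@components %*% object@ccaWeightsY))
    if (dx > 1e-12 || dy > 1e-12)
        "total weights must equal components %*% ccaWeights" else TRUE
})

#' Tuning/validation split with cross-validation folds
#'
#' @slot tuningIds,validationIds disjoint character vectors covering all
#'   samples.
#' @slot folds list of k disjoint character vectors partitioning the tuning
#'   ids.
#' @slot stratifyLabels named character (per sample id) or zero-length when
#'   unstratified.
#' @slot seed integer seed that produced the plan.
#' @export
setClass("SplitPlan",
    representation(tuningIds = "character", validationIds = "character",
                   folds = "list", stratifyLabels = "character",
                   seed = "integer"))

setValidity("SplitPlan", function(object) {
    msg <- character(0)
    if (length(intersect(object@tuningIds, object@validationIds)))
        msg <- c(msg, "tuning and validation ids must be disjoint")
    fold_ids <- unlist(object@folds, use.names = FALSE)
    if (anyDuplicated(fold_ids) || !setequal(fold_ids, object@tuningIds))
        msg <- c(msg, "folds must partition the tuning ids")
    if (length(msg)) msg else TRUE
})

#' Cross-validated canonical correlation over a regularization grid
#'
#' @slot grid data.frame with columns tau_x, tau_y, rho_cv_1.
#' @slot best \linkS4class{RegularizationPair} maximizing rho_cv_1 (ties
#'   broken toward larger tau_x + tau_y, then larger tau_x).
#' @slot rhoCv2 numeric, second-component rho_cv at the best pair (NA when not
#'   computed).
#' @slot k integer fold count; @slot seed integer.
#' @export
setClass("CVResult",
    representation(grid = "data.frame", best = "RegularizationPair",
                   rhoCv2 = "numeric", k = "integer", seed = "integer"))

setValidity("CVResult", function(object) {
    g <- object@grid
    msg <- character(0)
    if (!all(c("tau_x", "tau_y", "rho_cv_1") %in% colnames(g)))
        msg <- c(msg, "grid needs columns tau_x, tau_y, rho_cv_1")
    else {
        if (any(g$rho_cv_1 < -1e-12 | g$rho_cv_1 > 1 + 1e-12))
            msg <- c(msg, "rho_cv values must lie in [0, 1]")
        top <- max(g$rho_cv_1)
        at_best <- abs(g$tau_x - object@best@tauX) < 1e-12 &
                   abs(g$tau_y - object@best@tauY) < 1e-12
        if (!any(at_best) || g$rho_cv_1[which(at_best)[1L]] < top - 1e-12)
            msg <- c(msg, "best must attain the grid maximum of rho_cv_1")
    }
    if (length(msg)) msg else TRUE
})

#' Permutation null distribution of the cross-validated canonical correlation
#'
#' @slot B integer permutation count.
#' @slot values numeric, B rho_cv estimates under sample permutation.
#' @slot mean,sd summary of values.
#' @slot seed integer.
#' @export
setClass("PermutationNull",
    representation(B = "integer", values = "numeric", mean = "numeric",
                   sd = "numeric", seed = "integer"))

setValidity("PermutationNull", function(object) {
    msg <- character(0)
    if (length(object@values) != object@B)
        msg <- c(msg, "values must have length B")
    if (any(object@values < -1e-12 | object@values > 1 + 1e-12))
        msg <- c(msg, "null values must lie in [0, 1]")
    if (abs(object@mean - mean(object@values)) > 1e-10 ||
        abs(object@sd - stats::sd(object@values)) > 1e-10)
        msg <- c(msg, "mean/sd must match values")
    if (length(msg)) msg else TRUE
})

#' Per-variable loadings on extracted features
#'
#' Entry (i, j) is the Pearson correlation of variable i with the j-th feature
#' scores. For \code{basis = "cross"} the scores come from the other variable
#' set (cross-loadings, the relevance measure); for \code{basis = "own"} from
#' the variable's own set.
#'
#' @slot values variables x d matrix of correlations in [-1, 1] (rownames are
#'   variable ids).
#' @slot featureSource which side's features the correlations are against
#'   (\code{"x"} or \code{"y"}).
#' @slot basis \code{"cross"} or \code{"own"}.
#' @export
setClass("CrossLoadingMatrix",
    representation(values = "matrix", featureSource = "character",
                   basis = "character"))

setValidity("CrossLoadingMatrix", function(object) {
    msg <- character(0)
    if (any(abs(object@values) > 1 + 1e-8, na.rm = TRUE))
        msg <- c(msg, "loadings must lie in [-1, 1]")
    if (is.null(rownames(object@values)))
        msg <- c(msg, "values must carry variable ids as rownames")
    if (!object@featureSource %in% c("x", "y"))
        msg <- c(msg, "featureSource must be 'x' or 'y'")
    if (!object@basis %in% c("cross", "own"))
        msg <- c(msg, "basis must be 'cross' or 'own'")
    if (length(msg)) msg else TRUE
})

#' Synthetic paired-data configuration
#'
#' Describes a latent-factor generative model for a paired data set: per
#' factor a target latent correlation rho between the x-side and y-side
#' drivers, contiguous x-variable blocks with common loading (mimicking
#' segmental copy-number alterations), a y-side loading block, optional
#' discrete sample groups shifting specific factors (mimicking disease
#' subtypes), and independent Gaussian noise.
#'
#' @slot N,nX,nY integer sample and variable counts.
#' @slot factors list; each element a list with entries \code{rho} (in [0,1]),
#'   \code{xBlocks} (list of c(start, end) index ranges, possibly empty),
#'   \code{xLoadings} (one loading per block), \code{yBlock} (c(start, end)),
#'   \code{yLoading} (scalar).
#' @slot groups list with entries \code{label} (character), \code{fraction}
#'   (sums to 1) and \code{shift} (groups x factors matrix of latent mean
#'   shifts), or an empty list for a single unlabeled population.
#' @slot noiseSdX,noiseSdY positive noise standard deviations.
#' @export
setClass("SyntheticConfig",
    representation(N = "integer", nX = "integer", nY = "integer",
                   factors = "list", groups = "list",
                   noiseSdX = "numeric", noiseSdY = "numeric"))

setValidity("SyntheticConfig", function(object) {
    msg <- character(0)
    if (object@noiseSdX <= 0 || object@noiseSdY <= 0)
        msg <- c(msg, "noise SDs must be positive")
    used_x <- integer(0); used_y <- integer(0)
    for (f in object@factors) {
        if (f$rho < 0 || f$rho > 1)
            msg <- c(msg, "factor rho must lie in [0, 1]")
        for (b in f$xBlocks) {
            if (b[1L] < 1L || b[2L] > object@nX || b[1L] > b[2L])
                msg <- c(msg, "x block out of range")
            used_x <- c(used_x, seq(b[1L], b[2L]))
        }
        if (length(f$xBlocks) != length(f$xLoadings))
            msg <- c(msg, "one x loading per x block required")
        b <- f$yBlock
        if (b[1L] < 1L || b[2L] > object@nY || b[1L] > b[2L])
            msg <- c(msg, "y block out of range")
        used_y <- c(used_y, seq(b[1L], b[2L]))
    }
    if (anyDuplicated(used_x))
        msg <- c(msg, "x blocks must be disjoint across factors")
    if (anyDuplicated(used_y))
        msg <- c(msg, "y blocks must be disjoint across factors")
    if (length(object@groups)) {
        fr <- object@groups$fraction
        if (abs(sum(fr) - 1) > 1e-8)
            msg <- c(msg, "group fractions must sum to 1")
        if (nrow(object@groups$shift) != length(object@groups$label) ||
            ncol(object@groups$shift) != length(object@factors))
            msg <- c(msg, "shift must be a groups x factors matrix")
    }
    if (length(msg)) msg else TRUE
})
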