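#' Construct a PairedOmicsMatrix
#'
#' @param values numeric matrix, variables in rows and samples in columns.
#' @param variableIds,sampleIds optional id vectors; taken from dimnames when
#'   omitted.
#' @param annotation optional data.frame with columns \code{variable_id},
#'   \code{chromosome}, \code{position}.
#' @return A \linkS4class{PairedOmicsMatrix}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' PairedOmicsMatrix(m)
#' @export
PairedOmicsMatrix <- function(values, variableIds = rownames(values),
                              sampleIds = colnames(values),
                              annotation = NULL) {
    values <- as.matrix(values)
    if (is.null(variableIds) || is.null(sampleIds))
        stop("variable and sample ids are required (as arguments or dimnames)")
    dimnames(values) <- list(as.character(variableIds), as.character(sampleIds))
    if (is.null(annotation))
        annotation <- data.frame(variable_id = character(0),
                                 chromosome = character(0),
                                 position = integer(0))
    new("PairedOmicsMatrix", values = values, annotation = annotation)
}

#' Construct a RegularizationPair
#' @param tauX,tauY ridge parameters in [0, 1].
#' @return A \linkS4class{RegularizationPair}.
#' @export
regPair <- function(tauX, tauY) {
    new("RegularizationPair", tauX = as.numeric(tauX), tauY = as.numeric(tauY))
}

#' @rdname PairedOmicsMatrix
#' @param x a PairedOmicsMatrix.
#' @export
omicsValues <- function(x) x@values

#' @rdname PairedOmicsMatrix
#' @export
variableIds <- function(x) rownames(x@values)

#' @rdname PairedOmicsMatrix
#' @export
sampleIds <- function(x) colnames(x@values)

#' @rdname PairedOmicsMatrix
#' @export
variableAnnotation <- function(x) x@annotation

#' Number of variables / samples of a PairedOmicsMatrix
#' @param x a \linkS4class{PairedOmicsMatrix}.
#' @export
nVariables <- function(x) nrow(x@values)

#' @rdname nVariables
#' @export
nSamples <- function(x) ncol(x@values)

#' Subset a PairedOmicsMatrix by variables and/or samples
#'
#' @param x a \linkS4class{PairedOmicsMatrix}.
#' @param variables,samples character ids (or indices) to keep, in order.
#' @return A \linkS4class{PairedOmicsMatrix}.
#' @export
subsetOmics <- function(x, variables = NULL, samples = NULL) {
    v <- x@values
    if (!is.null(variables)) v <- v[variables, , drop = FALSE]
    if (!is.null(samples)) v <- v[, samples, drop = FALSE]
    ann <- x@annotation
    if (nrow(ann) > 0L)
        ann <- ann[match(rownames(v), ann$variable_id), , drop = FALSE]
    PairedOmicsMatrix(v, annotation = ann)
}

#' Accessors for fitted canonical models
#'
#' @param object a \linkS4class{CanonicalModel}.
#' @return \code{canonicalWeights} returns the variables x d weight matrix of
#'   the requested side; \code{trainCorrelations} the per-component training
#'   canonical correlations.
#' @param side \code{"x"} or \code{"y"}.
#' @export
canonicalWeights <- function(object, side = c("x", "y")) {
    side <- match.arg(side)
    if (side == "x") object@Wx else object@Wy
}

#' @rdname canonicalWeights
#' @export
trainCorrelations <- function(object) object@correlationsTrain

#' @rdname canonicalWeights
#' @export
modelRegularization <- function(object) object@regularization

#' Best regularization pair of a cross-validation grid search
#' @param object a \linkS4class{CVResult}.
#' @export
bestRegularization <- function(object) object@best

#' @rdname bestRegularization
#' @export
cvGrid <- function(object) object@grid

setMethod("show", "PairedOmicsMatrix", function(object) {
    cat("PairedOmicsMatrix:", nrow(object@values), "variables x",
        ncol(object@values), "samples\n")
    if (nrow(object@annotation) > 0L)
        cat("  genome annotation attached (",
            length(unique(object@annotation$chromosome)), " chromosomes )\n",
            sep = "")
})

setMethod("show", "CanonicalModel", function(object) {
    d <- length(object@correlationsTrain)
    cat("CanonicalModel (", object@method, "), ", d, " component",
        if (d != 1) "s", "\n", sep = "")
    if (!is.null(object@regularization))
        cat(sprintf("  regularization: tau_x = %g, tau_y = %g\n",
                    object@regularization@tauX, object@regularization@tauY))
    cat("  training canonical correlations:",
        paste(sprintf("%.4f", object@correlationsTrain), collapse = ", "), "\n")
    cat("  ", nrow(object@Wx), " x-variables, ", nrow(object@Wy),
        " y-variables\n", sep = "")
})

setMethod("show", "CVResult", function(object) {
    cat("CVResult:", nrow(object@grid), "grid points,", object@k, "folds\n")
    cat(sprintf("  best: tau_x = %g, tau_y = %g, rho_cv_1 = %.4f\n",
                object@best@tauX, object@best@tauY, max(object@grid$rho_cv_1)))
    if (!is.na(object@rhoCv2))
        cat(sprintf("  rho_cv_2 at best: %.4f\n", object@rhoCv2))
})

setMethod("show", "PermutationNull", function(object) {
    cat(sprintf("PermutationNull: B = %d, mean = %.4f, sd = %.4f\n",
                object@B, object@mean, object@sd))
})

setMethod("show", "SplitPlan", function(object) {
    cat(sprintf("SplitPlan: %d tuning / %d validation samples, %d folds (seed %d)\n",
                length(object@tuningIds), length(object@validationIds),
                length(object@folds), object@seed))
})
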