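#' Fit a per-variable standardization model on training samples
#'
#' Each variable (row) is mean-centered and scaled to unit variance across the
#' training samples. The default convention is the population SD (divide by
#' N), so a standardized row has sum of squares exactly N and the scaled
#' covariance matrix XX' has diagonal N; this is the scaling under which the
#' ridge term tau * N * I is commensurate with the covariance term. Variables
#' with zero training variance are dropped and recorded.
#'
#' @param train a \linkS4class{PairedOmicsMatrix} with at least 3 samples.
#' @param convention \code{"population"} (default, divide by N) or
#'   \code{"sample"} (divide by N - 1).
#' @return A \linkS4class{StandardizationModel}.
#' @seealso [applyStandardization()]
#' @export
fitStandardization <- function(train, convention = c("population", "sample")) {
    convention <- match.arg(convention)
    v <- omicsValues(train)
    if (ncol(v) < 3L)
        stop("standardization requires at least 3 samples, got ", ncol(v))
    if (any(!is.finite(v)))
        stop("non-finite values in input matrix")
    N <- ncol(v)
    mu <- rowMeans(v)
    ss <- rowSums((v - mu)^2)
    denom <- if (convention == "population") N else N - 1L
    sds <- sqrt(ss / denom)
    zero <- sds == 0
    if (all(zero))
        stop("all variables have zero variance; empty standardization model")
    new("StandardizationModel",
        means = mu[!zero], sds = sds[!zero],
        dropped = rownames(v)[zero], convention = convention)
}

#' Standardize a matrix with training statistics
#'
#' Transforms each retained variable by (value - train_mean) / train_sd, so
#' held-out samples are standardized with the statistics of the training set
#' (never their own). Variables dropped at fit time are removed; variables
#' present in the data but unknown to the model are ignored with a warning.
#'
#' @param model a \linkS4class{StandardizationModel}.
#' @param data a \linkS4class{PairedOmicsMatrix} containing all retained
#'   variables of the model.
#' @return A standardized \linkS4class{PairedOmicsMatrix} (same sample
#'   order, model's variable order).
#' @export
applyStandardization <- function(model, data) {
    v <- omicsValues(data)
    keep <- names(model@means)
    missing <- setdiff(keep, rownames(v))
    if (length(missing))
        stop("variables required by the standardization model are missing: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) ", ...")
    extra <- setdiff(rownames(v), c(keep, model@dropped))
    if (length(extra))
        warning(length(extra), " variables unknown to the model were ignored")
    v <- v[keep, , drop = FALSE]
    out <- (v - model@means) / model@sds
    ann <- variableAnnotation(data)
    if (nrow(ann) > 0L)
        ann <- ann[match(keep, ann$variable_id), , drop = FALSE]
    PairedOmicsMatrix(out, annotation = ann)
}

#' Fit and apply standardization in one step
#' @inheritParams fitStandardization
#' @return list with elements \code{data} (standardized
#'   \linkS4class{PairedOmicsMatrix}) and \code{model}.
#' @export
standardizeOmics <- function(train, convention = c("population", "sample")) {
    model <- fitStandardization(train, convention)
    list(data = applyStandardization(model, train), model = model)
}
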