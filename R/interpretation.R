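#' Cross-loadings: correlation of each variable with extracted features
#'
#' Entry (i, j) is the Pearson correlation, over the evaluation samples, of
#' variable i with the j-th feature scores -- typically the features
#' extracted from the *other* variable set (cross-loadings), the relevance
#' measure of choice: unlike raw weights, cross-loadings are stable under
#' collinearity, and highly correlated variables obtain similar values even
#' when their weights differ.
#'
#' @param variables a standardized \linkS4class{PairedOmicsMatrix} over the
#'   evaluation samples.
#' @param scores samples x d feature score matrix (same samples).
#' @param featureSource which side the scores were extracted from
#'   (\code{"x"} or \code{"y"}).
#' @param basis \code{"cross"} when the scores come from the other variable
#'   set, \code{"own"} for own-set loadings.
#' @return A \linkS4class{CrossLoadingMatrix}.
#' @export
crossLoadings <- function(variables, scores, featureSource = "y",
                          basis = "cross") {
    v <- omicsValues(variables)
    scores <- as.matrix(scores)
    if (ncol(v) != nrow(scores))
        stop("variables and scores must cover the same samples")
    sdv <- apply(v, 1L, stats::sd)
    sds <- apply(scores, 2L, stats::sd)
    if (any(sds == 0))
        stop("zero-variance feature scores")
    out <- matrix(0, nrow(v), ncol(scores),
                  dimnames = list(rownames(v),
                                  paste0("f", seq_len(ncol(scores)))))
    if (any(sdv == 0))
        warning(sum(sdv == 0), " zero-variance variable(s); loading set to 0")
    ok <- sdv > 0
    if (any(ok))
        out[ok, ] <- stats::cor(t(v[ok, , drop = FALSE]), scores)
    out[out > 1] <- 1; out[out < -1] <- -1
    new("CrossLoadingMatrix", values = out,
        featureSource = featureSource, basis = basis)
}

#' Redundancy coefficients from a loading matrix
#'
#' Per feature j, the redundancy coefficient is the mean squared loading over
#' the variables, R_j = (1/m) sum_i c_ij^2 (Stewart-Love): the fraction of
#' the variable set's variance shared with feature j. Supplying
#' cross-loadings yields R_{set|other-side features}; supplying own-set
#' loadings yields R_{set|own features}.
#'
#' @param cross a \linkS4class{CrossLoadingMatrix}.
#' @return numeric vector, one coefficient in [0, 1] per feature.
#' @export
redundancy <- function(cross) {
    v <- cross@values
    if (nrow(v) == 0L) stop("empty variable set")
    colMeans(v^2)
}

#' Redundancy table for a fitted model
#'
#' Computes the four redundancy summaries per feature: R_{x|y} (variance of
#' the x-variables shared with the y-side features), R_{y|x}, and the own-set
#' quantities R_{x|x}, R_{y|y}.
#'
#' @param model a \linkS4class{CanonicalModel}.
#' @param X,Y \linkS4class{PairedOmicsMatrix} objects (the evaluation set,
#'   typically the tuning samples).
#' @return data.frame with columns feature, R_x_given_y, R_y_given_x,
#'   R_x_given_x, R_y_given_y.
#' @export
redundancyTable <- function(model, X, Y) {
    Xs <- applyStandardization(model@stdX, X)
    Ys <- applyStandardization(model@stdY, Y)
    sx <- projectSamples(model, X, "x")
    sy <- projectSamples(model, Y, "y")
    d <- ncol(sx)
    data.frame(
        feature = seq_len(d),
        R_x_given_y = redundancy(crossLoadings(Xs, sy, "y", "cross")),
        R_y_given_x = redundancy(crossLoadings(Ys, sx, "x", "cross")),
        R_x_given_x = redundancy(crossLoadings(Xs, sx, "x", "own")),
        R_y_given_y = redundancy(crossLoadings(Ys, sy, "y", "own")),
        row.names = NULL)
}

#' Top-k variables by absolute loading on one feature
#'
#' @param cross a \linkS4class{CrossLoadingMatrix}.
#' @param j feature index.
#' @param k list length (default 150).
#' @return data.frame (variable_id, loading) sorted by decreasing |loading|;
#'   ties broken by variable id in lexicographic order for reproducibility.
#' @export
topVariables <- function(cross, j = 1L, k = 150L) {
    v <- cross@values
    if (j < 1L || j > ncol(v)) stop("feature index out of range")
    if (k > nrow(v)) stop("k exceeds the variable count")
    ids <- rownames(v)
    o <- order(-abs(v[, j]), ids)
    data.frame(variable_id = ids[o[seq_len(k)]],
               loading = unname(v[o[seq_len(k)], j]))
}

## Karyotype order of chromosome labels: 1..22, then X, then Y. Accepts an
## optional "chr" prefix. Unrecognized labels are an error.
.chromOrder <- function(chrom) {
    lab <- sub("^chr", "", as.character(chrom))
    lev <- c(as.character(1:22), "X", "Y")
    match(lab, lev)
}

#' Genome-ordered loading table
#'
#' Orders variables along the genome (chromosomes in karyotype order 1..22,
#' X, Y; then position ascending) and reports chromosome boundary row
#' indices, the data behind genome-track relevance plots. Variables without
#' annotation are appended at the end and flagged unplaced.
#'
#' @param cross a \linkS4class{CrossLoadingMatrix}.
#' @param annotation data.frame with columns variable_id, chromosome,
#'   position.
#' @return list with \code{table} (variable_id, chromosome, position,
#'   placed, one loading column per feature) and \code{boundaries} (named
#'   integer vector: last row index of each chromosome).
#' @export
genomeOrderedLoadings <- function(cross, annotation) {
    v <- cross@values
    ids <- rownames(v)
    ann <- annotation[match(ids, annotation$variable_id), , drop = FALSE]
    placed <- !is.na(ann$variable_id)
    bad <- placed & is.na(.chromOrder(ann$chromosome))
    if (any(bad))
        stop("malformed chromosome labels: ",
             paste(unique(ann$chromosome[bad]), collapse = ", "))
    ord_key <- .chromOrder(ann$chromosome)
    o <- c(which(placed)[order(ord_key[placed], ann$position[placed])],
           which(!placed))
    tab <- data.frame(variable_id = ids[o],
                      chromosome = ann$chromosome[o],
                      position = ann$position[o],
                      placed = placed[o])
    for (j in seq_len(ncol(v)))
        tab[[paste0("loading_f", j)]] <- unname(v[o, j])
    chrom_placed <- tab$chromosome[tab$placed]
    boundaries <- if (length(chrom_placed))
        vapply(unique(chrom_placed),
               function(cc) max(which(tab$chromosome == cc & tab$placed)),
               integer(1))
    else integer(0)
    list(table = tab, boundaries = boundaries)
}

#' Superimposed standardized sample coordinates
#'
#' Projects the samples onto the first two feature pairs of both sides and
#' standardizes each of the four coordinate columns to unit variance, so each
#' sample is represented by an x-side point and a y-side point in the same
#' plane; the closer the canonical correlation is to one, the closer the two
#' points per sample.
#'
#' @param model a \linkS4class{CanonicalModel} with at least 2 components.
#' @param X,Y \linkS4class{PairedOmicsMatrix} objects (the samples to show).
#' @param labels optional per-sample labels (named character).
#' @return data.frame with columns sample_id, side, f1, f2, label.
#' @export
sampleCoordinates <- function(model, X, Y, labels = NULL) {
    if (length(model@correlationsTrain) < 2L)
        stop("model must have at least 2 components")
    sx <- projectSamples(model, X, "x")[, 1:2, drop = FALSE]
    sy <- projectSamples(model, Y, "y")[, 1:2, drop = FALSE]
    std <- function(m) apply(m, 2L, function(col) {
        s <- stats::sd(col)
        if (s == 0) stop("zero-variance feature column over the sample set")
        (col - mean(col)) / s
    })
    sx <- std(sx); sy <- std(sy)
    ids <- rownames(sx)
    lab <- if (is.null(labels)) NA_character_ else as.character(labels[ids])
    out <- rbind(
        data.frame(sample_id = ids, side = "x",
                   f1 = sx[, 1L], f2 = sx[, 2L], label = lab),
        data.frame(sample_id = ids, side = "y",
                   f1 = sy[, 1L], f2 = sy[, 2L], label = lab))
    rownames(out) <- NULL
    out
}
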