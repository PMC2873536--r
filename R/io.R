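## Separator sniffing: tab wins over comma when both appear (TSV is the
## native output format; CSV accepted on input). Connections auto-inflate
## gzip.
.sniffSep <- function(path) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    first <- readLines(con, n = 1L)
    repeat {
        if (!length(first)) stop("empty file: ", path)
        if (!startsWith(first, "#")) break
        first <- readLines(con, n = 1L)
    }
    if (lengths(regmatches(first, gregexpr("\t", first))) > 0L) "\t" else ","
}

#' Read a delimited variables x samples matrix
#'
#' Expects a header row of sample ids and a first column of variable ids;
#' tab- or comma-delimited, gzip transparently supported, leading lines
#' starting with '#' ignored. The method assumes complete matrices: missing
#' or non-numeric cells are an error naming the offending row and column, as
#' are duplicated ids.
#'
#' @param path file path (.tsv, .csv, optionally .gz).
#' @param annotation optional annotation data.frame or path to a
#'   three-column (variable_id, chromosome, position) table.
#' @return A \linkS4class{PairedOmicsMatrix}.
#' @export
readMatrix <- function(path, annotation = NULL) {
    sep <- .sniffSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicated variable id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    samples <- colnames(df)[-1L]
    if (anyDuplicated(samples))
        stop("duplicated sample id(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    body <- df[, -1L, drop = FALSE]
    for (jc in seq_along(body)) {
        col <- body[[jc]]
        if (!is.numeric(col)) {
            suppressWarnings(num <- as.numeric(col))
            bad <- which(is.na(num) & !is.na(col))
            if (length(bad))
                stop("non-numeric value at row '", ids[bad[1L]],
                     "', column '", samples[jc], "'")
            body[[jc]] <- num
        }
    }
    m <- as.matrix(body)
    if (anyNA(m)) {
        w <- which(is.na(m), arr.ind = TRUE)[1L, ]
        stop("missing value at row '", ids[w[1L]], "', column '",
             samples[w[2L]], "' (the method assumes complete matrices)")
    }
    dimnames(m) <- list(ids, samples)
    if (is.character(annotation))
        annotation <- readAnnotation(annotation)
    PairedOmicsMatrix(m, annotation = annotation)
}

#' Write a PairedOmicsMatrix as a normalized TSV
#'
#' Tab-delimited, a '#' schema comment line first, variable ids in the first
#' column, floating point at 17 significant digits so values round-trip
#' exactly through [readMatrix()].
#'
#' @param x a \linkS4class{PairedOmicsMatrix}.
#' @param path output path (gzip when it ends in .gz).
#' @return the path, invisibly.
#' @export
writeMatrix <- function(x, path) {
    v <- omicsValues(x)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(paste0("# variables x samples matrix: variable_id\t",
                      "one column per sample"), con)
    writeLines(paste(c("variable_id", colnames(v)), collapse = "\t"), con)
    for (i in seq_len(nrow(v)))
        writeLines(paste(c(rownames(v)[i],
                           formatC(v[i, ], digits = 17, format = "g")),
                         collapse = "\t"), con)
    invisible(path)
}

#' Read a variable annotation table
#'
#' Three delimited columns: variable_id, chromosome, position (1-based).
#' @param path file path.
#' @return data.frame.
#' @export
readAnnotation <- function(path) {
    sep <- .sniffSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            comment.char = "#", stringsAsFactors = FALSE)
    need <- c("variable_id", "chromosome", "position")
    if (!all(need %in% colnames(df)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    df$variable_id <- as.character(df$variable_id)
    df$chromosome <- as.character(df$chromosome)
    df$position <- as.integer(df$position)
    if (any(df$position < 1L, na.rm = TRUE))
        stop("positions must be 1-based positive integers")
    df[need]
}

#' Read a sample label table
#'
#' Two delimited columns: sample_id, label.
#' @param path file path.
#' @return named character vector (names are sample ids).
#' @export
readLabels <- function(path) {
    sep <- .sniffSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("label table must have two columns: sample_id, label")
    stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Align the sample order of a paired matrix pair
#'
#' The canonical correlation machinery requires both matrices to cover the
#' same samples in the same column order; this reorders Y's columns to X's
#' order.
#'
#' @param X,Y \linkS4class{PairedOmicsMatrix} objects whose sample id sets
#'   are identical as sets.
#' @return list with \code{X} (unchanged) and \code{Y} (reordered).
#' @export
alignPair <- function(X, Y) {
    sx <- sampleIds(X); sy <- sampleIds(Y)
    if (!setequal(sx, sy)) {
        only_x <- setdiff(sx, sy); only_y <- setdiff(sy, sx)
        stop("sample id mismatch; only in X: ",
             paste(only_x, collapse = ", "), "; only in Y: ",
             paste(only_y, collapse = ", "))
    }
    if (identical(sx, sy)) return(list(X = X, Y = Y))
    list(X = X, Y = subsetOmics(Y, samples = sx))
}

## ---- model serialization ---------------------------------------------------

.stdToList <- function(m) {
    list(variable_ids = names(m@means), means = unname(m@means),
         sds = unname(m@sds), dropped = m@dropped,
         convention = m@convention)
}

.stdFromList <- function(l) {
    new("StandardizationModel",
        means = stats::setNames(as.numeric(l$means),
                                as.character(l$variable_ids)),
        sds = stats::setNames(as.numeric(l$sds),
                              as.character(l$variable_ids)),
        dropped = as.character(l$dropped), convention = l$convention)
}

#' Serialize a CanonicalModel to a JSON file
#'
#' The schema stores weights, standardization statistics, method,
#' regularization and a sign-convention version, at full double precision,
#' so projections are reproducible across releases.
#'
#' @param model a \linkS4class{CanonicalModel}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeModel <- function(model, path) {
    obj <- list(
        format = "dualCCA-model",
        sign_convention = "largest-abs-entry-of-Wx-positive/v1",
        method = model@method,
        regularization = if (is.null(model@regularization)) NULL else
            list(tau_x = model@regularization@tauX,
                 tau_y = model@regularization@tauY),
        correlations_train = model@correlationsTrain,
        penalized_correlations = model@penalizedCorrelations,
        x = list(variable_ids = rownames(model@Wx),
                 weights = asplit(unname(model@Wx), 2L),
                 standardization = .stdToList(model@stdX)),
        y = list(variable_ids = rownames(model@Wy),
                 weights = asplit(unname(model@Wy), 2L),
                 standardization = .stdToList(model@stdY)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' Read a serialized CanonicalModel
#' @param path path written by [writeModel()].
#' @return A \linkS4class{CanonicalModel}.
#' @export
readModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "dualCCA-model"))
        stop("not a dualCCA model file: ", path)
    asW <- function(side) {
        w <- side$weights
        W <- if (is.matrix(w)) t(w)
             else if (is.list(w)) do.call(cbind, lapply(w, as.numeric))
             else matrix(as.numeric(w), ncol = 1L)
        rownames(W) <- as.character(side$variable_ids)
        W
    }
    reg <- if (is.null(obj$regularization)) NULL else
        regPair(obj$regularization$tau_x, obj$regularization$tau_y)
    new("CanonicalModel",
        Wx = asW(obj$x), Wy = asW(obj$y),
        correlationsTrain = as.numeric(obj$correlations_train),
        penalizedCorrelations = as.numeric(obj$penalized_correlations),
        method = obj$method, regularization = reg,
        stdX = .stdFromList(obj$x$standardization),
        stdY = .stdFromList(obj$y$standardization))
}

#' Write a generic result table with a schema comment line
#'
#' All floating point columns are written at 17 significant digits.
#' @param df data.frame.
#' @param path output path.
#' @param schema one-line description of the columns.
#' @return the path, invisibly.
#' @export
writeTable <- function(df, path, schema = paste(colnames(df),
                                                collapse = "\t")) {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(paste0("# ", schema), con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    for (i in seq_len(nrow(df))) {
        cells <- vapply(df[i, , drop = FALSE], function(x) {
            if (is.double(x)) formatC(x, digits = 17, format = "g")
            else as.character(x)
        }, character(1))
        writeLines(paste(cells, collapse = "\t"), con)
    }
    invisible(path)
}

#' Serialize a SplitPlan as a two-column table
#'
#' Columns sample_id and role: \code{validation} or \code{fold<i>} for
#' tuning samples.
#' @param plan a \linkS4class{SplitPlan}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSplitPlan <- function(plan, path) {
    rows <- rbind(
        do.call(rbind, lapply(seq_along(plan@folds), function(i)
            data.frame(sample_id = plan@folds[[i]],
                       role = paste0("fold", i)))),
        data.frame(sample_id = plan@validationIds, role = "validation"))
    attr(rows, "seed") <- plan@seed
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(paste0("# split plan: sample_id\trole (seed=", plan@seed,
                      ")"), con)
    writeLines("sample_id\trole", con)
    writeLines(paste(rows$sample_id, rows$role, sep = "\t"), con)
    invisible(path)
}

#' Read a serialized SplitPlan
#' @param path path written by [writeSplitPlan()].
#' @return A \linkS4class{SplitPlan}.
#' @export
readSplitPlan <- function(path) {
    first <- readLines(path, n = 1L)
    seed <- if (grepl("seed=", first))
        as.integer(sub(".*seed=([0-9]+).*", "\\1", first)) else NA_integer_
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    foldNames <- sort(unique(df$role[df$role != "validation"]))
    folds <- lapply(foldNames, function(fn) df$sample_id[df$role == fn])
    new("SplitPlan",
        tuningIds = df$sample_id[df$role != "validation"],
        validationIds = df$sample_id[df$role == "validation"],
        folds = folds, stratifyLabels = character(0), seed = seed)
}
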