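## Random variables x samples fixture with ids
randomOmics <- function(n, N, prefix = "v", seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    m <- matrix(rnorm(n * N), n, N,
                dimnames = list(paste0(prefix, seq_len(n)),
                                paste0("s", seq_len(N))))
    PairedOmicsMatrix(m)
}

## Standardize both sides of a pair, returning data and models
stdPair <- function(X, Y) {
    sx <- standardizeOmics(X)
    sy <- standardizeOmics(Y)
    list(X = sx$data, Y = sy$data, mx = sx$model, my = sy$model)
}

## |cosine| between two vectors
absCosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

## Tiny paired data set with an exactly shared single variable
identicalPair <- function(N = 12, seed = 1) {
    set.seed(seed)
    v <- rnorm(N)
    m <- matrix(v, 1, N, dimnames = list("v1", paste0("s", seq_len(N))))
    list(X = PairedOmicsMatrix(m, variableIds = "x1"),
         Y = PairedOmicsMatrix(m, variableIds = "y1"))
}
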