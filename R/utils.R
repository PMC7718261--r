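# internal helpers

# run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (had) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

.checkBinary <- function(labels, what = "labels") {
    labels <- as.integer(labels)
    if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
        stop("'", what, "' must be binary 0/1 without missing values")
    if (length(unique(labels)) < 2L)
        stop("'", what, "' must contain both classes")
    labels
}

.checkFiniteScalar <- function(x, name, min = -Inf, max = Inf,
                               strictMin = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop("'", name, "' must be a single finite number")
    if (x < min || x > max || (strictMin && x <= min))
        stop("'", name, "' out of range")
    invisible(x)
}

# stratified fold assignment (both classes spread over every fold)
.stratifiedFolds <- function(y, folds, seed) {
    .withSeed(seed, {
        assign <- integer(length(y))
        for (cls in unique(y)) {
            idx <- which(y == cls)
            idx <- idx[sample.int(length(idx))]
            assign[idx] <- rep_len(seq_len(folds), length(idx))
        }
        assign
    })
}

.logloss <- function(y, f) {
    p <- stats::plogis(f)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
}
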