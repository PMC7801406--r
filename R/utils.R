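## Run `expr` under a local RNG stream: the global .Random.seed is
## restored afterwards, so seeded package functions never perturb the
## caller's random sequence. seed = NULL uses (and advances) the global
## stream as usual.
withLocalSeed <- function(seed, expr) {
    if (is.null(seed) || (length(seed) == 1L && is.na(seed)))
        return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    expr
}

.asSeed <- function(seed) {
    if (is.null(seed)) NA_integer_ else as.integer(seed)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## All permutations of seq_len(n), one per row; n <= 8 (8! = 40320).
allPermutations <- function(n) {
    stopifnot(n >= 1L, n <= 8L)
    rec <- function(v) {
        if (length(v) == 1L) return(matrix(v, 1L, 1L))
        out <- vector("list", length(v))
        for (i in seq_along(v))
            out[[i]] <- cbind(v[i], rec(v[-i]), deparse.level = 0L)
        do.call(rbind, out)
    }
    rec(seq_len(n))
}

## Hamilton (largest-remainder) apportionment of `total` seats across
## strata with the given sizes. Floors of the exact quotas first; leftover
## seats go one each to the largest fractional remainders (ties broken by
## stratum order). Deterministic; preserves sum(alloc) == total and
## alloc <= sizes when total <= sum(sizes).
largestRemainderAllocation <- function(sizes, total) {
    stopifnot(total >= 0, total <= sum(sizes))
    quota <- total * sizes / sum(sizes)
    alloc <- floor(quota)
    remainder <- quota - alloc
    left <- total - sum(alloc)
    while (left > 0L) {
        ## never allocate past a stratum's size
        eligible <- which(alloc < sizes)
        ord <- eligible[order(-remainder[eligible], eligible)]
        take <- ord[seq_len(min(left, length(ord)))]
        alloc[take] <- alloc[take] + 1L
        remainder[take] <- -Inf
        left <- total - sum(alloc)
    }
    as.integer(alloc)
}

## quantile type 7 on a numeric vector, guarded for length-1 input
percentileCI <- function(draws, level = 0.90) {
    a <- (1 - level) / 2
    unname(stats::quantile(draws, probs = c(a, 1 - a), names = FALSE, type = 7))
}
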