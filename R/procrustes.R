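## Center columns and scale to unit total sum of squares. Errors on a
## configuration with no variation (all rows identical / all zero).
.prepConfig <- function(m, what = "matrix") {
    m <- as.matrix(m)
    m <- sweep(m, 2L, colMeans(m))
    ss <- sum(m^2)
    if (ss < 1e-12)
        stop(sprintf("degenerate configuration: %s has no variation after centering", what))
    m / sqrt(ss)
}

## Pseudo-R of two prepared (centered, unit-SS) configurations: the sum of
## singular values of t(X) %*% Y. Column padding only appends zero
## singular values, so the statistic is computed on the unpadded widths.
.procrustesStat <- function(X, Y) {
    d <- svd(crossprod(X, Y), nu = 0L, nv = 0L)$d
    min(1, sum(d))
}

#' Symmetric Procrustes superimposition of two row-matched matrices
#'
#' Finds the congruence between two multivariate configurations observed
#' on the same sites. Both matrices are column-centered and scaled to
#' unit total sum of squares (the symmetric form, so the statistic does
#' not depend on argument order), then the second is rotated onto the
#' first by the orthogonal matrix (reflections allowed) that minimizes
#' the residual sum of squares. With singular values \eqn{\sigma_i} of
#' the cross-product of the scaled configurations, the Procrustes
#' correlation is \eqn{r = \sum_i \sigma_i} and the residual statistic
#' \eqn{m^2 = 1 - r^2}. Matrices of unequal width are zero-padded to a
#' common dimension first (this leaves \eqn{r} unchanged).
#'
#' @param x,y numeric matrices with the same rows (sites) in the same
#'   order; typically Hellinger-transformed community matrices or
#'   z-scored hydroperiod indicators.
#' @return a [ProcrustesResult-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(20), 10, 2)
#' procrustesFit(x, x)  # self-congruence: r = 1
#' @export
procrustesFit <- function(x, y) {
    p <- padToCommonDimension(as.matrix(x), as.matrix(y))
    X <- .prepConfig(p$x, "first matrix")
    Y <- .prepConfig(p$y, "second matrix")
    s <- svd(crossprod(X, Y))
    r <- min(1, sum(s$d))
    rotation <- s$v %*% t(s$u)
    new("ProcrustesResult", r = r, m2 = 1 - r^2, rotation = rotation,
        nSites = nrow(X), nDims = ncol(X))
}

#' PROTEST: permutation test of Procrustes congruence
#'
#' Builds the null distribution of the Procrustes pseudo-R by uniformly
#' permuting the rows (sites) of the second matrix while holding the
#' first fixed, and reports
#' \code{p = (1 + #\{r_perm >= r_obs\}) / (B + 1)} — ties count against
#' the observed statistic and the +1 correction keeps p valid (never 0).
#'
#' @param x,y as in [procrustesFit()].
#' @param B number of permutations (default 999).
#' @param seed optional integer seed; the global RNG state is left
#'   untouched when a seed is given.
#' @return a [ProtestResult-class].
#' @examples
#' set.seed(42)
#' x <- matrix(rnorm(20), 10, 2)
#' y <- x + matrix(rnorm(20, sd = 0.1), 10, 2)
#' protest(x, y, B = 199, seed = 1)
#' @export
protest <- function(x, y, B = 999L, seed = NULL) {
    stopifnot(B >= 1L)
    B <- as.integer(B)
    p <- padToCommonDimension(as.matrix(x), as.matrix(y))
    X <- .prepConfig(p$x, "first matrix")
    Y <- .prepConfig(p$y, "second matrix")
    s <- svd(crossprod(X, Y))
    rObs <- min(1, sum(s$d))
    n <- nrow(X)
    rPerm <- withLocalSeed(seed, {
        vapply(seq_len(B), function(i) {
            Yp <- Y[sample.int(n), , drop = FALSE]
            ## row permutation preserves column means and total SS, so the
            ## permuted configuration cannot become degenerate
            .procrustesStat(X, Yp)
        }, numeric(1))
    })
    pVal <- (1 + sum(rPerm >= rObs - 1e-10)) / (B + 1)
    obs <- new("ProcrustesResult", r = rObs, m2 = 1 - rObs^2,
               rotation = s$v %*% t(s$u), nSites = n, nDims = ncol(X))
    new("ProtestResult", observed = obs, nPermutations = B,
        pValue = pVal, permutedR = rPerm, seed = .asSeed(seed))
}

#' Exact PROTEST p-value by exhaustive enumeration
#'
#' Enumerates all n! row permutations of the second matrix (feasible for
#' n <= 8) and returns the exact permutation p-value
#' \code{#\{r_perm >= r_obs\} / n!}. The identity permutation is part of
#' the enumeration, so p >= 1/n!. Intended as a ground-truth oracle for
#' the Monte-Carlo [protest()] at small n.
#'
#' @param x,y as in [procrustesFit()], with at most 8 rows.
#' @return a list with \code{p} (exact p-value), \code{rObserved} and
#'   \code{rPermuted} (all n! draws, identity included).
#' @export
exhaustiveProtest <- function(x, y) {
    x <- as.matrix(x); y <- as.matrix(y)
    n <- nrow(x)
    if (n > 8L) stop("exhaustive enumeration is limited to n <= 8 sites")
    p <- padToCommonDimension(x, y)
    X <- .prepConfig(p$x, "first matrix")
    Y <- .prepConfig(p$y, "second matrix")
    rObs <- .procrustesStat(X, Y)
    perms <- allPermutations(n)
    rAll <- apply(perms, 1L, function(idx)
        .procrustesStat(X, Y[idx, , drop = FALSE]))
    list(p = sum(rAll >= rObs - 1e-10) / nrow(perms),
         rObserved = rObs, rPermuted = rAll)
}
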