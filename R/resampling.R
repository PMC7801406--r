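#' Rarefaction sensitivity sweep of the congruence estimate
#'
#' Procrustes congruence is upward biased at small sample sizes, so the
#' estimate is recomputed on random site subsamples of increasing size n
#' to locate the plateau beyond which it stabilizes. For each n, B
#' subsamples are drawn without replacement and the same site subset is
#' applied to both matrices; the per-n mean pseudo-R and its standard
#' error (SD/sqrt(B)) are recorded.
#'
#' @param x,y row-matched numeric matrices (already transformed, e.g.
#'   Hellinger community matrices or z-scored hydroperiod indicators).
#' @param nMin,nMax subsample size range (defaults 3 and 40); nMin must
#'   be at least 3 and nMax cannot exceed the available sites.
#' @param B subsamples per n (default 100).
#' @param seed optional integer seed.
#' @param label optional matrix-pair label stored on the result.
#' @return data.frame with columns \code{n}, \code{mean_r}, \code{se_r},
#'   \code{n_ok} (non-degenerate draws), carrying attributes \code{B},
#'   \code{seed} and \code{pair}.
#' @seealso [detectPlateau()]
#' @export
rarefactionCurve <- function(x, y, nMin = 3L, nMax = 40L, B = 100L,
                             seed = NULL, label = NULL) {
    x <- as.matrix(x); y <- as.matrix(y)
    if (nrow(x) != nrow(y)) stop("matrices must have the same sites")
    if (nMin < 3L) stop("nMin must be at least 3 (Procrustes needs >= 3 rows)")
    if (nMax > nrow(x))
        stop(sprintf("nMax (%d) exceeds the %d available sites", nMax, nrow(x)))
    if (nMax < nMin) stop("nMax must be >= nMin")
    ns <- seq.int(nMin, nMax)
    total <- nrow(x)
    res <- withLocalSeed(seed, {
        lapply(ns, function(n) {
            draws <- vapply(seq_len(B), function(b) {
                idx <- sample.int(total, n)
                tryCatch(
                    .procrustesStat(.prepConfig(x[idx, , drop = FALSE]),
                                    .prepConfig(y[idx, , drop = FALSE])),
                    error = function(e) NA_real_)
            }, numeric(1))
            ok <- sum(!is.na(draws))
            c(mean_r = mean(draws, na.rm = TRUE),
              se_r = stats::sd(draws, na.rm = TRUE) / sqrt(ok),
              n_ok = ok)
        })
    })
    out <- data.frame(n = ns, do.call(rbind, res))
    attr(out, "B") <- as.integer(B)
    attr(out, "seed") <- .asSeed(seed)
    attr(out, "pair") <- label
    out
}

#' Locate the sample-size plateau of a rarefaction curve
#'
#' Returns the smallest subsample size n* from which the curve is flat:
#' each of the next \code{run} successive changes in mean pseudo-R is
#' below \code{tol} in absolute value.
#'
#' @param curve data.frame from [rarefactionCurve()] (columns \code{n}
#'   and \code{mean_r}).
#' @param tol flatness tolerance on successive mean-r changes (default 0.01).
#' @param run number of consecutive sub-tolerance steps required (default 3).
#' @return the plateau n* as an integer, or \code{NA_integer_} when the
#'   curve never flattens.
#' @export
detectPlateau <- function(curve, tol = 0.01, run = 3L) {
    if (nrow(curve) < run + 1L)
        stop(sprintf("curve needs at least run + 1 = %d points", run + 1L))
    steps <- abs(diff(curve$mean_r))
    flat <- steps < tol
    for (k in seq_len(length(steps) - run + 1L)) {
        if (all(flat[k:(k + run - 1L)]))
            return(as.integer(curve$n[k]))
    }
    NA_integer_
}

## One stratified subset of nTarget sites from groupSites, proportional
## allocation across permanence classes with largest-remainder rounding.
## Draws from the current RNG stream; callers seed around it.
.stratifiedSubset <- function(metadata, groupSites, nTarget) {
    cls <- metadata$permanence_class[match(groupSites, metadata$site_id)]
    strata <- split(groupSites, factor(cls, intersect(PERMANENCE_CLASSES, cls)))
    alloc <- largestRemainderAllocation(lengths(strata), nTarget)
    sort(unlist(mapply(function(ids, k) ids[sample.int(length(ids), k)],
                       strata, alloc, SIMPLIFY = FALSE), use.names = FALSE))
}

## Shared engine: draws `iterations` stratified subsets for a group and
## evaluates every matrix pair on the *same* subset per iteration.
## pairs: named list of list(x=, y=) matrices (rownames = site IDs).
.balancedDraws <- function(pairs, metadata, group, nTarget, iterations,
                           BPerm) {
    groupSites <- suppressMessages(assignGroup(metadata, group))
    if (length(groupSites) < nTarget)
        stop(sprintf("group '%s' has %d sites, fewer than the target %d",
                     group, length(groupSites), nTarget))
    fixed <- length(groupSites) == nTarget
    iters <- if (fixed) 1L else as.integer(iterations)
    rDraws <- matrix(NA_real_, iters, length(pairs),
                     dimnames = list(NULL, names(pairs)))
    pDraws <- rDraws
    for (i in seq_len(iters)) {
        subset <- if (fixed) groupSites
                  else .stratifiedSubset(metadata, groupSites, nTarget)
        for (j in seq_along(pairs)) {
            xs <- pairs[[j]]$x[subset, , drop = FALSE]
            ys <- pairs[[j]]$y[subset, , drop = FALSE]
            ok <- tryCatch({
                if (BPerm > 0L) {
                    pr <- protest(xs, ys, B = BPerm)
                    rDraws[i, j] <- pseudoR(pr)
                    pDraws[i, j] <- pValue(pr)
                } else {
                    rDraws[i, j] <- .procrustesStat(.prepConfig(xs), .prepConfig(ys))
                }
                TRUE
            }, error = function(e) FALSE)
            if (!ok)
                warning(sprintf("degenerate subsample in group '%s', pair '%s' (iteration %d); recorded as NA",
                                group, names(pairs)[j], i))
        }
    }
    list(r = rDraws, p = pDraws, iterations = iters, fixed = fixed,
         groupSize = length(groupSites))
}

#' Stratified balanced bootstrap of Procrustes congruence
#'
#' Equalizes group sizes before comparing congruence across hydroperiod
#' groups: each iteration draws \code{nTarget} sites without replacement,
#' stratified by permanence class with proportional allocation
#' (largest-remainder rounding), applies the identical subset to both
#' matrices, and records the Procrustes pseudo-R (plus a PROTEST p-value
#' when \code{BPerm > 0}). A group holding exactly \code{nTarget} sites
#' is computed once, deterministically, rather than resampled. The
#' summary reports the mean pseudo-R, the percentile confidence interval
#' of the draws, and the median per-iteration PROTEST p-value with a
#' significance flag at \code{alpha}.
#'
#' @param x,y row-matched numeric matrices with site IDs as rownames.
#' @param metadata validated site metadata (columns \code{site_id},
#'   \code{permanence_class}).
#' @param group \code{"all"}, \code{"short"} or \code{"long"}.
#' @param nTarget sites per draw; defaults to the size of the smallest
#'   hydroperiod group present in \code{metadata} (31 in the motivating
#'   design).
#' @param iterations bootstrap iterations (default 1000).
#' @param BPerm permutations per within-iteration PROTEST (default 199;
#'   0 skips significance testing).
#' @param ciLevel confidence level of the percentile interval (default 0.90).
#' @param alpha significance threshold on the median p (default 0.1).
#' @param seed optional integer seed.
#' @return list of class \code{"BootstrapSummary"}: group, target n,
#'   iterations, pseudo-R draws, mean, percentile CI, median p,
#'   significance flag, seed.
#' @export
balancedBootstrap <- function(x, y, metadata, group = c("all", "short", "long"),
                              nTarget = NULL, iterations = 1000L,
                              BPerm = 199L, ciLevel = 0.90, alpha = 0.1,
                              seed = NULL) {
    group <- match.arg(group)
    x <- as.matrix(x); y <- as.matrix(y)
    if (is.null(nTarget))
        nTarget <- min(length(suppressMessages(assignGroup(metadata, "short"))),
                       length(suppressMessages(assignGroup(metadata, "long"))))
    draws <- withLocalSeed(seed,
        .balancedDraws(list(pair = list(x = x, y = y)), metadata, group,
                       nTarget, iterations, BPerm))
    r <- draws$r[, 1L]
    p <- draws$p[, 1L]
    if (all(is.na(r)))
        stop("degenerate configuration in every subsample")
    medianP <- if (BPerm > 0L) stats::median(p, na.rm = TRUE) else NA_real_
    structure(list(
        group = group, nTarget = as.integer(nTarget),
        iterations = draws$iterations, groupSize = draws$groupSize,
        draws = r, meanR = mean(r, na.rm = TRUE),
        ci = percentileCI(r[!is.na(r)], ciLevel), ciLevel = ciLevel,
        medianP = medianP,
        significant = if (BPerm > 0L) medianP < alpha else NA,
        alpha = alpha, BPerm = as.integer(BPerm), seed = .asSeed(seed)),
        class = "BootstrapSummary")
}

#' @export
print.BootstrapSummary <- function(x, ...) {
    cat(sprintf("Balanced bootstrap, group '%s' (%d sites -> %d per draw)\n",
                x$group, x$groupSize, x$nTarget))
    cat(sprintf("  %d iteration(s): mean pseudo-R = %.4f, %d%% CI [%.4f, %.4f]\n",
                x$iterations, x$meanR, round(100 * x$ciLevel),
                x$ci[1], x$ci[2]))
    if (!is.na(x$medianP))
        cat(sprintf("  median PROTEST p = %.4g (B = %d) %s\n", x$medianP,
                    x$BPerm,
                    if (isTRUE(x$significant)) sprintf("< %g *", x$alpha) else ""))
    invisible(x)
}
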