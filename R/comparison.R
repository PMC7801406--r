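#' Full congruence table across matrix pairs and hydroperiod groups
#'
#' Runs the stratified balanced bootstrap for every matrix pair — each
#' pair of horizontal communities plus each community against the
#' hydroperiod indicators — within each requested hydroperiod group.
#' Within a group, every bootstrap iteration draws one stratified site
#' subset and evaluates all pairs on that same subset, mirroring a
#' design in which the community and hydroperiod matrices are subsampled
#' together.
#'
#' @param communities named list of transformed (Hellinger) community
#'   matrices with site IDs as rownames; three communities give the six
#'   canonical pairs.
#' @param hydro transformed (z-scored) hydroperiod indicator matrix with
#'   matching rownames.
#' @param metadata validated site metadata.
#' @param groups hydroperiod groups to evaluate (default all/short/long).
#' @param nTarget sites per draw; defaults to the smallest group size.
#' @param iterations bootstrap iterations per group (default 1000).
#' @param BPerm permutations per within-iteration PROTEST (default 199;
#'   0 skips p-values).
#' @param ciLevel percentile CI level (default 0.90).
#' @param alpha significance threshold on the median p (default 0.1).
#' @param seed optional integer seed.
#' @return data.frame of class \code{"CongruenceTable"}, one row per
#'   group x pair: \code{group}, \code{pair}, \code{community1},
#'   \code{community2} (\code{"hydroperiod"} for environment pairs),
#'   \code{type} (\code{"cross"}/\code{"env"}), \code{mean_r},
#'   \code{ci_lo}, \code{ci_hi}, \code{median_p}, \code{significant},
#'   \code{iterations}.
#' @export
congruenceTable <- function(communities, hydro, metadata,
                            groups = c("all", "short", "long"),
                            nTarget = NULL, iterations = 1000L,
                            BPerm = 199L, ciLevel = 0.90, alpha = 0.1,
                            seed = NULL) {
    stopifnot(length(communities) >= 2L, !is.null(names(communities)))
    labs <- names(communities)
    pairs <- list()
    for (i in seq_along(labs)) {
        for (j in seq_along(labs)) {
            if (i < j)
                pairs[[paste(labs[i], labs[j], sep = "-")]] <-
                    list(x = as.matrix(communities[[i]]),
                         y = as.matrix(communities[[j]]),
                         c1 = labs[i], c2 = labs[j], type = "cross")
        }
    }
    for (lab in labs)
        pairs[[paste(lab, "hydroperiod", sep = "-")]] <-
            list(x = as.matrix(communities[[lab]]), y = as.matrix(hydro),
                 c1 = lab, c2 = "hydroperiod", type = "env")
    if (is.null(nTarget))
        nTarget <- min(vapply(c("short", "long"), function(g)
            length(suppressMessages(assignGroup(metadata, g))), integer(1)))
    rows <- withLocalSeed(seed, {
        lapply(groups, function(g) {
            d <- .balancedDraws(lapply(pairs, function(p) p[c("x", "y")]),
                                metadata, g, nTarget, iterations, BPerm)
            do.call(rbind, lapply(names(pairs), function(nm) {
                r <- d$r[, nm]
                ok <- r[!is.na(r)]
                if (length(ok) == 0L)
                    stop(sprintf("pair '%s', group '%s': degenerate configuration in every subsample",
                                 nm, g))
                medP <- if (BPerm > 0L) stats::median(d$p[, nm], na.rm = TRUE)
                        else NA_real_
                ci <- percentileCI(ok, ciLevel)
                data.frame(group = g, pair = nm,
                           community1 = pairs[[nm]]$c1,
                           community2 = pairs[[nm]]$c2,
                           type = pairs[[nm]]$type,
                           mean_r = mean(ok), ci_lo = ci[1], ci_hi = ci[2],
                           median_p = medP,
                           significant = if (BPerm > 0L) medP < alpha else NA,
                           iterations = d$iterations)
            }))
        })
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "nTarget") <- as.integer(nTarget)
    attr(out, "ciLevel") <- ciLevel
    attr(out, "alpha") <- alpha
    attr(out, "seed") <- .asSeed(seed)
    class(out) <- c("CongruenceTable", "data.frame")
    out
}

#' Percent elevation of cross-community congruence over the environment
#'
#' Expresses how much stronger a community's cross-community congruence
#' is than its congruence with the hydroperiod indicators:
#' \code{100 * (mean(rCross) - rEnv) / rEnv}.
#'
#' @param rCross numeric vector of the community's cross-community
#'   pseudo-R values (with three communities, the two pairs involving it).
#' @param rEnv the community's pseudo-R with the hydroperiod matrix
#'   (must be > 0).
#' @return percent elevation (may be negative).
#' @examples
#' percentElevation(c(0.9, 0.9), 0.45)  # 100: cross is double env
#' @export
percentElevation <- function(rCross, rEnv) {
    if (length(rEnv) != 1L || is.na(rEnv) || rEnv <= 0)
        stop("rEnv must be a single positive value; a non-positive environmental congruence suggests a degenerate hydroperiod matrix")
    100 * (mean(rCross) - rEnv) / rEnv
}

#' Summarize per-community congruence elevations
#'
#' @param percents numeric vector of per-community percent elevations
#'   (one per community, length >= 2).
#' @return list with \code{percents}, \code{mean} (arithmetic mean) and
#'   \code{se} (sample SD / sqrt(n)).
#' @examples
#' elevationSummary(c(84, 52, 95))  # mean 77
#' @export
elevationSummary <- function(percents) {
    if (length(percents) < 2L)
        stop("at least 2 per-community elevations are required")
    list(percents = percents,
         mean = mean(percents),
         se = stats::sd(percents) / sqrt(length(percents)))
}

#' Classify the congruence pattern of a group
#'
#' Applies the decision rule distinguishing an interactions-dominant
#' pattern (cross-community congruence systematically above what a shared
#' response to hydroperiod would produce) from an environment-consistent
#' one: the mean per-community percent elevation must be positive and
#' every cross-community pair's confidence interval must exclude the mean
#' environmental pseudo-R of both communities involved.
#'
#' @param table a [congruenceTable()] result.
#' @param group which group's rows to classify (default \code{"all"}).
#' @return list with the per-community \code{percents}, their \code{mean}
#'   and \code{se}, and \code{interpretation}, one of
#'   \code{"interactions-dominant"} or \code{"environment-consistent"}.
#' @export
interpretPattern <- function(table, group = "all") {
    tab <- table[table$group == group, , drop = FALSE]
    if (nrow(tab) == 0L) stop(sprintf("group '%s' not present in table", group))
    cross <- tab[tab$type == "cross", , drop = FALSE]
    env <- tab[tab$type == "env", , drop = FALSE]
    envR <- stats::setNames(env$mean_r, env$community1)
    percents <- vapply(names(envR), function(comm) {
        rCross <- cross$mean_r[cross$community1 == comm | cross$community2 == comm]
        percentElevation(rCross, envR[[comm]])
    }, numeric(1))
    summary <- elevationSummary(percents)
    excludes <- vapply(seq_len(nrow(cross)), function(k) {
        e <- envR[c(cross$community1[k], cross$community2[k])]
        all(e < cross$ci_lo[k] | e > cross$ci_hi[k])
    }, logical(1))
    summary$interpretation <-
        if (summary$mean > 0 && all(excludes)) "interactions-dominant"
        else "environment-consistent"
    summary
}

#' Short- vs long-hydroperiod stationarity contrast
#'
#' Compares congruence between the two hydroperiod groups pair by pair:
#' the difference in mean pseudo-R (long minus short) and whether the two
#' confidence intervals overlap. Overlapping intervals are read as a
#' stationary relationship (no detectable change in congruence strength
#' along the gradient).
#'
#' @param table a [congruenceTable()] result containing both the
#'   \code{"short"} and \code{"long"} groups.
#' @return data.frame, one row per pair: \code{pair}, \code{type},
#'   \code{delta_r} (long - short), \code{ci_overlap}, \code{verdict}
#'   (\code{"stationary"}/\code{"non-stationary"}).
#' @export
stationarityContrast <- function(table) {
    short <- table[table$group == "short", , drop = FALSE]
    long <- table[table$group == "long", , drop = FALSE]
    if (nrow(short) == 0L || nrow(long) == 0L)
        stop("both 'short' and 'long' groups are required in the table")
    stopifnot(identical(short$pair, long$pair))
    overlap <- short$ci_lo <= long$ci_hi & long$ci_lo <= short$ci_hi
    data.frame(pair = short$pair, type = short$type,
               delta_r = long$mean_r - short$mean_r,
               ci_overlap = overlap,
               verdict = ifelse(overlap, "stationary", "non-stationary"))
}
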