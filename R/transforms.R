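.hellingerMatrix <- function(v) {
    if (anyNA(v)) stop("matrix contains missing values")
    if (any(v < 0)) stop("Hellinger transformation requires non-negative values")
    rs <- rowSums(v)
    empty <- rs == 0
    if (any(empty)) {
        warning(sprintf("%d empty site(s) (all-zero rows) kept as zero rows: %s",
                        sum(empty),
                        paste(utils::head(rownames(v)[empty], 5L), collapse = ", ")))
        rs[empty] <- 1  # avoids 0/0; the rows stay exactly zero
    }
    out <- sqrt(v / rs)
    attr(out, "provenance") <- "hellinger"
    out
}

#' @rdname hellinger
#' @export
setMethod("hellinger", "matrix", function(object) .hellingerMatrix(object))

#' @rdname hellinger
#' @export
setMethod("hellinger", "CommunityMatrix",
          function(object) .hellingerMatrix(object@values))

.zscoreMatrix <- function(v) {
    if (nrow(v) < 2L) stop("standardization requires at least 2 sites")
    mu <- colMeans(v)
    centered <- sweep(v, 2L, mu)
    ## population SD (divisor n): the matrix is the analysis population,
    ## and the choice cancels inside the unit-trace Procrustes scaling
    sdp <- sqrt(colMeans(centered^2))
    flat <- sdp < 1e-12
    if (any(flat)) {
        warning(sprintf("zero-variance column(s) set to zero: %s",
                        paste(colnames(v)[flat], collapse = ", ")))
        sdp[flat] <- 1
    }
    out <- sweep(centered, 2L, sdp, "/")
    attr(out, "provenance") <- "zscore"
    out
}

#' @rdname standardizeEnv
#' @export
setMethod("standardizeEnv", "matrix", function(object) .zscoreMatrix(object))

#' @rdname standardizeEnv
#' @export
setMethod("standardizeEnv", "HydroperiodMatrix",
          function(object) .zscoreMatrix(object@values))

#' Zero-pad two row-matched matrices to a common column dimension
#'
#' Procrustes superimposition needs configurations of equal dimension;
#' zero-filled columns are appended to the narrower matrix to match the
#' wider one. Padding adds only zero singular values to the
#' cross-product, so the congruence statistic is unchanged.
#'
#' @param x,y numeric matrices with identical row counts (and identical
#'   rownames when both are named).
#' @return a list with elements \code{x} and \code{y}, both with
#'   \code{max(ncol(x), ncol(y))} columns; existing cells are untouched
#'   and pad columns are named \code{.pad1}, \code{.pad2}, ...
#' @export
padToCommonDimension <- function(x, y) {
    if (nrow(x) != nrow(y))
        stop("matrices must have the same number of rows (sites)")
    if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
        !identical(rownames(x), rownames(y)))
        stop("matrices must share the same site order")
    p <- max(ncol(x), ncol(y))
    pad <- function(m) {
        k <- p - ncol(m)
        if (k == 0L) return(m)
        z <- matrix(0, nrow(m), k,
                    dimnames = list(rownames(m), paste0(".pad", seq_len(k))))
        out <- cbind(m, z)
        attr(out, "provenance") <- "padded"
        out
    }
    list(x = pad(x), y = pad(y))
}

#' Derive one row of hydroperiod indicators from staff-gauge readings
#'
#' Converts a season of water-depth readings (May through September) at
#' one wetland into the four hydroperiod indicators. A wetland still
#' flooded in September is treated as possessing ponded water for 365
#' days; otherwise days ponded counts calendar days from the first
#' (installation) reading to the date the wetland was first observed dry.
#'
#' @param depths numeric vector of water-depth readings (cm), >= 2 values.
#' @param dates readings' dates (Date or ISO-8601 strings), same length.
#' @param dryDate date first observed dry (required unless
#'   \code{floodedThroughSeptember}).
#' @param floodedThroughSeptember logical; TRUE if ponded water persisted
#'   to the September visit.
#' @param evapIndex stable-isotope evaporative-loss index, passed through.
#' @return one-row data.frame with columns \code{days_ponded},
#'   \code{max_depth}, \code{amplitude_ratio}, \code{evap_index}.
#' @examples
#' deriveHydroIndicators(c(50, 40, 30),
#'                       c("2014-05-01", "2014-07-01", "2014-09-01"),
#'                       floodedThroughSeptember = TRUE, evapIndex = 0.3)
#' @export
deriveHydroIndicators <- function(depths, dates, dryDate = NULL,
                                  floodedThroughSeptember = FALSE,
                                  evapIndex = NA_real_) {
    if (length(depths) < 2L) stop("at least 2 gauge readings are required")
    if (anyNA(depths) || any(depths < 0)) stop("gauge readings must be non-negative")
    dates <- as.Date(dates)
    if (length(dates) != length(depths)) stop("one date per reading is required")
    if (floodedThroughSeptember) {
        daysPonded <- 365
    } else {
        if (is.null(dryDate))
            stop("hydroperiod undetermined: wetland not flooded through September but no dry date recorded")
        daysPonded <- as.numeric(as.Date(dryDate) - min(dates))
    }
    maxDepth <- max(depths)
    amplitude <- maxDepth - min(depths)
    data.frame(days_ponded = clamp(daysPonded, 0, 365),
               max_depth = maxDepth,
               amplitude_ratio = if (maxDepth > 0) amplitude / maxDepth else 0,
               evap_index = evapIndex)
}
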