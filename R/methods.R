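#' @describeIn CommunityMatrix-class site IDs in row order.
#' @param object a CommunityMatrix.
#' @export
setMethod("siteIds", "CommunityMatrix", function(object) rownames(object@values))

#' @describeIn HydroperiodMatrix-class site IDs in row order.
#' @param object a HydroperiodMatrix.
#' @export
setMethod("siteIds", "HydroperiodMatrix", function(object) rownames(object@values))

#' @describeIn CommunityMatrix-class taxon codes in column order.
#' @export
setMethod("taxonIds", "CommunityMatrix", function(object) colnames(object@values))

#' @describeIn CommunityMatrix-class community label.
#' @export
setMethod("communityLabel", "CommunityMatrix", function(object) object@label)

#' @describeIn CommunityMatrix-class underlying abundance matrix.
#' @export
setMethod("abundances", "CommunityMatrix", function(object) object@values)

#' @describeIn HydroperiodMatrix-class underlying indicator matrix.
#' @export
setMethod("indicators", "HydroperiodMatrix", function(object) object@values)

setMethod("dim", "CommunityMatrix", function(x) dim(x@values))
setMethod("dim", "HydroperiodMatrix", function(x) dim(x@values))

setMethod("show", "CommunityMatrix", function(object) {
    cat(sprintf("CommunityMatrix '%s': %d sites x %d taxa\n",
                object@label, nrow(object@values), ncol(object@values)))
    cat(sprintf("  total abundance %.4g; %d empty sites\n",
                sum(object@values), sum(rowSums(object@values) == 0)))
})

setMethod("show", "HydroperiodMatrix", function(object) {
    cat(sprintf("HydroperiodMatrix: %d sites x 4 indicators (%s)\n",
                nrow(object@values), paste(HYDRO_VARIABLES, collapse = ", ")))
})

#' @describeIn ProcrustesResult-class pseudo-R.
#' @param object a ProcrustesResult.
#' @export
setMethod("pseudoR", "ProcrustesResult", function(object) object@r)

#' @describeIn ProcrustesResult-class m2 statistic.
#' @export
setMethod("squaredResiduals", "ProcrustesResult", function(object) object@m2)

#' @describeIn ProcrustesResult-class rotation matrix.
#' @export
setMethod("rotationMatrix", "ProcrustesResult", function(object) object@rotation)

#' @describeIn ProtestResult-class pseudo-R of the observed fit.
#' @param object a ProtestResult.
#' @export
setMethod("pseudoR", "ProtestResult", function(object) object@observed@r)

#' @describeIn ProtestResult-class m2 of the observed fit.
#' @export
setMethod("squaredResiduals", "ProtestResult", function(object) object@observed@m2)

#' @describeIn ProtestResult-class permutation p-value.
#' @export
setMethod("pValue", "ProtestResult", function(object) object@pValue)

#' @describeIn ProtestResult-class permutation pseudo-R draws.
#' @export
setMethod("permutedR", "ProtestResult", function(object) object@permutedR)

setMethod("show", "ProcrustesResult", function(object) {
    cat("Symmetric Procrustes superimposition\n")
    cat(sprintf("  n = %d sites, %d dimensions\n", object@nSites, object@nDims))
    cat(sprintf("  pseudo-R = %.6f, m2 = %.6f\n", object@r, object@m2))
})

setMethod("show", "ProtestResult", function(object) {
    show(object@observed)
    cat(sprintf("  PROTEST: B = %d permutations, p = %.6g\n",
                object@nPermutations, object@pValue))
})

setMethod("show", "SyntheticScenario", function(object) {
    cat("SyntheticScenario\n")
    cat(sprintf("  %d sites; class thresholds %s\n", object@nSites,
                paste(signif(object@classThresholds, 4), collapse = ", ")))
    cat(sprintf("  taxa: %s\n",
                paste(sprintf("%s=%d", names(object@nTaxa), object@nTaxa),
                      collapse = ", ")))
    cat(sprintf("  niche widths: %s; A = %g; kappa = %g\n",
                paste(signif(object@nicheWidth, 3), collapse = ", "),
                object@maxAbundance, object@kappa))
    cat(sprintf("  indicator noise SD = %g; gradient jitter SD = %g\n",
                object@indicatorNoiseSd, object@gradientNoiseSd))
    cat(sprintf("  dispersion = %g; seed = %s\n", object@dispersion,
                ifelse(is.na(object@seed), "none", object@seed)))
})

#' Serialize a protest result to a JSON record
#'
#' @param object a ProtestResult.
#' @return a JSON string with fields r, m2, p, B, seed, n, dims.
#' @export
protestToJSON <- function(object) {
    stopifnot(is(object, "ProtestResult"))
    jsonlite::toJSON(list(
        r = object@observed@r, m2 = object@observed@m2,
        p = object@pValue, B = object@nPermutations,
        seed = if (is.na(object@seed)) NULL else object@seed,
        n = object@observed@nSites, dims = object@observed@nDims),
        auto_unbox = TRUE, digits = NA, null = "null")
}
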