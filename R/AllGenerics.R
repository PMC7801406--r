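#' Site identifiers of a data object
#' @param object a CommunityMatrix or HydroperiodMatrix.
#' @return character vector of site IDs in row order.
#' @export
setGeneric("siteIds", function(object) standardGeneric("siteIds"))

#' Taxon identifiers of a community matrix
#' @param object a CommunityMatrix.
#' @return character vector of taxon codes in column order.
#' @export
setGeneric("taxonIds", function(object) standardGeneric("taxonIds"))

#' Community label
#' @param object a CommunityMatrix.
#' @return single character label.
#' @export
setGeneric("communityLabel", function(object) standardGeneric("communityLabel"))

#' Abundance values as a base matrix
#' @param object a CommunityMatrix.
#' @return the underlying site x taxon numeric matrix.
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))

#' Hydroperiod indicator values as a base matrix
#' @param object a HydroperiodMatrix.
#' @return the underlying site x 4 numeric matrix.
#' @export
setGeneric("indicators", function(object) standardGeneric("indicators"))

#' Procrustes pseudo-R (congruence)
#' @param object a ProcrustesResult or ProtestResult.
#' @return numeric pseudo-R in [0, 1].
#' @export
setGeneric("pseudoR", function(object) standardGeneric("pseudoR"))

#' Procrustes m2 residual statistic
#' @param object a ProcrustesResult or ProtestResult.
#' @return numeric m2 = 1 - r^2.
#' @export
setGeneric("squaredResiduals", function(object) standardGeneric("squaredResiduals"))

#' Optimal rotation matrix
#' @param object a ProcrustesResult.
#' @return p x p orthogonal matrix mapping the second configuration onto the first.
#' @export
setGeneric("rotationMatrix", function(object) standardGeneric("rotationMatrix"))

#' Permutation p-value
#' @param object a ProtestResult.
#' @return numeric p-value.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' Permutation pseudo-R draws
#' @param object a ProtestResult.
#' @return numeric vector of length B.
#' @export
setGeneric("permutedR", function(object) standardGeneric("permutedR"))

#' Hellinger transformation
#'
#' Row-wise transform \code{sqrt(x / rowSums(x))} that converts abundances
#' to square-rooted relative abundances, making community data suitable
#' for Euclidean-space methods such as Procrustes superimposition.
#'
#' @param object a CommunityMatrix or non-negative numeric matrix.
#' @return numeric matrix of the same dimension; rows with positive totals
#'   have unit Euclidean norm, all-zero rows stay zero (with a warning:
#'   empty sites are kept so row order stays synchronized across
#'   communities). Carries attribute \code{provenance = "hellinger"}.
#' @examples
#' hellinger(matrix(c(1, 1, 2), 1, 3, dimnames = list("s1", c("a", "b", "c"))))
#' @export
setGeneric("hellinger", function(object) standardGeneric("hellinger"))

#' Column standardization of hydroperiod indicators
#'
#' Z-scores each indicator column (population SD, divisor n) so that days,
#' centimetres, ratios and isotope indices contribute comparably to the
#' unit-trace scaling inside the Procrustes fit. Zero-variance columns
#' become all-zero with a warning.
#'
#' @param object a HydroperiodMatrix or numeric matrix with >= 2 rows.
#' @return numeric matrix with column means 0 and (where variance was
#'   positive) population SD 1; attribute \code{provenance = "zscore"}.
#' @export
setGeneric("standardizeEnv", function(object) standardGeneric("standardizeEnv"))
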