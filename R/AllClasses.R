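#' @import methods
NULL

## Permanence classes ordered by increasing hydroperiod; the short/long
## grouping follows the temporary+seasonal vs semi-permanent+permanent split.
PERMANENCE_CLASSES <- c("temporary", "seasonal", "semi-permanent", "permanent")

HYDRO_VARIABLES <- c("days_ponded", "max_depth", "amplitude_ratio", "evap_index")

#' Site-by-taxon abundance matrix for one horizontal community
#'
#' An S4 container for the non-negative abundance table of a single
#' horizontal community (a set of species sharing common resource or space
#' requirements, sampled as one taxon group — e.g. wetland birds, aquatic
#' macroinvertebrates, or vascular plants). Sites are rows, taxa are
#' columns. Abundances may be counts, densities per square metre, or
#' percent cover; all downstream congruence analysis is performed on
#' Hellinger-transformed relative abundances, so the recording unit only
#' needs to be consistent within a community.
#'
#' @slot values numeric matrix, sites x taxa, non-negative, with unique
#'   rownames (site identifiers) and colnames (taxon codes).
#' @slot label single character community label (e.g. \code{"birds"}).
#'
#' @seealso [communityMatrix()] for the user constructor, [hellinger()],
#'   [procrustesFit()].
#' @export
setClass("CommunityMatrix",
    representation(values = "matrix", label = "character"))

setValidity("CommunityMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "abundance values must be numeric")
    if (anyNA(v))
        msg <- c(msg, "abundance matrix contains missing cells; blanks are data errors, not zeros")
    else if (any(v < 0))
        msg <- c(msg, "abundance values must be non-negative")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "site identifiers (rownames) must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
        msg <- c(msg, "taxon identifiers (colnames) must be present and unique")
    if (nrow(v) < 3L)
        msg <- c(msg, "at least 3 sites are required (Procrustes needs >= 3 rows)")
    if (ncol(v) < 2L)
        msg <- c(msg, "at least 2 taxa are required (Procrustes needs >= 2 dimensions)")
    if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
        msg <- c(msg, "community label must be a single non-empty string")
    if (length(msg)) msg else TRUE
})

#' Construct a CommunityMatrix
#'
#' @param values numeric site x taxon matrix with rownames = site IDs and
#'   colnames = taxon codes; all entries must be non-negative and complete.
#' @param label single character community label.
#' @return A [CommunityMatrix-class] object.
#' @examples
#' m <- matrix(rpois(12, 5), 4, 3,
#'             dimnames = list(paste0("W", 1:4), paste0("sp", 1:3)))
#' communityMatrix(m, "birds")
#' @export
communityMatrix <- function(values, label) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("CommunityMatrix", values = values, label = label)
}

#' Hydroperiod indicator matrix
#'
#' Sites x 4 matrix of the hydroperiod indicators used to approximate the
#' latent hydroperiod variable: \code{days_ponded} (days with ponded water,
#' 0-365), \code{max_depth} (maximum water depth, cm), \code{amplitude_ratio}
#' (water-level amplitude divided by maximum depth, 0-1) and
#' \code{evap_index} (stable-isotope evaporative-loss index, unitless,
#' consumed as given).
#'
#' @slot values numeric matrix with exactly the four indicator columns and
#'   unique site rownames.
#' @export
setClass("HydroperiodMatrix", representation(values = "matrix"))

setValidity("HydroperiodMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!identical(colnames(v), HYDRO_VARIABLES))
        msg <- c(msg, sprintf("columns must be exactly: %s",
                              paste(HYDRO_VARIABLES, collapse = ", ")))
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "site identifiers (rownames) must be present and unique")
    if (anyNA(v)) {
        msg <- c(msg, "hydroperiod indicators contain missing values")
    } else if (length(msg) == 0L) {
        if (any(v[, "days_ponded"] < 0 | v[, "days_ponded"] > 365))
            msg <- c(msg, "days_ponded must lie in [0, 365]")
        if (any(v[, "amplitude_ratio"] < 0 | v[, "amplitude_ratio"] > 1))
            msg <- c(msg, "amplitude_ratio must lie in [0, 1]")
        if (any(v[, "max_depth"] < 0))
            msg <- c(msg, "max_depth must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a HydroperiodMatrix
#'
#' @param values numeric sites x 4 matrix (or data.frame) with columns
#'   \code{days_ponded}, \code{max_depth}, \code{amplitude_ratio},
#'   \code{evap_index} and site IDs as rownames.
#' @return A [HydroperiodMatrix-class] object.
#' @export
hydroperiodMatrix <- function(values) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("HydroperiodMatrix", values = values[, HYDRO_VARIABLES, drop = FALSE])
}

#' Result of a symmetric Procrustes superimposition
#'
#' Holds the fit of two row-matched configurations after column-centering,
#' scaling each to unit total sum of squares, and optimal orthogonal
#' rotation (reflections permitted). The congruence statistic is the
#' Procrustes correlation (pseudo-R) \eqn{r = \sum_i \sigma_i}, the sum of
#' singular values of the cross-product of the two scaled configurations;
#' the residual statistic is \eqn{m^2 = 1 - r^2}.
#'
#' @slot r Procrustes pseudo-R in [0, 1].
#' @slot m2 residual sum of squares statistic, \code{1 - r^2}.
#' @slot rotation p x p orthogonal matrix mapping the second configuration
#'   onto the first (applied as \code{Y \%*\% rotation}).
#' @slot nSites number of rows (sites) in the configurations.
#' @slot nDims common column dimension after zero-padding.
#' @export
setClass("ProcrustesResult",
    representation(r = "numeric", m2 = "numeric", rotation = "matrix",
                   nSites = "integer", nDims = "integer"))

setValidity("ProcrustesResult", function(object) {
    msg <- character()
    if (object@r < -1e-10 || object@r > 1 + 1e-10)
        msg <- c(msg, "pseudo-R must lie in [0, 1]")
    if (abs(object@m2 - (1 - object@r^2)) > 1e-10)
        msg <- c(msg, "m2 must equal 1 - r^2")
    rtr <- crossprod(object@rotation)
    if (max(abs(rtr - diag(nrow(rtr)))) > 1e-8)
        msg <- c(msg, "rotation must be orthogonal")
    if (length(msg)) msg else TRUE
})

#' Result of a PROTEST permutation test
#'
#' @slot observed the [ProcrustesResult-class] for the unpermuted matrices.
#' @slot nPermutations number of random row permutations B.
#' @slot pValue permutation p-value, \code{(1 + #\{r_perm >= r_obs\}) / (B + 1)}.
#' @slot permutedR the B permutation pseudo-R draws (for diagnostics).
#' @slot seed the seed used, or NA if none was supplied.
#' @export
setClass("ProtestResult",
    representation(observed = "ProcrustesResult", nPermutations = "integer",
                   pValue = "numeric", permutedR = "numeric", seed = "integer"))

setValidity("ProtestResult", function(object) {
    B <- object@nPermutations
    msg <- character()
    if (length(object@permutedR) != B)
        msg <- c(msg, "permutedR must hold one draw per permutation")
    if (object@pValue < 1 / (B + 1) - 1e-12 || object@pValue > 1 + 1e-12)
        msg <- c(msg, "pValue must lie in [1/(B+1), 1]")
    if (length(msg)) msg else TRUE
})

#' Scenario parameters for the synthetic wetland generator
#'
#' Bundles every knob of the niche-based community simulator: the number of
#' sites, the latent-gradient thresholds that carve out the four permanence
#' classes, taxon richness and Gaussian niche width per community, the
#' maximum expected abundance, the direct cross-community coupling strength
#' kappa routed from plants and invertebrates into birds, the indicator
#' noise level, and the count overdispersion.
#'
#' @slot nSites number of wetland sites (default 96, the study design).
#' @slot classThresholds three strictly increasing cut points in (0, 1) on
#'   the latent gradient separating temporary / seasonal / semi-permanent /
#'   permanent classes. Defaults 28/96, 63/96, 80/96 so the expected class
#'   counts reproduce the 28/35/17/14 design.
#' @slot nTaxa named integer vector: taxa per community
#'   (birds 40, invertebrates 60, plants 80 by default).
#' @slot nicheWidth named numeric: Gaussian niche width sigma per community
#'   on the unit gradient; environmental filtering strength is 1/sigma.
#' @slot maxAbundance expected abundance at a taxon's niche optimum.
#' @slot kappa coupling strength in [0, 1]: 0 = birds respond to the
#'   gradient only; 1 = birds driven entirely by the plant and
#'   invertebrate profiles.
#' @slot indicatorNoiseSd Gaussian noise SD of the hydroperiod indicators,
#'   expressed on the unit gradient scale (scaled by each indicator's range).
#' @slot gradientNoiseSd SD of each community's private Gaussian jitter of
#'   the latent gradient: a community responds to its own noisy perception
#'   of site hydroperiod, so different communities are not deterministic
#'   copies of one another.
#' @slot dispersion gamma-Poisson (negative binomial size) dispersion of
#'   the abundance draws; larger = closer to Poisson.
#' @slot seed integer seed driving the single root generator, or NA.
#' @export
setClass("SyntheticScenario",
    representation(nSites = "integer", classThresholds = "numeric",
                   nTaxa = "integer", nicheWidth = "numeric",
                   maxAbundance = "numeric", kappa = "numeric",
                   indicatorNoiseSd = "numeric", gradientNoiseSd = "numeric",
                   dispersion = "numeric", seed = "integer"))

setValidity("SyntheticScenario", function(object) {
    msg <- character()
    if (object@nSites < 3L)
        msg <- c(msg, "nSites must be >= 3")
    th <- object@classThresholds
    if (length(th) != 3L || any(diff(th) <= 0) || any(th <= 0) || any(th >= 1))
        msg <- c(msg, "classThresholds must be 3 strictly increasing values in (0, 1)")
    comm <- c("birds", "invertebrates", "plants")
    if (!identical(names(object@nTaxa), comm))
        msg <- c(msg, "nTaxa must be named birds, invertebrates, plants")
    if (!identical(names(object@nicheWidth), comm))
        msg <- c(msg, "nicheWidth must be named birds, invertebrates, plants")
    else if (any(object@nicheWidth <= 0))
        msg <- c(msg, "niche widths must be > 0")
    if (object@kappa < 0 || object@kappa > 1)
        msg <- c(msg, "kappa must lie in [0, 1]")
    if (object@maxAbundance < 0)
        msg <- c(msg, "maxAbundance must be >= 0")
    if (object@indicatorNoiseSd < 0)
        msg <- c(msg, "indicatorNoiseSd must be >= 0")
    if (object@gradientNoiseSd < 0)
        msg <- c(msg, "gradientNoiseSd must be >= 0")
    if (object@dispersion <= 0)
        msg <- c(msg, "dispersion must be > 0")
    if (length(msg)) msg else TRUE
})
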