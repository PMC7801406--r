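#' Construct a synthetic-wetland scenario
#'
#' Defaults reproduce the statistical structure the congruence analysis
#' assumes: 96 sites whose latent hydroperiod gradient is carved into
#' four permanence classes with expected counts 28/35/17/14, three
#' horizontal communities (birds 40, invertebrates 60, plants 80 taxa)
#' filtered by Gaussian niches along the gradient, four noisy monotone
#' hydroperiod indicators, and a direct plant/invertebrate-to-bird
#' coupling of strength \code{kappa}.
#'
#' @param nSites number of sites (default 96).
#' @param classThresholds three increasing cut points in (0, 1); defaults
#'   28/96, 63/96, 80/96.
#' @param nTaxa named vector (birds, invertebrates, plants) of taxon
#'   counts.
#' @param nicheWidth named vector of Gaussian niche widths on the unit
#'   gradient.
#' @param maxAbundance expected abundance at the niche optimum.
#' @param kappa cross-community coupling in [0, 1].
#' @param indicatorNoiseSd indicator noise SD on the unit-gradient scale.
#' @param gradientNoiseSd SD of each community's private jitter of the
#'   latent gradient (default 0.15).
#' @param dispersion negative-binomial size of the count draws.
#' @param seed optional integer seed (drives the whole simulation).
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(nSites = 96L,
                              classThresholds = c(28, 63, 80) / 96,
                              nTaxa = c(birds = 40L, invertebrates = 60L,
                                        plants = 80L),
                              nicheWidth = c(birds = 0.15,
                                             invertebrates = 0.15,
                                             plants = 0.15),
                              maxAbundance = 30,
                              kappa = 0,
                              indicatorNoiseSd = 0.05,
                              gradientNoiseSd = 0.15,
                              dispersion = 1,
                              seed = NULL) {
    new("SyntheticScenario", nSites = as.integer(nSites),
        classThresholds = classThresholds,
        nTaxa = vapply(nTaxa, as.integer, integer(1)),
        nicheWidth = nicheWidth, maxAbundance = maxAbundance,
        kappa = kappa, indicatorNoiseSd = indicatorNoiseSd,
        gradientNoiseSd = gradientNoiseSd,
        dispersion = dispersion, seed = .asSeed(seed))
}

#' Preset scenarios realizing the two hypothesized worlds
#'
#' \code{scenarioInteractionsWorld()} configures a strong direct
#' plant/invertebrate-to-bird coupling (kappa = 0.9 by default) on top of
#' the default gradient structure: cross-community congruence then
#' exceeds what a shared hydroperiod response produces, the
#' interactions-dominant pattern.
#'
#' \code{scenarioFilteringWorld()} configures a world where hydroperiod
#' filtering is the only structuring force: no coupling (kappa = 0),
#' noise-free indicators, and species-poor communities (8/10/12 taxa)
#' with moderate niche width. The low richness matters: the permutation
#' null baseline of the Procrustes pseudo-R grows with matrix width, so
#' species-rich cross-community pairs sit near their null ceiling at
#' bootstrap sample sizes and would dominate the magnitude comparison
#' for purely dimensional reasons (see the package vignette).
#'
#' @param kappa coupling strength of the interactions world.
#' @param seed optional integer seed.
#' @param ... further arguments passed to [syntheticScenario()].
#' @return a [SyntheticScenario-class].
#' @export
scenarioInteractionsWorld <- function(kappa = 0.9, seed = NULL, ...) {
    syntheticScenario(kappa = kappa, seed = seed, ...)
}

#' @rdname scenarioInteractionsWorld
#' @export
scenarioFilteringWorld <- function(seed = NULL, ...) {
    syntheticScenario(kappa = 0, indicatorNoiseSd = 0,
                      nTaxa = c(birds = 8L, invertebrates = 10L,
                                plants = 12L),
                      nicheWidth = c(birds = 0.3, invertebrates = 0.3,
                                     plants = 0.3),
                      dispersion = 5, seed = seed, ...)
}

#' Generate the synthetic landscape: sites, classes and indicators
#'
#' Draws a latent hydroperiod position h ~ Uniform(0, 1) per site,
#' assigns the permanence class by thresholding h, and produces the four
#' hydroperiod indicators as noisy monotone transforms of h:
#' \code{days_ponded = clamp(365 h + e, 0, 365)},
#' \code{max_depth = max(120 h + e, 0)} cm,
#' \code{amplitude_ratio = clamp(1 - 0.8 h + e, 0, 1)} (more ephemeral
#' wetlands fluctuate more relative to their depth), and
#' \code{evap_index = 1 - h + e}; each noise term is Gaussian with SD
#' \code{indicatorNoiseSd} scaled by the indicator's range. Draws come
#' from the current RNG stream; use [simulateWetlandDataset()] for a
#' fully seeded simulation.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list with \code{metadata} (data.frame in the loader's format),
#'   \code{hydro} ([HydroperiodMatrix-class]) and \code{truth} (list with
#'   the latent \code{h}, \code{class}, \code{kappa}; niche optima are
#'   added by [generateCommunities()]).
#' @export
generateLandscape <- function(scenario) {
    stopifnot(is(scenario, "SyntheticScenario"))
    n <- scenario@nSites
    ids <- sprintf("W%04d", seq_len(n))
    h <- stats::runif(n)
    cls <- PERMANENCE_CLASSES[findInterval(h, scenario@classThresholds) + 1L]
    sd0 <- scenario@indicatorNoiseSd
    noise <- function(scale) stats::rnorm(n, 0, sd0 * scale)
    meta <- data.frame(
        site_id = ids,
        permanence_class = cls,
        days_ponded = clamp(365 * h + noise(365), 0, 365),
        max_depth_cm = pmax(120 * h + noise(120), 0),
        amplitude_ratio = clamp(1 - 0.8 * h + noise(1), 0, 1),
        evap_index = 1 - h + noise(1))
    truth <- list(h = stats::setNames(h, ids),
                  class = stats::setNames(cls, ids),
                  kappa = scenario@kappa, nicheOptima = list())
    list(metadata = meta, hydro = .hydroFromMetadata(meta), truth = truth)
}

## Gaussian niche response of every taxon at every site, taxa optima
## equally spaced on [0, 1] so composition turns over along the gradient.
.nicheExpectation <- function(h, nTaxa, sigma, A) {
    mu <- seq(0, 1, length.out = nTaxa)
    E <- A * exp(-outer(h, mu, "-")^2 / (2 * sigma^2))
    list(E = E, mu = mu)
}

.drawCounts <- function(E, dispersion) {
    counts <- suppressWarnings(
        stats::rnbinom(length(E), mu = as.vector(E), size = dispersion))
    counts[is.na(counts)] <- 0L  # mu = 0 cells
    matrix(as.numeric(counts), nrow(E), ncol(E), dimnames = dimnames(E))
}

#' Generate the three horizontal communities for a landscape
#'
#' Each community responds to its own noisy perception of the latent
#' gradient, \code{h_c = clamp(h + e_c, 0, 1)} with community-private
#' jitter \code{e_c ~ N(0, gradientNoiseSd)} — communities are filtered
#' by the same hydroperiod but are not deterministic copies of one
#' another. Taxon j of a community then has expected abundance
#' \eqn{A \exp(-(h_{c,i} - \mu_j)^2 / (2\sigma^2))} with equally spaced
#' niche optima, and counts are drawn from an overdispersed (gamma-mixed
#' Poisson, i.e. negative binomial) distribution.
#'
#' Bird expectations mix their own niche response with a habitat term of
#' weight \code{kappa}: for bird taxon j, a fixed random non-negative
#' sparse linear combination of the site's Hellinger-transformed plant
#' and invertebrate profiles, the contributing resource taxa drawn with
#' probability proportional to how close their niche optima sit to the
#' bird's own (birds forage and nest where their resources occur), and
#' rescaled to the mean of the bird's niche term so kappa interpolates
#' between comparably scaled fields. At kappa = 0 birds track
#' hydroperiod only; at kappa = 1 they are driven entirely by the
#' realized plant and invertebrate communities. Draws come from the
#' current RNG stream.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param truth the \code{truth} element from [generateLandscape()].
#' @return list with \code{communities} (named list of three
#'   [CommunityMatrix-class]: birds, invertebrates, plants) and the
#'   updated \code{truth} carrying the per-taxon niche optima.
#' @export
generateCommunities <- function(scenario, truth) {
    stopifnot(is(scenario, "SyntheticScenario"))
    h <- truth$h
    A <- scenario@maxAbundance
    disp <- scenario@dispersion
    taxaNames <- function(comm, k)
        sprintf("%s%03d", toupper(substr(comm, 1, 2)), seq_len(k))
    build <- function(comm) {
        hc <- clamp(h + stats::rnorm(length(h), 0, scenario@gradientNoiseSd),
                    0, 1)
        ne <- .nicheExpectation(hc, scenario@nTaxa[[comm]],
                                scenario@nicheWidth[[comm]], A)
        dimnames(ne$E) <- list(names(h), taxaNames(comm, ncol(ne$E)))
        ne
    }
    plantsNe <- build("plants")
    invertsNe <- build("invertebrates")
    plants <- .drawCounts(plantsNe$E, disp)
    inverts <- .drawCounts(invertsNe$E, disp)

    birdsNe <- build("birds")
    kappa <- scenario@kappa
    EBirds <- birdsNe$E
    if (kappa > 0 && A > 0) {
        profiles <- cbind(suppressWarnings(hellinger(plants)),
                          suppressWarnings(hellinger(inverts)))
        resourceOptima <- c(plantsNe$mu, invertsNe$mu)
        nBirds <- ncol(birdsNe$E)
        k <- min(6L, ncol(profiles))
        ## matching kernel width on the gradient: birds draw resources
        ## whose optima lie near their own
        matchSd <- 0.1
        habitat <- matrix(0, length(h), nBirds)
        for (j in seq_len(nBirds)) {
            affinity <- exp(-(birdsNe$mu[j] - resourceOptima)^2 /
                                (2 * matchSd^2))
            picks <- sample.int(ncol(profiles), k, prob = affinity)
            hj <- profiles[, picks, drop = FALSE] %*%
                stats::runif(k, 0.5, 1.5)
            mh <- mean(hj)
            mn <- mean(birdsNe$E[, j])
            if (mh > 0 && mn > 0) hj <- hj * (mn / mh)
            habitat[, j] <- hj
        }
        EBirds <- (1 - kappa) * birdsNe$E + kappa * habitat
    }
    birds <- .drawCounts(EBirds, disp)

    truth$nicheOptima <- list(birds = birdsNe$mu,
                              invertebrates = invertsNe$mu,
                              plants = plantsNe$mu)
    communities <- list(
        birds = communityMatrix(birds, "birds"),
        invertebrates = communityMatrix(inverts, "invertebrates"),
        plants = communityMatrix(plants, "plants"))
    list(communities = communities, truth = truth)
}

#' Simulate a complete synthetic wetland dataset
#'
#' Runs [generateLandscape()] and [generateCommunities()] under the
#' scenario's single root seed, returning the same structure
#' [loadDataset()] + [alignSites()] produce, plus the ground truth.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list with \code{communities}, \code{metadata}, \code{hydro}
#'   and \code{truth}.
#' @examples
#' sim <- simulateWetlandDataset(syntheticScenario(seed = 1))
#' sapply(sim$communities, dim)
#' @export
simulateWetlandDataset <- function(scenario) {
    stopifnot(is(scenario, "SyntheticScenario"))
    seed <- if (is.na(scenario@seed)) NULL else scenario@seed
    withLocalSeed(seed, {
        land <- generateLandscape(scenario)
        comm <- generateCommunities(scenario, land$truth)
        list(communities = comm$communities, metadata = land$metadata,
             hydro = land$hydro, truth = comm$truth)
    })
}

#' Write a simulated dataset in the loader's CSV formats
#'
#' Emits one community CSV per horizontal community (first column
#' \code{site_id}), the site metadata CSV, and the scenario as YAML, so
#' a simulated dataset round-trips through [loadDataset()].
#'
#' @param dataset result of [simulateWetlandDataset()].
#' @param dir output directory (created if needed).
#' @param scenario optional [SyntheticScenario-class] saved as
#'   \code{scenario.yaml} alongside the data.
#' @return invisibly, a named vector of the files written.
#' @export
writeWetlandDataset <- function(dataset, dir, scenario = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c()
    for (lab in names(dataset$communities)) {
        v <- abundances(dataset$communities[[lab]])
        df <- data.frame(site_id = rownames(v), v, check.names = FALSE)
        f <- file.path(dir, paste0(lab, ".csv"))
        utils::write.csv(df, f, row.names = FALSE)
        files[lab] <- f
    }
    f <- file.path(dir, "metadata.csv")
    utils::write.csv(dataset$metadata, f, row.names = FALSE)
    files["metadata"] <- f
    if (!is.null(scenario)) {
        f <- file.path(dir, "scenario.yaml")
        yaml::write_yaml(list(
            nSites = scenario@nSites,
            classThresholds = scenario@classThresholds,
            nTaxa = as.list(scenario@nTaxa),
            nicheWidth = as.list(scenario@nicheWidth),
            maxAbundance = scenario@maxAbundance,
            kappa = scenario@kappa,
            indicatorNoiseSd = scenario@indicatorNoiseSd,
            gradientNoiseSd = scenario@gradientNoiseSd,
            dispersion = scenario@dispersion,
            seed = if (is.na(scenario@seed)) NULL else scenario@seed), f)
        files["scenario"] <- f
    }
    invisible(files)
}
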