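test_that("percent elevation follows its closed form and guards the denominator", {
    expect_equal(percentElevation(c(0.9, 0.9), 0.45), 100)
    expect_equal(percentElevation(0.5, 0.5), 0)
    expect_equal(percentElevation(c(0.94, 0.90), 0.50), 84)
    expect_equal(percentElevation(c(0.3, 0.5), 0.8), -50)
    expect_error(percentElevation(c(0.5, 0.6), 0), "degenerate")
    ## scale invariance: rescaling every congruence leaves it unchanged
    set.seed(2)
    for (i in 1:10) {
        rc <- stats::runif(2); re <- stats::runif(1, 0.1, 1)
        cc <- stats::runif(1, 0.1, 5)
        expect_equal(percentElevation(cc * rc, cc * re),
                     percentElevation(rc, re), tolerance = 1e-10)
    }
})

test_that("elevation summary reproduces the three-community worked example", {
    s <- elevationSummary(c(84, 52, 95))
    expect_identical(s$mean, 77)  # exact on these rationals
    expect_equal(s$se, stats::sd(c(84, 52, 95)) / sqrt(3))
    expect_equal(s$se, 12.9, tolerance = 0.05)
    expect_equal(elevationSummary(c(40, 40, 40))$se, 0)
    expect_error(elevationSummary(50), "at least 2")
})

fakeTable <- function(rows) {
    out <- do.call(rbind, lapply(rows, as.data.frame))
    class(out) <- c("CongruenceTable", "data.frame")
    out
}

crossRow <- function(group, c1, c2, r, lo, hi)
    list(group = group, pair = paste(c1, c2, sep = "-"), community1 = c1,
         community2 = c2, type = "cross", mean_r = r, ci_lo = lo, ci_hi = hi,
         median_p = 0.005, significant = TRUE, iterations = 100)

envRow <- function(group, c1, r, lo, hi)
    list(group = group, pair = paste(c1, "hydroperiod", sep = "-"),
         community1 = c1, community2 = "hydroperiod", type = "env",
         mean_r = r, ci_lo = lo, ci_hi = hi, median_p = 0.005,
         significant = TRUE, iterations = 100)

test_that("pattern classification separates the two hypothesized worlds", {
    ## cross congruence far above every environmental value
    tabC <- fakeTable(c(
        list(crossRow("all", "birds", "invertebrates", 0.90, 0.85, 0.95),
             crossRow("all", "birds", "plants", 0.94, 0.89, 0.98),
             crossRow("all", "invertebrates", "plants", 0.78, 0.73, 0.83)),
        list(envRow("all", "birds", 0.50, 0.45, 0.55),
             envRow("all", "invertebrates", 0.55, 0.50, 0.60),
             envRow("all", "plants", 0.45, 0.40, 0.50))))
    out <- interpretPattern(tabC)
    expect_identical(out$interpretation, "interactions-dominant")
    ## birds: cross pairs (0.90, 0.94) vs env 0.50 -> 84%
    expect_equal(unname(out$percents["birds"]), 84)
    ## cross intervals straddling the environmental values: no evidence
    ## that interactions add anything
    tabE <- fakeTable(c(
        list(crossRow("all", "birds", "invertebrates", 0.52, 0.40, 0.62),
             crossRow("all", "birds", "plants", 0.50, 0.38, 0.60),
             crossRow("all", "invertebrates", "plants", 0.51, 0.39, 0.61)),
        list(envRow("all", "birds", 0.55, 0.50, 0.60),
             envRow("all", "invertebrates", 0.52, 0.47, 0.57),
             envRow("all", "plants", 0.50, 0.45, 0.55))))
    expect_identical(interpretPattern(tabE)$interpretation,
                     "environment-consistent")
    expect_error(interpretPattern(tabC, group = "short"), "not present")
})

test_that("stationarity is read off confidence-interval overlap per pair", {
    mk <- function(grp, r, lo, hi) c(
        list(crossRow(grp, "birds", "invertebrates", r, lo, hi),
             crossRow(grp, "birds", "plants", r, lo, hi),
             crossRow(grp, "invertebrates", "plants", r, lo, hi)),
        list(envRow(grp, "birds", r, lo, hi),
             envRow(grp, "invertebrates", r, lo, hi),
             envRow(grp, "plants", r, lo, hi)))
    ## identical distributions in both groups: all stationary
    tab <- fakeTable(c(mk("short", 0.6, 0.5, 0.7), mk("long", 0.6, 0.5, 0.7)))
    sc <- stationarityContrast(tab)
    expect_equal(nrow(sc), 6)
    expect_true(all(sc$delta_r == 0))
    expect_true(all(sc$verdict == "stationary"))
    ## disjoint intervals: non-stationary
    tab2 <- fakeTable(c(mk("short", 0.3, 0.2, 0.4), mk("long", 0.6, 0.5, 0.7)))
    sc2 <- stationarityContrast(tab2)
    expect_true(all(sc2$verdict == "non-stationary"))
    expect_equal(sc2$delta_r, rep(0.3, 6), tolerance = 1e-10)
    ## touching intervals still count as overlap
    tab3 <- fakeTable(c(mk("short", 0.3, 0.2, 0.5), mk("long", 0.6, 0.5, 0.7)))
    expect_true(all(stationarityContrast(tab3)$ci_overlap))
    expect_error(stationarityContrast(fakeTable(mk("short", 0.5, 0.4, 0.6))),
                 "both")
})

test_that("the congruence table covers every pair in every group", {
    sim <- simulateWetlandDataset(syntheticScenario(nSites = 40, seed = 4))
    tr <- lapply(sim$communities, function(cm) suppressWarnings(hellinger(cm)))
    hz <- standardizeEnv(sim$hydro)
    tab <- congruenceTable(tr, hz, sim$metadata,
                           groups = c("all", "short", "long"),
                           nTarget = 8, iterations = 8, BPerm = 9, seed = 1)
    expect_equal(nrow(tab), 18)
    expect_equal(length(unique(tab$pair)), 6)
    expect_true(all(table(tab$group) == 6))
    expect_true(all(tab$mean_r >= 0 & tab$mean_r <= 1))
    expect_true(all(tab$ci_lo <= tab$ci_hi))
    expect_true(all(tab$median_p >= 1 / 10 - 1e-12))  # PROTEST floor at B = 9
    ## deterministic under the seed
    tab2 <- congruenceTable(tr, hz, sim$metadata,
                            groups = c("all", "short", "long"),
                            nTarget = 8, iterations = 8, BPerm = 9, seed = 1)
    expect_identical(tab$mean_r, tab2$mean_r)
})
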