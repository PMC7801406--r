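test_that("rarefaction of a matrix against itself is exactly flat at r = 1", {
    x <- hellinger(randomAbundance(20, 6, seed = 3) + 1)
    curve <- rarefactionCurve(x, x, nMin = 3, nMax = 8, B = 10, seed = 1)
    expect_equal(curve$mean_r, rep(1, 6), tolerance = 1e-10)
    expect_equal(curve$se_r, rep(0, 6), tolerance = 1e-10)
    expect_identical(curve$n, 3:8)
})

test_that("null congruence is upward biased at small n and decays with n", {
    set.seed(8)
    x <- matrix(stats::rnorm(50 * 5), 50, 5)
    y <- matrix(stats::rnorm(50 * 5), 50, 5)
    rownames(x) <- rownames(y) <- sprintf("W%02d", 1:50)
    curve <- rarefactionCurve(x, y, nMin = 3, nMax = 25, B = 60, seed = 2)
    expect_gt(curve$mean_r[curve$n == 3], curve$mean_r[curve$n == 25] + 0.1)
    ## identical seeds give identical curves
    curve2 <- rarefactionCurve(x, y, nMin = 3, nMax = 25, B = 60, seed = 2)
    expect_identical(curve, curve2)
})

test_that("rarefaction guards its sample-size bounds", {
    x <- randomConfig(10, 3, seed = 1)
    expect_error(rarefactionCurve(x, x, nMin = 2, nMax = 8), "at least 3")
    expect_error(rarefactionCurve(x, x, nMin = 3, nMax = 11), "exceeds")
})

test_that("plateau detection follows the run-of-small-steps rule", {
    ## constant curve: plateau at the first point
    flat <- data.frame(n = 3:10, mean_r = rep(0.5, 8))
    expect_identical(detectPlateau(flat), 3L)
    ## all steps above tolerance: no plateau
    steep <- data.frame(n = 3:10, mean_r = seq(1, 0.3, length.out = 8))
    expect_identical(detectPlateau(steep), NA_integer_)
    ## hand-traced mixed curve: steps 0.1, 0.05, 0.009, 0.008, 0.007, 0.001
    ## from n = 3, so n = 5 is the first point whose next 3 steps are all
    ## below 0.01
    mixed <- data.frame(n = 3:9,
                        mean_r = cumsum(c(1, -0.1, -0.05, -0.009, -0.008,
                                          -0.007, -0.001)))
    expect_identical(detectPlateau(mixed, tol = 0.01, run = 3), 5L)
    expect_error(detectPlateau(flat[1:3, ]), "at least")
})

test_that("largest-remainder allocation is proportional, exact and deterministic", {
    ## the motivating design: 31 of 28/35 -> quotas 13.35/16.69,
    ## floors 13/16, both leftover seats to the largest remainders
    expect_identical(largestRemainderAllocation(c(28, 35), 31), c(14L, 17L))
    ## quotas 9.23/11.54/5.61/4.62: floors 9/11/5/4, two leftover seats
    ## to the .62 and .61 remainders
    expect_identical(largestRemainderAllocation(c(28, 35, 17, 14), 31),
                     c(9L, 11L, 6L, 5L))
    expect_identical(sum(largestRemainderAllocation(c(3, 3, 3), 5)), 5L)
    ## never allocates beyond a stratum size
    expect_true(all(largestRemainderAllocation(c(2, 9), 10) <= c(2, 9)))
    set.seed(6)
    for (i in 1:20) {
        sizes <- sample(1:40, 4)
        tot <- sample(seq_len(sum(sizes)), 1)
        a <- largestRemainderAllocation(sizes, tot)
        expect_identical(sum(a), as.integer(tot))
        expect_true(all(a <= sizes))
        expect_true(all(abs(a - tot * sizes / sum(sizes)) <= 1))
    }
})

test_that("balanced bootstrap resamples stratified subsets reproducibly", {
    meta <- designMetadata(c(temporary = 10, seasonal = 12,
                             `semi-permanent` = 6, permanent = 5))
    x <- hellinger(randomAbundance(33, 8, seed = 4) + 1)
    rownames(x) <- meta$site_id
    y <- x + matrix(stats::rnorm(length(x), sd = 0.05), nrow(x))
    bs <- balancedBootstrap(x, y, meta, "short", nTarget = 11,
                            iterations = 25, BPerm = 19, seed = 3)
    expect_length(bs$draws, 25)
    expect_true(all(bs$draws >= 0 & bs$draws <= 1))
    expect_true(bs$ci[1] <= bs$ci[2])
    expect_true(bs$medianP >= 1 / 20 && bs$medianP <= 1)
    bs2 <- balancedBootstrap(x, y, meta, "short", nTarget = 11,
                             iterations = 25, BPerm = 19, seed = 3)
    expect_identical(bs2$draws, bs$draws)
    ## a group of exactly the target size is computed once, with a
    ## zero-width interval
    bsLong <- balancedBootstrap(x, y, meta, "long", nTarget = 11,
                                iterations = 25, BPerm = 19, seed = 3)
    expect_identical(bsLong$iterations, 1L)
    expect_equal(diff(bsLong$ci), 0)
    ## identical matrices: every draw is perfectly congruent
    bsSelf <- balancedBootstrap(x, x, meta, "all", nTarget = 11,
                                iterations = 10, BPerm = 19, seed = 2)
    expect_equal(bsSelf$draws, rep(1, 10), tolerance = 1e-10)
    expect_equal(unname(bsSelf$ci), c(1, 1), tolerance = 1e-10)
    expect_equal(bsSelf$medianP, 1 / 20)
    ## too-small groups are refused
    expect_error(balancedBootstrap(x, y, meta, "long", nTarget = 12,
                                   iterations = 5, BPerm = 0), "fewer")
})

test_that("each bootstrap iteration applies one subset to every matrix pair", {
    meta <- designMetadata(c(temporary = 8, seasonal = 8,
                             `semi-permanent` = 4, permanent = 4))
    base <- hellinger(randomAbundance(24, 6, seed = 9) + 1)
    rownames(base) <- meta$site_id
    ## record which sites each pair sees by hijacking matrix contents:
    ## pair matrices are site-indicator columns, so the recovered subset
    ## is readable off the drawn rows
    marker <- diag(24)
    rownames(marker) <- meta$site_id
    pairs <- list(p1 = list(x = base, y = marker),
                  p2 = list(x = marker, y = base))
    seen <- local({
        set.seed(4)
        HydroCongruence:::.balancedDraws(pairs, meta, "all", nTarget = 9,
                                         iterations = 6, BPerm = 0L)
    })
    ## same subset => same r for both orientations (statistic is symmetric)
    expect_equal(seen$r[, "p1"], seen$r[, "p2"], tolerance = 1e-10)
    ## stratified subsets respect the largest-remainder allocation
    set.seed(10)
    sub <- HydroCongruence:::.stratifiedSubset(meta, meta$site_id, 9)
    cls <- table(meta$permanence_class[match(sub, meta$site_id)])
    expect_identical(as.integer(cls[c("temporary", "seasonal",
                                      "semi-permanent", "permanent")]),
                     c(3L, 3L, 2L, 1L))
})
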