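test_that("rank-sum test: degenerate, exact and symmetric behavior", {
    expect_warning(r <- rankSumTest(c(2, 2, 2), c(2, 2)), "identical")
    expect_equal(r$p.value, 1)
    r2 <- rankSumTest(c(1, 2), c(3, 4))
    expect_equal(r2$p.value, 1 / 3, tolerance = 1e-12)
    expect_equal(r2$method, "exact")
    ## identical samples under exact enumeration
    r3 <- rankSumTest(c(1, 3, 5), c(2, 4, 6))
    r3s <- rankSumTest(c(2, 4, 6), c(1, 3, 5))
    expect_equal(r3$p.value, r3s$p.value)
    ## a = b gives p = 1 (ties force the approximate path)
    r4 <- rankSumTest(c(1, 2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6, 7))
    expect_gt(r4$p.value, 0.9)
})

test_that("rank-sum exact p matches full enumeration at small n", {
    set.seed(44)
    for (i in 1:20) {
        a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
        expect_equal(rankSumTest(a, b)$p.value, exactRankSumP(a, b),
                     tolerance = 1e-9)
    }
})

test_that("normal approximation is within 0.02 of exact enumeration at 6+6", {
    set.seed(45)
    worst <- 0
    for (i in 1:200) {
        a <- rnorm(6); b <- rnorm(6, sample(c(0, 1, 2), 1))
        pEx <- exactRankSumP(a, b)
        wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                           correct = TRUE))
        worst <- max(worst, abs(wt$p.value - pEx))
    }
    expect_lt(worst, 0.02)
})

test_that("count comparisons: Welch t with Bonferroni adjustment", {
    d <- data.frame(condition = rep(c("ctl", "n60"), each = 10),
                    value = c(rnorm(10, 17, 1), rnorm(10, 9, 1)))
    res <- compareCounts(d, baseline = "ctl")
    expect_lt(res$p_adjusted, 1e-6)
    ## single comparison leaves the raw p unchanged
    expect_equal(res$p_adjusted, res$p_raw)
    ## identical condition gives an adjusted p of ~1 when several comparisons cap
    set.seed(2)
    d2 <- data.frame(condition = rep(c("ctl", "same"), each = 6),
                     value = rep(c(5, 6, 7, 5, 6, 7), 2))
    res2 <- compareCounts(d2, baseline = "ctl")
    expect_equal(res2$p_adjusted, 1)
    d3 <- data.frame(condition = rep(c("ctl", "x"), each = 3),
                     value = rep(5, 6))
    expect_error(compareCounts(d3, baseline = "ctl"), "zero variance")
})

test_that("Bonferroni multiplies by the number of comparisons and caps at 1", {
    set.seed(3)
    d <- data.frame(condition = rep(c("ctl", "a", "b", "c"), each = 8),
                    value = c(rnorm(8), rnorm(8, 0.2), rnorm(8, 0.1),
                              rnorm(8, 3)))
    res <- compareCounts(d, baseline = "ctl")
    expect_equal(res$p_adjusted, pmin(res$p_raw * 3, 1))
})

test_that("volume summaries: moments, quantiles, KDE normalization", {
    set.seed(19)
    v <- rlnorm(2000, log(0.1), 0.4)
    s <- volumeSummary(v)
    analytic <- exp(log(0.1) + 0.4^2 / 2)
    seMean <- sd(v) / sqrt(2000)
    expect_lt(abs(s$mean - analytic), 3 * seMean)
    expect_equal(s$variance, var(v))
    expect_false(is.unsorted(s$quantiles))
    ## KDE integrates to 1 on its grid
    dx <- diff(s$kde$x[1:2])
    expect_lt(abs(sum(s$kde$y) * dx - 1), 1e-3)
    expect_false(s$pointMass)
    ## degenerate sample
    s0 <- volumeSummary(rep(0.2, 12))
    expect_true(s0$pointMass)
    expect_equal(s0$variance, 0)
    expect_error(volumeSummary(1:5), "fewer than 10")
})

test_that("collapsed post-noise mixture has smaller volume variance than control", {
    set.seed(77)
    ctl <- getPreset("control_24k")@volumeMixture
    post <- getPreset("noise60_24k")@volumeMixture
    draw <- function(m, n) {
        comp <- sample.int(3, n, TRUE, prob = m[, "weight"])
        rlnorm(n, m[comp, "meanlog"], m[comp, "sdlog"])
    }
    wins <- vapply(1:50, function(i)
        var(draw(post, 300)) < var(draw(ctl, 300)), logical(1))
    expect_true(all(wins))
})

test_that("energy-dose ratios follow the equal-intensity model", {
    expect_equal(energyRatio(exposureDose(100, 60), exposureDose(100, 60)), 1)
    a <- exposureDose(105, 30); b <- exposureDose(100, 120)
    expect_equal(energyRatio(a, b) * energyRatio(b, a), 1, tolerance = 0)
    ## doubling duration doubles energy
    expect_equal(energyRatio(exposureDose(90, 20), exposureDose(90, 10)), 2)
    expect_error(exposureDose(100, 0), "positive")
})
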