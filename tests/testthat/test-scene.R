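test_that("zero-mean preset yields an empty scene", {
    p <- tinyPreset(total = 0, paired = 0, orphan = 0, orphanRec = 0)
    sc <- sampleScene(p, nCells = 3, seed = 4)
    expect_equal(nrow(ribbons(sc)), 0)
    expect_equal(nrow(receptors(sc)), 0)
})

test_that("generated counts match preset means within 3 standard errors", {
    n <- 600
    sc <- sampleScene(getPreset("control_12k"), nCells = n, seed = 101)
    rib <- ribbons(sc)
    se <- function(m) sqrt(m / n)
    expect_lt(abs(nrow(rib) / n - 17.3), 3 * se(17.3))
    expect_lt(abs(sum(rib$paired) / n - 15.8), 3 * se(15.8))
    expect_lt(abs(sum(!rib$paired) / n - 1.5), 3 * se(1.5))
    ## conservation is exact per cell by construction
    perCell <- table(factor(rib$cell, levels = seq_len(n)))
    perCellPaired <- tapply(rib$paired, factor(rib$cell, levels = seq_len(n)),
                            sum, default = 0)
    expect_true(all(perCell == perCellPaired +
                        (as.numeric(perCell) - perCellPaired)))
})

test_that("scene invariants hold: bounds, mutual pairing, orthonormal axes", {
    sc <- sampleScene(getPreset("noise60_24k"), nCells = 8, seed = 7)
    expect_true(validObject(sc))  # validity encodes the invariants
    rib <- ribbons(sc); rec <- receptors(sc)
    pr <- which(!is.na(rib$receptor))
    d <- sqrt((rib$z[pr] - rec$z[rib$receptor[pr]])^2 +
              (rib$y[pr] - rec$y[rib$receptor[pr]])^2 +
              (rib$x[pr] - rec$x[rib$receptor[pr]])^2)
    expect_true(all(d <= sc@pairingDistance + 1e-12))
    A <- cellAxes(sc)[[1]]
    expect_lt(max(abs(A %*% t(A) - diag(3))), 1e-9)
})

test_that("modiolar-pillar spread matches the two-Gaussian closed form", {
    p <- tinyPreset(total = 20, paired = 20, orphan = 0, orphanRec = 0,
                    sep = 6, mix = 0.5)
    g <- sceneGeometry(yVoxels = 140L, jitterSD = 0.5, minSpacing = 0.3)
    expected <- 0.5 * 0.5 * 6^2 + 0.5^2
    sc <- sampleScene(p, nCells = 400, geometry = g, seed = 56)
    u <- ribbons(sc)$y - cellTable(sc)$cy[1]
    expect_lt(abs(var(u) / expected - 1), 0.05)
})

test_that("scenes are reproducible from their seed", {
    p <- getPreset("control_24k")
    s1 <- sampleScene(p, 3, seed = 12)
    s2 <- sampleScene(p, 3, seed = 12)
    expect_identical(ribbons(s1), ribbons(s2))
    expect_identical(receptors(s1), receptors(s2))
    s3 <- sampleScene(p, 3, seed = 13)
    expect_false(identical(ribbons(s1), ribbons(s3)))
})

test_that("a soma that cannot fit the stack raises a bounds error", {
    g <- sceneGeometry(zPlanes = 10L)
    expect_error(sampleScene(getPreset("control_12k"), 1, geometry = g),
                 "soma does not fit")
})

test_that("volume-position coupling places large ribbons cuticular", {
    p <- tinyPreset(total = 15, paired = 15, orphan = 0, orphanRec = 0,
                    vpc = 0.8)
    sc <- sampleScene(p, nCells = 60, seed = 31)
    rib <- ribbons(sc)
    v <- rib$z - cellTable(sc)$cz[1]
    expect_gt(cor(v, rib$volume, method = "spearman"), 0.5)
})
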