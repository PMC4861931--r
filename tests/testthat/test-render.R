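test_that("empty scene with zero read noise is pure Poisson background", {
    p <- tinyPreset(0, 0, 0, 0)
    sc <- sampleScene(p, 1, geometry = tinyGeometry(), seed = 3)
    st <- renderStack(sc, background = 5, readNoiseSD = 0, seed = 3)
    x <- channelData(st, "ribbon")
    expect_true(all(x == round(x)))
    expect_lt(abs(mean(x) - 5), 3 * sqrt(5 / length(x)))
    expect_lt(abs(var(as.numeric(x)) / 5 - 1), 0.05)
    clean <- renderStack(sc, background = 5, readNoiseSD = 0, noise = FALSE)
    expect_true(all(channelData(clean, "ribbon") == 5))
})

test_that("noise-free integrated intensity matches the brute-force voxel sum", {
    g <- tinyGeometry()
    p <- tinyPreset(0, 0, 0, 0)
    sc <- sampleScene(p, 1, geometry = g, seed = 9)
    ## inject a single known ribbon of 0.1 um^3 in the scene interior
    ctr <- c(cellTable(sc)$cz[1], cellTable(sc)$cy[1], cellTable(sc)$cx[1])
    sc@ribbons <- data.frame(cell = 1L, z = ctr[1], y = ctr[2], x = ctr[3],
                             volume = 0.1, cluster = "modiolar",
                             paired = FALSE, receptor = NA_integer_)
    st <- renderStack(sc, photonScale = 100, background = 0,
                      readNoiseSD = 0, noise = FALSE)
    nvox <- bruteSphereCount(stackShape(sc), voxelSize(sc), ctr, 0.1)
    expect_gt(nvox, 0)
    expect_equal(sum(channelData(st, "ribbon")), 100 * nvox,
                 tolerance = 1e-8)
})

test_that("noise-free rendering is linear in photonScale", {
    sc <- sampleScene(tinyPreset(4, 3, 1, 1), 1, geometry = tinyGeometry(),
                      seed = 21)
    a <- renderStack(sc, photonScale = 100, background = 0, noise = FALSE)
    b <- renderStack(sc, photonScale = 200, background = 0, noise = FALSE)
    expect_equal(2 * channelData(a, "ribbon"), channelData(b, "ribbon"),
                 tolerance = 1e-12)
})

test_that("rendering is bit-identical for the same scene and seed", {
    sc <- sampleScene(tinyPreset(), 1, geometry = tinyGeometry(), seed = 5)
    a <- renderStack(sc, seed = 5)
    b <- renderStack(sc, seed = 5)
    expect_identical(a@data, b@data)
})

test_that("render rejects bad noise parameters", {
    sc <- sampleScene(tinyPreset(), 1, geometry = tinyGeometry(), seed = 5)
    expect_error(renderStack(sc, photonScale = 0), "photonScale")
    expect_error(renderStack(sc, background = -1), "non-negative")
})

test_that("TIFF + metadata round trip preserves the counts exactly", {
    sc <- sampleScene(tinyPreset(), 1, geometry = tinyGeometry(), seed = 8)
    st <- renderStack(sc, seed = 8)
    pre <- file.path(withr::local_tempdir(), "stk")
    writeStack(st, pre)
    st2 <- readStack(pre)
    expect_equal(st2@data, st@data, tolerance = 0)
    expect_identical(channelRoles(st2), channelRoles(st))
    expect_equal(voxelSize(st2), voxelSize(st))
})

test_that("truth sidecar round trip reproduces the scene field-for-field", {
    sc <- sampleScene(getPreset("noise30_12k"), 3, seed = 14)
    path <- file.path(withr::local_tempdir(), "truth.json")
    writeSceneTruth(sc, path)
    sc2 <- readSceneTruth(path)
    expect_equal(ribbons(sc2), ribbons(sc), tolerance = 1e-12)
    expect_equal(receptors(sc2), receptors(sc), tolerance = 1e-12)
    expect_equal(cellTable(sc2), cellTable(sc), tolerance = 1e-12)
    expect_equal(cellAxes(sc2), cellAxes(sc))
    expect_identical(stackShape(sc2), stackShape(sc))
    expect_equal(sc2@pairingDistance, sc@pairingDistance)
    expect_identical(sc2@seed, sc@seed)
})
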