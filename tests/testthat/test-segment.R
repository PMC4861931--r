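vsz <- c(0.3, 0.08, 0.08)

test_that("an all-zero or constant stack yields no components", {
    x <- array(0, c(6, 10, 10))
    expect_equal(nrow(segmentComponents(x, vsz)), 0)
    expect_equal(nrow(segmentComponents(array(4, c(6, 10, 10)), vsz)), 0)
})

test_that("two well-separated blobs give two components at true positions", {
    x <- array(0, c(12, 60, 60))
    x[5:7, 10:14, 10:14] <- 50   # blob A
    x[5:7, 48:52, 48:52] <- 50   # blob B, ~3 um away in y
    comps <- segmentComponents(x, vsz, thresholdMethod = "fixed:10")
    expect_equal(nrow(comps), 2)
    ## intensity-weighted centroids of symmetric blobs sit at their centres
    expect_lt(abs(comps$cy[1] - (12 + 0.5) * 0.08), 0.081)
    expect_lt(abs(comps$cz[1] - (6 + 0.5) * 0.3), 0.301)
    expect_lt(abs(comps$cy[2] - (50 + 0.5) * 0.08), 0.081)
})

test_that("voxel counts agree with an independent graph-based labeling", {
    skip_if_not_installed("igraph")
    set.seed(77)
    x <- array(0, c(10, 16, 16))
    ## sprinkle random blobs and speckle noise
    for (i in 1:6) {
        c0 <- c(sample(2:9, 1), sample(2:15, 1), sample(2:15, 1))
        x[max(1, c0[1]-1):min(10, c0[1]+1),
          max(1, c0[2]-1):min(16, c0[2]+1),
          max(1, c0[3]-1):min(16, c0[3]+1)] <- 20
    }
    x <- x + array(runif(length(x), 0, 12), dim(x))
    thr <- 10; minVox <- 3L
    comps <- segmentComponents(x, vsz, thresholdMethod = thr,
                               minVoxels = minVox)
    ## oracle: build the 26-adjacency graph of suprathreshold voxels
    idx <- which(x > thr, arr.ind = TRUE)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    ids <- setNames(seq_len(nrow(idx)), key(idx))
    edges <- integer(0)
    for (v in seq_len(nrow(idx))) {
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
            if (dz == 0 && dy == 0 && dx == 0) next
            nb <- idx[v, ] + c(dz, dy, dx)
            j <- ids[paste(nb[1], nb[2], nb[3])]
            if (!is.na(j) && j > v) edges <- c(edges, v, j)
        }
    }
    gr <- igraph::make_graph(edges, n = nrow(idx), directed = FALSE)
    sizes <- igraph::components(gr)$csize
    expect_equal(sort(comps$voxel_count), sort(sizes[sizes >= minVox]))
    expect_equal(sum(comps$voxel_count), sum(sizes[sizes >= minVox]))
})

test_that("component invariants hold and segmentation is deterministic", {
    sc <- sampleScene(tinyPreset(), 2, seed = 19)
    st <- renderStack(sc, seed = 19)
    dec <- deconvolve(channelData(st, "ribbon"), gaussianPSF(), 15,
                      voxelSize(st))
    a <- segmentComponents(dec, voxelSize(st))
    b <- segmentComponents(dec, voxelSize(st))
    expect_identical(a, b)
    voxvol <- prod(voxelSize(st))
    expect_equal(a$volume, a$voxel_count * voxvol, tolerance = 1e-12)
    ## centroid inside the physical bounding box
    expect_true(all(a$cz >= a$z0 * 0.3 & a$cz <= a$z1 * 0.3))
    expect_true(all(a$cy >= a$y0 * 0.08 & a$cy <= a$y1 * 0.08))
    expect_true(all(a$cx >= a$x0 * 0.08 & a$cx <= a$x1 * 0.08))
    expect_true(all(a$voxel_count >= 2))
})

test_that("min_voxels filters small components", {
    x <- array(0, c(6, 12, 12))
    x[3, 4, 4] <- 100                 # single voxel speck
    x[3:4, 8:9, 8:9] <- 100           # 8-voxel blob
    c1 <- segmentComponents(x, vsz, thresholdMethod = "fixed:10",
                            minVoxels = 4L)
    expect_equal(nrow(c1), 1)
    c2 <- segmentComponents(x, vsz, thresholdMethod = "fixed:10",
                            minVoxels = 1L)
    expect_equal(nrow(c2), 2)
})

test_that("estimated volumes track true volumes on a rendered scene", {
    sc <- sampleScene(getPreset("control_12k"), 2, seed = 23)
    st <- renderStack(sc, seed = 23)
    dec <- deconvolve(channelData(st, "ribbon"), gaussianPSF(), 25,
                      voxelSize(st))
    comps <- segmentComponents(dec, voxelSize(st))
    tr <- ribbons(sc)
    D <- sqrt(outer(tr$z, comps$cz, "-")^2 + outer(tr$y, comps$cy, "-")^2 +
              outer(tr$x, comps$cx, "-")^2)
    nn <- apply(D, 1, which.min)
    matched <- apply(D, 1, min) < 0.4
    expect_gt(mean(matched), 0.9)
    expect_gt(cor(tr$volume[matched], comps$volume[nn[matched]],
                  method = "spearman"), 0.9)
})

test_that("threshold methods are parsed and validated", {
    x <- array(c(rep(1, 500), rep(30, 100)), c(6, 10, 10))
    expect_equal(attr(segmentComponents(x, vsz,
                                        thresholdMethod = "fixed:12"),
                      "threshold"), 12)
    q <- attr(segmentComponents(x, vsz, thresholdMethod = "quantile:0.5"),
              "threshold")
    expect_equal(q, unname(quantile(x, 0.5)))
    expect_error(segmentComponents(x, vsz, thresholdMethod = "quantile:1.5"),
                 "quantile")
    expect_error(segmentComponents(x, vsz, thresholdMethod = "foo"),
                 "unknown threshold")
})
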