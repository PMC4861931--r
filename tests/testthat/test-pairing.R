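mkComp <- function(pos, ids = seq_len(nrow(pos))) {
    data.frame(id = ids, cz = pos[, 1], cy = pos[, 2], cx = pos[, 3])
}

test_that("degenerate inputs orphan everything", {
    rc <- mkComp(rbind(c(0, 0, 0), c(0, 0, 1)))
    pr <- pairComponents(mkComp(matrix(numeric(0), ncol = 3)), rc)
    expect_equal(nrow(synapsePairs(pr)), 0)
    expect_equal(nrow(orphanReceptors(pr)), 2)
    ## one ribbon, one receptor, beyond the distance threshold
    pr2 <- pairComponents(mkComp(rbind(c(0, 0, 0))),
                          mkComp(rbind(c(0, 0, 5))), maxPairDistance = 1)
    expect_equal(nrow(synapsePairs(pr2)), 0)
    expect_equal(nrow(orphanRibbons(pr2)), 1)
    expect_equal(nrow(orphanReceptors(pr2)), 1)
})

test_that("pairs and orphans partition the inputs; swap symmetry holds", {
    set.seed(42)
    for (rep in 1:25) {
        nr <- sample(0:8, 1); nc <- sample(0:8, 1)
        rb <- mkComp(matrix(runif(nr * 3, 0, 4), ncol = 3))
        rc <- mkComp(matrix(runif(nc * 3, 0, 4), ncol = 3))
        pr <- pairComponents(rb, rc, 1.0)
        expect_equal(nrow(synapsePairs(pr)) + nrow(orphanRibbons(pr)), nr)
        expect_equal(nrow(synapsePairs(pr)) + nrow(orphanReceptors(pr)), nc)
        ## symmetry: swapping roles exchanges the pair columns
        sw <- pairComponents(rc, rb, 1.0)
        a <- synapsePairs(pr); b <- synapsePairs(sw)
        expect_equal(nrow(a), nrow(b))
        if (nrow(a)) {
            expect_setequal(paste(a$ribbon_id, a$receptor_id),
                            paste(b$receptor_id, b$ribbon_id))
        }
    }
})

test_that("pair count is monotone in the distance threshold", {
    set.seed(9)
    rb <- mkComp(matrix(runif(24, 0, 4), ncol = 3))
    rc <- mkComp(matrix(runif(24, 0, 4), ncol = 3))
    counts <- vapply(c(0.2, 0.5, 1, 2, 5),
                     function(d) nrow(synapsePairs(pairComponents(rb, rc, d))),
                     numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("greedy matching attains the exhaustive optimum when synapses are separated", {
    set.seed(7)
    gaps <- integer(200)
    for (i in seq_len(200)) {
        n <- sample(2:6, 1)
        ## well-separated ribbon positions with nearby receptors
        base <- matrix(runif(n * 3, 0, 20), ncol = 3)
        while (n > 1 && min(dist(base)) < 2.5)
            base <- matrix(runif(n * 3, 0, 20), ncol = 3)
        off <- matrix(rnorm(n * 3, 0, 0.15), ncol = 3)
        rb <- mkComp(base)
        rc <- mkComp(base + off)
        D <- as.matrix(dist(rbind(base, base + off)))[seq_len(n),
                                                      n + seq_len(n)]
        greedy <- nrow(synapsePairs(pairComponents(rb, rc, 1.0)))
        gaps[i] <- maxMatchingSize(D, 1.0) - greedy
    }
    expect_true(all(gaps == 0))
})

test_that("cell assignment reproduces known memberships and per-cell counts", {
    sc <- sampleScene(getPreset("control_12k"), 3, seed = 2)
    rib <- ribbons(sc); rec <- receptors(sc)
    rb <- data.frame(id = seq_len(nrow(rib)), cz = rib$z, cy = rib$y,
                     cx = rib$x)
    rc <- data.frame(id = seq_len(nrow(rec)), cz = rec$z, cy = rec$y,
                     cx = rec$x)
    pr <- pairComponents(rb, rc, 1.0)
    asg <- assignToCells(pr, cellTable(sc))
    expect_identical(asg$ribbonCell, as.integer(rib$cell))
    expect_identical(asg$receptorCell, as.integer(rec$cell))
    pc <- asg$perCell
    expect_equal(pc$total_ribbons, pc$paired + pc$orphan_ribbons)
    expect_equal(sum(pc$total_ribbons), nrow(rib))
    ## single giant cell covering everything reproduces the global counts
    one <- data.frame(cell_id = 1L, cz = mean(rib$z), cy = mean(rib$y),
                      cx = mean(rib$x))
    asg1 <- assignToCells(pr, one, maxSomaDistance = 1e6)
    expect_equal(asg1$perCell$paired, nrow(synapsePairs(pr)))
    expect_equal(asg1$perCell$orphan_receptors, nrow(orphanReceptors(pr)))
})

test_that("components beyond the soma cutoff are flagged unassigned", {
    rb <- data.frame(id = 1:2, cz = c(0, 0), cy = c(0, 0), cx = c(0, 50))
    pr <- pairComponents(rb, rb[0, ], 1.0)
    asg <- assignToCells(pr, data.frame(cell_id = 1, cz = 0, cy = 0, cx = 0),
                         maxSomaDistance = 6)
    expect_identical(asg$ribbonCell, c(1L, NA_integer_))
    expect_equal(asg$perCell$total_ribbons, 1)
})

test_that("count summaries report mean and s.e.m. by group", {
    pc <- data.frame(total_ribbons = c(4, 6, 5), paired = c(3, 5, 4),
                     orphan_ribbons = c(1, 1, 1), orphan_receptors = 0,
                     condition = "control", frequency = "12k")
    cs <- countSummary(pc)
    expect_equal(cs$total_mean, 5)
    expect_equal(cs$paired_mean, 4)
    expect_equal(cs$orphan_mean, 1)
    expect_equal(cs$total_mean, cs$paired_mean + cs$orphan_mean)
    expect_equal(cs$total_sem, sd(c(4, 6, 5)) / sqrt(3))
    ## one cell with 3 pairs + 1 orphan
    one <- data.frame(total_ribbons = 4, paired = 3, orphan_ribbons = 1,
                      orphan_receptors = 0)
    cs1 <- countSummary(one)
    expect_equal(cs1$total_mean, 4)
    expect_equal(cs1$paired_mean, 3)
    expect_equal(cs1$orphan_mean, 1)
})
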