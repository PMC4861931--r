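axdef <- rbind(mp = c(0, 1, 0), ch = c(1, 0, 0), row = c(0, 0, 1))
colnames(axdef) <- c("z", "y", "x")

test_that("projection maps the soma centre to the origin and reads off axes", {
    expect_equal(unlist(projectToAxes(rbind(c(1, 2, 3)), c(1, 2, 3), axdef)),
                 c(u = 0, v = 0))
    uv <- projectToAxes(rbind(c(3, 2, 0)), c(0, 0, 0), axdef)
    expect_equal(uv$u, 2)  # along mp = y
    expect_equal(uv$v, 3)  # along ch = z
})

test_that("projection is a contraction of pairwise distances under rotation", {
    set.seed(3)
    for (i in 1:200) {
        ## random orthonormal frame via QR
        Q <- qr.Q(qr(matrix(rnorm(9), 3)))
        A <- rbind(mp = Q[, 1], ch = Q[, 2], row = Q[, 3])
        colnames(A) <- c("z", "y", "x")
        pts <- matrix(rnorm(15), ncol = 3)
        uv <- as.matrix(projectToAxes(pts, c(0, 0, 0), A))
        expect_true(all(dist(uv) <= dist(pts) + 1e-9))
    }
})

test_that("non-orthonormal axes are rejected", {
    bad <- axdef; bad["mp", ] <- c(0, 2, 0)
    expect_error(projectToAxes(rbind(c(0, 0, 0)), c(0, 0, 0), bad),
                 "orthonormal")
    bad2 <- axdef; bad2["ch", ] <- c(0, 1, 0)
    expect_error(projectToAxes(rbind(c(0, 0, 0)), c(0, 0, 0), bad2),
                 "orthonormal")
})

test_that("Gaussian MLE fit returns the sample mean and /n covariance", {
    sq <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
    fit <- fitGaussianMLE(sq)
    expect_equal(unname(fit$mean), c(0.5, 0.5))
    expect_equal(unname(fit$cov), diag(c(0.25, 0.25)))
    same <- matrix(rep(c(2, 3), each = 5), ncol = 2)
    fit2 <- fitGaussianMLE(same)
    expect_equal(unname(fit2$mean), c(2, 3))
    expect_equal(unname(fit2$cov), matrix(0, 2, 2))
    expect_error(fitGaussianMLE(sq[1:2, ]), "3 points")
})

test_that("Gaussian MLE recovers parameters of a known distribution", {
    set.seed(8)
    n <- 4000
    S <- matrix(c(2, 0.6, 0.6, 1), 2)
    L <- chol(S)
    x <- matrix(rnorm(2 * n), ncol = 2) %*% L
    x <- sweep(x, 2, c(-1, 2), "+")
    fit <- fitGaussianMLE(x)
    expect_lt(max(abs(fit$mean - c(-1, 2))), 3 * sqrt(2 / n))
    expect_lt(max(abs(fit$cov - S)), 3 * 2 * sqrt(2 / n) * 2)
})

test_that("alignment centres every stack and preserves internal distances", {
    set.seed(11)
    s1 <- data.frame(u = rnorm(8), v = rnorm(8), volume = rlnorm(8),
                     pair_id = 1:8)
    s2 <- transform(s1, u = u + 10, v = v - 4)
    ens <- alignEnsemble(list(a = s1, b = s2))
    p <- ensemblePoints(ens)
    for (sid in c("a", "b")) {
        sub <- p[p$stack_id == sid, ]
        expect_lt(max(abs(c(mean(sub$u), mean(sub$v)))), 1e-9)
        expect_equal(dist(cbind(sub$u, sub$v)), dist(cbind(s1$u, s1$v)),
                     tolerance = 1e-12, ignore_attr = TRUE)
    }
    ## constant-shift stacks collapse onto identical clouds
    a <- p[p$stack_id == "a", c("u", "v")]
    b <- p[p$stack_id == "b", c("u", "v")]
    expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("stacks below the minimum pair count are excluded with a warning", {
    s1 <- data.frame(u = rnorm(5), v = rnorm(5), volume = 1, pair_id = 1:5)
    s2 <- data.frame(u = 0, v = 0, volume = 1, pair_id = 1)
    expect_warning(ens <- alignEnsemble(list(big = s1, small = s2)),
                   "excluded")
    expect_equal(unique(ensemblePoints(ens)$stack_id), "big")
    expect_error(suppressWarnings(alignEnsemble(list(small = s2))),
                 "no stack")
})
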