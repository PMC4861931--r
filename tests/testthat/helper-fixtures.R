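## shared fixtures: small presets/geometries so unit tests stay fast.

tinyPreset <- function(total = 6, paired = 5, orphan = 1, orphanRec = 1,
                       sep = 3.4, mix = 0.5, vpc = 0) {
    makePreset("tiny", meanTotal = total, meanPaired = paired,
               meanOrphanRibbons = orphan, orphanReceptorRate = orphanRec,
               clusterSeparation = sep, clusterMix = mix,
               volumePositionCor = vpc)
}

## one-cell geometry with a smaller soma so little stacks stay legal
tinyGeometry <- function(...) {
    sceneGeometry(zPlanes = 24L, yVoxels = 96L, cellPitchVoxels = 80L,
                  somaAxes = c(z = 3.0, y = 2.8, x = 2.6),
                  synapticHalfV = 1.8, synapticHalfRow = 1.8, ...)
}

## brute-force sphere painting used as an independent rendering oracle
bruteSphereCount <- function(shape, voxelSize, center, volume) {
    r <- (3 * volume / (4 * pi))^(1 / 3)
    n <- 0L
    for (z in 0:(shape[1] - 1)) for (y in 0:(shape[2] - 1))
        for (x in 0:(shape[3] - 1)) {
            p <- (c(z, y, x) + 0.5) * voxelSize
            if (sum((p - center)^2) <= r^2) n <- n + 1L
        }
    n
}

## exhaustive maximum-cardinality distance-constrained matching (bitmask
## recursion over receptors), independent of the greedy implementation
maxMatchingSize <- function(D, maxDist) {
    nr <- nrow(D); nc <- ncol(D)
    if (nr == 0 || nc == 0) return(0L)
    ok <- D <= maxDist
    memo <- new.env(hash = TRUE)
    rec <- function(i, used) {
        if (i > nr) return(0L)
        key <- paste0(i, "_", used)
        hit <- memo[[key]]
        if (!is.null(hit)) return(hit)
        best <- rec(i + 1L, used)  # leave ribbon i unmatched
        for (j in seq_len(nc)) {
            if (ok[i, j] && !bitwAnd(used, bitwShiftL(1L, j - 1L))) {
                cand <- 1L + rec(i + 1L, bitwOr(used, bitwShiftL(1L, j - 1L)))
                if (cand > best) best <- cand
            }
        }
        memo[[key]] <- best
        best
    }
    rec(1L, 0L)
}

## exact two-sided rank-sum p-value by full enumeration of group labelings
exactRankSumP <- function(a, b) {
    na <- length(a); nb <- length(b)
    pooled <- c(a, b)
    rk <- rank(pooled)
    wObs <- sum(rk[seq_len(na)])
    combs <- utils::combn(na + nb, na)
    ws <- apply(combs, 2, function(idx) sum(rk[idx]))
    mu <- na * (na + nb + 1) / 2
    mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}
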