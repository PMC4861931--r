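## synthetic ground-truth scenes: a row of IHCs with known synapses.

#' Stack and soma geometry for synthetic scenes
#'
#' Defaults emulate a high-NA confocal acquisition of the IHC basolateral
#' (synaptic) pole in whole-mount tissue: anisotropic voxels of
#' (0.3, 0.08, 0.08) micrometres (z, y, x), cells in a row along x at a
#' 7.52 micrometre pitch, the modiolar-pillar axis along y, and the
#' habenular-to-cuticular axis along z. Synapses occupy a basolateral band
#' of half-length `synapticHalfV` along the cell axis and `synapticHalfRow`
#' along the row axis, with a hard-core minimum spacing between distinct
#' synaptic structures (ribbons and orphan receptor patches are discrete
#' objects and do not interpenetrate).
#'
#' @param voxelSize `(z, y, x)` voxel size in micrometres.
#' @param zPlanes number of z planes.
#' @param yVoxels stack width in y voxels.
#' @param cellPitchVoxels per-cell x extent in voxels (pitch = voxels * x
#'   voxel size).
#' @param somaAxes soma ellipsoid semi-axes `(z, y, x)` in micrometres
#'   (recorded per cell; the soma must fit inside the stack).
#' @param synapticHalfV half-length of the synaptic band along the
#'   habenular-to-cuticular axis, micrometres.
#' @param synapticHalfRow half-width of the synaptic band along the cell
#'   row axis, micrometres.
#' @param jitterSD isotropic positional jitter SD around the cluster
#'   offset, micrometres.
#' @param minSpacing hard-core minimum distance between ribbons (and orphan
#'   receptor patches), micrometres; chosen above the default pairing
#'   distance so distinct synapses stay resolvable.
#' @param receptorSpacing minimum distance kept between a placed receptor
#'   patch and every other structure except its own ribbon, micrometres.
#' @param pairedOffsetRange min/max centroid offset of a paired receptor
#'   from its ribbon, micrometres.
#' @param pairingDistance maximum ribbon-receptor separation used at
#'   generation, micrometres.
#' @return A named list of geometry parameters.
#' @examples
#' g <- sceneGeometry()
#' g$voxelSize
#' @export
sceneGeometry <- function(voxelSize = c(z = 0.3, y = 0.08, x = 0.08),
                          zPlanes = 28L, yVoxels = 112L,
                          cellPitchVoxels = 94L,
                          somaAxes = c(z = 3.5, y = 3.0, x = 2.8),
                          synapticHalfV = 2.3, synapticHalfRow = 2.2,
                          jitterSD = 0.35, minSpacing = 1.2,
                          receptorSpacing = 1.0,
                          pairedOffsetRange = c(0.15, 0.4),
                          pairingDistance = 0.5) {
    stopifnot(length(voxelSize) == 3, all(voxelSize > 0),
              zPlanes >= 4, yVoxels >= 8, cellPitchVoxels >= 8,
              minSpacing > 0, pairingDistance > 0,
              pairedOffsetRange[2] <= pairingDistance)
    list(voxelSize = voxelSize, zPlanes = as.integer(zPlanes),
         yVoxels = as.integer(yVoxels),
         cellPitchVoxels = as.integer(cellPitchVoxels),
         somaAxes = somaAxes, synapticHalfV = synapticHalfV,
         synapticHalfRow = synapticHalfRow, jitterSD = jitterSD,
         minSpacing = minSpacing, receptorSpacing = receptorSpacing,
         pairedOffsetRange = pairedOffsetRange,
         pairingDistance = pairingDistance)
}

## dart-throwing placement with hard-core spacing; after `tries` failed
## attempts the spacing is relaxed geometrically so dense draws still
## terminate (relaxations are rare at the default densities).
.placePoint <- function(drawFun, accepted, minDist, tries = 300L) {
    d2min <- minDist^2
    relax <- 1
    repeat {
        for (i in seq_len(tries)) {
            p <- drawFun()
            if (nrow(accepted) == 0) return(p)
            dd <- (accepted[, 1] - p[1])^2 + (accepted[, 2] - p[2])^2 +
                (accepted[, 3] - p[3])^2
            if (min(dd) >= d2min * relax^2) return(p)
        }
        relax <- relax * 0.85
        if (relax < 0.2) return(p)
    }
}

.sampleMixtureVolumes <- function(n, mixture) {
    if (n == 0) return(numeric(0))
    comp <- sample.int(nrow(mixture), n, replace = TRUE,
                       prob = mixture[, "weight"])
    rlnorm(n, meanlog = mixture[comp, "meanlog"],
           sdlog = mixture[comp, "sdlog"])
}

## couple volumes to v-positions with approximate rank correlation rho
.coupleVolumes <- function(volumes, v, rho) {
    n <- length(volumes)
    if (n < 2 || rho == 0) return(volumes)
    zv <- qnorm((rank(v, ties.method = "first") - 0.5) / n)
    score <- rho * zv + sqrt(1 - rho^2) * rnorm(n)
    sort(volumes)[rank(score, ties.method = "first")]
}

#' Sample a ground-truth synthetic scene
#'
#' Draws per-cell paired and orphan ribbon counts from Poisson laws with
#' the preset means, places ribbons in the basolateral synaptic band offset
#' by +/- `clusterSeparation`/2 along the modiolar-pillar axis according to
#' a Bernoulli(`clusterMix`) cluster label plus isotropic Gaussian jitter,
#' draws volumes from the preset log-normal mixtures (optionally
#' rank-coupled to cuticular position), puts each paired receptor within
#' the generation pairing distance of its ribbon, and scatters orphan
#' receptors uniformly over the band. Fully reproducible from `seed`
#' (one RNG stream per scene).
#'
#' @param preset a [ConditionPreset-class], e.g. from [getPreset()].
#' @param nCells number of IHCs in the row (>= 1).
#' @param geometry see [sceneGeometry()].
#' @param seed integer seed.
#' @return A [GroundTruthScene-class].
#' @examples
#' sc <- sampleScene(getPreset("control_12k"), nCells = 2, seed = 1)
#' sc
#' @export
sampleScene <- function(preset, nCells, geometry = sceneGeometry(), seed = 1L) {
    stopifnot(is(preset, "ConditionPreset"), nCells >= 1)
    validObject(preset)
    g <- geometry
    vs <- g$voxelSize
    shape <- c(g$zPlanes, g$yVoxels, g$cellPitchVoxels * nCells)
    bounds <- unname(shape * vs)
    center0 <- c(bounds[1] / 2, bounds[2] / 2, NA)  # z, y; x per cell
    if (any(g$somaAxes > c(center0[1], center0[2], g$cellPitchVoxels * vs[3] / 2)))
        stop("soma does not fit in stack bounds; enlarge the stack geometry")

    set.seed(as.integer(seed))
    mp <- c(0, 1, 0); ch <- c(1, 0, 0); rowax <- c(0, 0, 1)  # (z,y,x) comps
    axes <- rbind(mp = mp, ch = ch, row = rowax)
    colnames(axes) <- c("z", "y", "x")

    cells <- data.frame(cell_id = seq_len(nCells),
                        cz = center0[1], cy = center0[2],
                        cx = (seq_len(nCells) - 0.5) * g$cellPitchVoxels *
                            unname(vs[3]),
                        az = unname(g$somaAxes[1]), ay = unname(g$somaAxes[2]),
                        ax = unname(g$somaAxes[3]))

    ribList <- list(); recList <- list()
    for (ci in seq_len(nCells)) {
        ctr <- c(cells$cz[ci], cells$cy[ci], cells$cx[ci])
        nPaired <- rpois(1, preset@meanPaired)
        nOrphanRib <- rpois(1, preset@meanOrphanRibbons)
        nOrphanRec <- rpois(1, preset@orphanReceptorRate)
        nRib <- nPaired + nOrphanRib

        clLabel <- ifelse(runif(nRib) < preset@clusterMix, "modiolar", "pillar")
        placed <- matrix(numeric(0), ncol = 3)
        ribPos <- matrix(NA_real_, nRib, 3)
        drawRibbon <- function(lab) {
            u <- (if (lab == "modiolar") 1 else -1) * preset@clusterSeparation / 2
            jit <- pmax(pmin(rnorm(3, 0, g$jitterSD), 3 * g$jitterSD),
                        -3 * g$jitterSD)
            v <- runif(1, -g$synapticHalfV, g$synapticHalfV)
            w <- runif(1, -g$synapticHalfRow, g$synapticHalfRow)
            ctr + u * mp + v * ch + w * rowax + jit
        }
        for (i in seq_len(nRib)) {
            lab <- clLabel[i]
            ribPos[i, ] <- .placePoint(function() drawRibbon(lab), placed,
                                       g$minSpacing)
            placed <- rbind(placed, ribPos[i, ])
        }
        orphanRecPos <- matrix(NA_real_, nOrphanRec, 3)
        uHalf <- preset@clusterSeparation / 2 + 0.8
        drawOrphanRec <- function() {
            u <- runif(1, -uHalf, uHalf)
            v <- runif(1, -g$synapticHalfV, g$synapticHalfV)
            w <- runif(1, -g$synapticHalfRow, g$synapticHalfRow)
            ctr + u * mp + v * ch + w * rowax
        }
        for (i in seq_len(nOrphanRec)) {
            orphanRecPos[i, ] <- .placePoint(drawOrphanRec, placed, g$minSpacing)
            placed <- rbind(placed, orphanRecPos[i, ])
        }

        ribVol <- .sampleMixtureVolumes(nRib, preset@volumeMixture)
        if (nRib > 0 && preset@volumePositionCor != 0) {
            vpos <- (ribPos[, 1] - ctr[1])  # component along ch (= z)
            ribVol <- .coupleVolumes(ribVol, vpos, preset@volumePositionCor)
        }

        ## paired receptors: small random offset from their ribbon, kept
        ## clear of every other structure so distinct synapses stay distinct
        pairedIdx <- if (nRib > 0) sort(sample.int(nRib, nPaired)) else integer(0)
        recPos <- matrix(numeric(0), ncol = 3)
        recOwner <- integer(0)
        allOther <- placed
        for (i in pairedIdx) {
            ok <- FALSE
            for (try in 1:60) {
                dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
                off <- runif(1, g$pairedOffsetRange[1], g$pairedOffsetRange[2])
                cand <- ribPos[i, ] + off * dir
                others <- rbind(allOther[-i, , drop = FALSE], recPos)
                if (nrow(others) == 0 ||
                    min((others[, 1] - cand[1])^2 + (others[, 2] - cand[2])^2 +
                        (others[, 3] - cand[3])^2) >= g$receptorSpacing^2) {
                    ok <- TRUE; break
                }
            }
            if (!ok) cand <- ribPos[i, ] + g$pairedOffsetRange[1] * c(0, 0, 1)
            recPos <- rbind(recPos, cand)
            recOwner <- c(recOwner, i)
        }
        recPos <- rbind(recPos, orphanRecPos)
        recOwner <- c(recOwner, rep(NA_integer_, nOrphanRec))
        nRec <- nrow(recPos)
        recVol <- .sampleMixtureVolumes(nRec, preset@receptorVolumeMixture)

        rib <- if (nRib > 0)
            data.frame(cell = ci,
                       z = ribPos[, 1], y = ribPos[, 2], x = ribPos[, 3],
                       volume = ribVol, cluster = clLabel,
                       paired = seq_len(nRib) %in% pairedIdx,
                       receptor = NA_integer_)
        else
            data.frame(cell = integer(0), z = numeric(0), y = numeric(0),
                       x = numeric(0), volume = numeric(0),
                       cluster = character(0), paired = logical(0),
                       receptor = integer(0))
        rec <- if (nRec > 0)
            data.frame(cell = ci, z = recPos[, 1], y = recPos[, 2],
                       x = recPos[, 3], volume = recVol,
                       ribbon = recOwner)
        else
            data.frame(cell = integer(0), z = numeric(0), y = numeric(0),
                       x = numeric(0), volume = numeric(0), ribbon = integer(0))
        if (length(pairedIdx))
            rib$receptor[pairedIdx] <- seq_along(pairedIdx)
        ribList[[ci]] <- rib
        recList[[ci]] <- rec
    }

    ## concatenate cells, fixing cross-references to global row indices
    ribAll <- do.call(rbind, ribList)
    recAll <- do.call(rbind, recList)
    if (is.null(ribAll)) ribAll <- ribList[[1]]
    ribOffset <- cumsum(c(0, vapply(ribList, nrow, 0L)))
    recOffset <- cumsum(c(0, vapply(recList, nrow, 0L)))
    for (ci in seq_len(nCells)) {
        rr <- ribOffset[ci] + seq_len(nrow(ribList[[ci]]))
        idx <- !is.na(ribAll$receptor[rr])
        ribAll$receptor[rr][idx] <- ribAll$receptor[rr][idx] + recOffset[ci]
        ss <- recOffset[ci] + seq_len(nrow(recList[[ci]]))
        jdx <- !is.na(recAll$ribbon[ss])
        recAll$ribbon[ss][jdx] <- recAll$ribbon[ss][jdx] + ribOffset[ci]
    }
    rownames(ribAll) <- NULL; rownames(recAll) <- NULL

    new("GroundTruthScene",
        cells = cells,
        axes = rep(list(axes), nCells),
        ribbons = ribAll, receptors = recAll,
        voxelSize = setNames(as.numeric(vs), c("z", "y", "x")),
        stackShape = as.integer(shape),
        seed = as.integer(seed), preset = preset@name,
        pairingDistance = g$pairingDistance)
}
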