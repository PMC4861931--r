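## confocal-like image formation: solid spheres of the true volume,
## separable Gaussian PSF blur, Poisson photon noise + Gaussian read noise.

#' Separable Gaussian point spread function
#'
#' A simple confocal PSF approximation: an axis-aligned Gaussian,
#' separable in z, y, x, with lateral width `sigmaXY` and axial width
#' `sigmaZ` (micrometres). Kernels are discretized on the voxel grid out to
#' 4 sigma and normalized to sum 1 per axis, so the 3D kernel sums to 1 and
#' blurring conserves flux.
#'
#' @param sigmaXY lateral standard deviation, micrometres.
#' @param sigmaZ axial standard deviation, micrometres.
#' @return An object of class `GaussianPSF`.
#' @examples
#' gaussianPSF()
#' @export
gaussianPSF <- function(sigmaXY = 0.12, sigmaZ = 0.35) {
    stopifnot(sigmaXY > 0, sigmaZ > 0)
    structure(list(sigmaXY = sigmaXY, sigmaZ = sigmaZ), class = "GaussianPSF")
}

#' @export
print.GaussianPSF <- function(x, ...) {
    cat(sprintf("GaussianPSF: sigma_xy = %.3f um, sigma_z = %.3f um\n",
                x$sigmaXY, x$sigmaZ))
    invisible(x)
}

.gaussKernel1d <- function(sigmaUm, voxelUm) {
    s <- sigmaUm / voxelUm
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k / sum(k)
}

## per-axis kernels (z, y, x) in voxel units for a given voxel size
psfKernels <- function(psf, voxelSize) {
    stopifnot(inherits(psf, "GaussianPSF"))
    list(kz = .gaussKernel1d(psf$sigmaZ, voxelSize[1]),
         ky = .gaussKernel1d(psf$sigmaXY, voxelSize[2]),
         kx = .gaussKernel1d(psf$sigmaXY, voxelSize[3]))
}

## normalized separable blur (flat images are fixed points)
.blur3d <- function(x, kernels) {
    conv3d_sep_cpp(x, as.integer(dim(x)), kernels$kz, kernels$ky,
                   kernels$kx, TRUE)
}

## paint solid spheres of the stated volumes into a (z,y,x) array;
## overlapping spheres add.
.paintSpheres <- function(shape, voxelSize, pos, volumes) {
    arr <- array(0, dim = shape)
    if (nrow(pos) == 0) return(arr)
    r <- (3 * volumes / (4 * pi))^(1 / 3)
    for (i in seq_len(nrow(pos))) {
        ctr <- pos[i, ]
        lo <- pmax(floor((ctr - r[i]) / voxelSize - 0.5), 0)
        hi <- pmin(ceiling((ctr + r[i]) / voxelSize - 0.5), shape - 1)
        if (any(hi < lo)) next
        zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
        dz <- (zi + 0.5) * voxelSize[1] - ctr[1]
        dy <- (yi + 0.5) * voxelSize[2] - ctr[2]
        dx <- (xi + 0.5) * voxelSize[3] - ctr[3]
        d2 <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")
        inside <- d2 <= r[i]^2
        if (!any(inside)) {
            ## guarantee at least the voxel containing the centre
            zi0 <- min(max(round(ctr[1] / voxelSize[1] - 0.5), 0), shape[1] - 1)
            yi0 <- min(max(round(ctr[2] / voxelSize[2] - 0.5), 0), shape[2] - 1)
            xi0 <- min(max(round(ctr[3] / voxelSize[3] - 0.5), 0), shape[3] - 1)
            arr[zi0 + 1, yi0 + 1, xi0 + 1] <- arr[zi0 + 1, yi0 + 1, xi0 + 1] + 1
            next
        }
        sub <- arr[zi + 1, yi + 1, xi + 1, drop = FALSE]
        dim(sub) <- dim(inside)
        arr[zi + 1, yi + 1, xi + 1] <- sub + inside
    }
    arr
}

#' Render a ground-truth scene into a noisy two-channel stack
#'
#' Each synapse is rendered as a solid sphere of its true volume at
#' intensity `photonScale` photons per voxel (overlaps add), blurred with
#' the PSF, offset by a flat `background` photon rate, then corrupted with
#' Poisson photon noise plus additive Gaussian read noise and quantized to
#' 16-bit counts. With `noise = FALSE` the pristine (un-quantized) expected
#' photon image is returned, which is linear in `photonScale`.
#'
#' @param scene a [GroundTruthScene-class].
#' @param psf a [gaussianPSF()].
#' @param photonScale photons per voxel inside a synapse (> 0).
#' @param background flat background photon rate per voxel (>= 0).
#' @param readNoiseSD Gaussian read-noise SD in counts (>= 0).
#' @param noise apply photon/read noise and 16-bit quantization?
#' @param seed RNG seed for the noise draw.
#' @return A [SynapseStack-class] with channels `ribbon` and `receptor`.
#' @examples
#' sc <- sampleScene(getPreset("control_12k"), nCells = 1, seed = 1)
#' st <- renderStack(sc, seed = 1)
#' st
#' @export
renderStack <- function(scene, psf = gaussianPSF(), photonScale = 150,
                        background = 3, readNoiseSD = 2, noise = TRUE,
                        seed = scene@seed) {
    stopifnot(is(scene, "GroundTruthScene"))
    if (photonScale <= 0) stop("photonScale must be > 0")
    if (background < 0 || readNoiseSD < 0)
        stop("noise parameters must be non-negative")
    shape <- scene@stackShape
    vs <- scene@voxelSize
    kern <- psfKernels(psf, vs)
    if (length(kern$kz) > shape[1] || length(kern$ky) > shape[2] ||
        length(kern$kx) > shape[3])
        stop("PSF kernel must be smaller than the stack")

    mkChannel <- function(df) {
        ind <- .paintSpheres(shape, vs, as.matrix(df[, c("z", "y", "x")]),
                             df$volume)
        .blur3d(ind * photonScale, kern) + background
    }
    lamR <- mkChannel(scene@ribbons)
    lamG <- mkChannel(scene@receptors)

    if (noise) {
        set.seed(as.integer(seed))
        addNoise <- function(lam) {
            n <- length(lam)
            v <- rpois(n, lam) + rnorm(n, 0, readNoiseSD)
            v <- pmin(pmax(round(v), 0), 65535)
            array(v, dim = dim(lam))
        }
        lamR <- addNoise(lamR)
        lamG <- addNoise(lamG)
    }
    dat <- array(0, dim = c(shape, 2L))
    dat[, , , 1] <- lamR
    dat[, , , 2] <- lamG
    new("SynapseStack", data = dat, channels = c("ribbon", "receptor"),
        voxelSize = vs)
}

#' Write / read a stack as 16-bit multi-page TIFF plus JSON metadata
#'
#' Pages are ordered channel-major then z (all z planes of channel 1, then
#' channel 2). Counts are stored as 16-bit samples; metadata (voxel size,
#' channel roles, shape) goes to `<prefix>_meta.json`.
#'
#' @param stack a [SynapseStack-class].
#' @param prefix file path prefix (no extension).
#' @return `writeStack` returns the TIFF path invisibly; `readStack`
#'   returns the [SynapseStack-class].
#' @examples
#' sc <- sampleScene(getPreset("control_12k"), nCells = 1, seed = 1)
#' st <- renderStack(sc, seed = 1)
#' pre <- file.path(tempdir(), "demo")
#' writeStack(st, pre)
#' st2 <- readStack(pre)
#' @export
writeStack <- function(stack, prefix) {
    stopifnot(is(stack, "SynapseStack"))
    d <- dim(stack@data)
    pages <- vector("list", d[1] * d[4])
    p <- 1L
    for (ch in seq_len(d[4])) for (z in seq_len(d[1])) {
        pages[[p]] <- pmin(pmax(stack@data[z, , , ch], 0), 65535) / 65535
        p <- p + 1L
    }
    tifPath <- paste0(prefix, ".tif")
    tiff::writeTIFF(pages, tifPath, bits.per.sample = 16L,
                    compression = "none")
    meta <- list(shape = as.integer(d[1:3]), channels = stack@channels,
                 voxel_size_um = as.numeric(stack@voxelSize))
    jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(tifPath)
}

#' @rdname writeStack
#' @export
readStack <- function(prefix) {
    meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                                simplifyVector = TRUE)
    pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
    shape <- as.integer(meta$shape)
    nch <- length(meta$channels)
    dat <- array(0, dim = c(shape, nch))
    p <- 1L
    for (ch in seq_len(nch)) for (z in seq_len(shape[1])) {
        dat[z, , , ch] <- round(pages[[p]] * 65535)
        p <- p + 1L
    }
    new("SynapseStack", data = dat, channels = as.character(meta$channels),
        voxelSize = setNames(as.numeric(meta$voxel_size_um), c("z", "y", "x")))
}

#' Write / read the ground-truth sidecar as JSON
#'
#' The sidecar records everything needed to score the pipeline against the
#' generated truth: cell table and axes, ribbon and receptor tables with
#' pairings and cluster labels, stack geometry, seed and preset name.
#'
#' @param scene a [GroundTruthScene-class].
#' @param path JSON file path.
#' @return `writeSceneTruth` returns `path` invisibly; `readSceneTruth`
#'   returns the reconstructed [GroundTruthScene-class].
#' @examples
#' sc <- sampleScene(getPreset("control_12k"), nCells = 1, seed = 1)
#' p <- file.path(tempdir(), "truth.json")
#' writeSceneTruth(sc, p)
#' sc2 <- readSceneTruth(p)
#' @export
writeSceneTruth <- function(scene, path) {
    stopifnot(is(scene, "GroundTruthScene"))
    obj <- list(cells = scene@cells,
                axes = lapply(scene@axes, function(a) unname(a)),
                ribbons = scene@ribbons, receptors = scene@receptors,
                voxel_size_um = as.numeric(scene@voxelSize),
                stack_shape = scene@stackShape, seed = scene@seed,
                preset = scene@preset,
                pairing_distance_um = scene@pairingDistance)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", matrix = "rowmajor")
    invisible(path)
}

#' @rdname writeSceneTruth
#' @export
readSceneTruth <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    fixdf <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
    rib <- fixdf(obj$ribbons)
    rib$receptor <- as.integer(rib$receptor)
    rib$paired <- as.logical(rib$paired)
    rec <- fixdf(obj$receptors)
    rec$ribbon <- as.integer(rec$ribbon)
    dn <- list(c("mp", "ch", "row"), c("z", "y", "x"))
    ax <- obj$axes
    axes <- if (is.array(ax) && length(dim(ax)) == 3) {
        ## identical per-cell matrices simplify to one (cell, row, col) array
        lapply(seq_len(dim(ax)[1]), function(i) {
            m <- matrix(as.numeric(ax[i, , ]), 3, 3)
            dimnames(m) <- dn
            m
        })
    } else {
        lapply(ax, function(a) {
            m <- matrix(as.numeric(t(a)), 3, 3, byrow = TRUE)
            dimnames(m) <- dn
            m
        })
    }
    new("GroundTruthScene", cells = fixdf(obj$cells), axes = axes,
        ribbons = rib, receptors = rec,
        voxelSize = setNames(as.numeric(obj$voxel_size_um), c("z", "y", "x")),
        stackShape = as.integer(obj$stack_shape),
        seed = as.integer(obj$seed), preset = as.character(obj$preset),
        pairingDistance = as.numeric(obj$pairing_distance_um))
}
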