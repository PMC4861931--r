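## Richardson-Lucy deconvolution.
##
## The maximum-likelihood estimate of the fluorophore distribution under a
## Poisson photon model with known PSF, obtained by the multiplicative
## fixed-point iteration
##     e_{k+1} = e_k * C'( obs / C(e_k) )
## where C is (normalized) convolution with the PSF and C' convolution with
## the mirrored PSF (identical for the symmetric Gaussian PSF used here).
## Border voxels use renormalized kernels, so a flat image is an exact
## fixed point and flux is conserved for interior sources.

#' Richardson-Lucy deconvolution of a 3D stack
#'
#' @param x non-negative 3D numeric array `(z, y, x)`, or a
#'   [SynapseStack-class] (every channel is deconvolved).
#' @param psf a [gaussianPSF()]; the separable kernels are normalized to
#'   sum 1.
#' @param nIterations number of iterations (>= 0; 0 returns the input;
#'   default 25).
#' @param voxelSize `(z, y, x)` voxel size in micrometres (taken from the
#'   stack when `x` is a [SynapseStack-class]).
#' @return Deconvolved array (or stack) of the same shape, non-negative.
#' @examples
#' img <- array(0, c(8, 16, 16)); img[4, 8, 8] <- 100
#' psf <- gaussianPSF()
#' blurred <- ribbonQuant:::.blur3d(img, ribbonQuant:::psfKernels(psf, c(0.3, 0.08, 0.08)))
#' sharp <- deconvolve(blurred, psf, nIterations = 10, voxelSize = c(0.3, 0.08, 0.08))
#' @export
deconvolve <- function(x, psf = gaussianPSF(), nIterations = 25L,
                       voxelSize = NULL) {
    if (is(x, "SynapseStack")) {
        out <- x
        for (ch in seq_along(x@channels))
            out@data[, , , ch] <- deconvolve(x@data[, , , ch, drop = TRUE],
                                             psf, nIterations, x@voxelSize)
        return(out)
    }
    stopifnot(is.array(x), length(dim(x)) == 3)
    if (is.null(voxelSize)) stop("voxelSize is required for array input")
    if (any(x < 0)) stop("input must be non-negative")
    if (nIterations < 0) stop("nIterations must be >= 0")
    kern <- psfKernels(psf, voxelSize)
    if (any(vapply(kern, sum, 0) == 0)) stop("PSF must have non-zero sum")
    est <- x
    eps <- 1e-12
    for (it in seq_len(nIterations)) {
        blur <- .blur3d(est, kern)
        ratio <- x / pmax(blur, eps)
        dim(ratio) <- dim(x)
        est <- est * .blur3d(ratio, kern)
        dim(est) <- dim(x)
    }
    est
}
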