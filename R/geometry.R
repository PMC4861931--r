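## projection onto anatomical axes and cross-stack centroid alignment.

#' Project 3D positions onto a cell's anatomical axes
#'
#' Translates positions to the soma centre and takes dot products with the
#' cell's modiolar-pillar and habenular-to-cuticular unit axes. This is a
#' rigid projection: pairwise distances among projected points never
#' exceed the 3D distances.
#'
#' @param positions numeric matrix `n x 3` in `(z, y, x)` micrometres.
#' @param center soma centre `(z, y, x)` micrometres.
#' @param axes `3 x 3` matrix with orthonormal rows `mp`, `ch` (a third
#'   row, if present, is ignored); columns in `(z, y, x)` order.
#' @return data.frame with `u` (modiolar-pillar) and `v`
#'   (habenular-to-cuticular) coordinates in micrometres.
#' @examples
#' ax <- rbind(mp = c(0, 1, 0), ch = c(1, 0, 0), row = c(0, 0, 1))
#' projectToAxes(rbind(c(3, 2, 0)), center = c(0, 0, 0), axes = ax)
#' @export
projectToAxes <- function(positions, center, axes) {
    positions <- rbind(positions)
    stopifnot(ncol(positions) == 3, length(center) == 3)
    a <- axes[c("mp", "ch"), , drop = FALSE]
    g <- a %*% t(a)
    if (max(abs(g - diag(2))) > 1e-8)
        stop("axes must be orthonormal unit vectors")
    rel <- sweep(positions, 2, center)
    data.frame(u = as.numeric(rel %*% a["mp", ]),
               v = as.numeric(rel %*% a["ch", ]))
}

#' Maximum-likelihood Gaussian fit of a 2D point set
#'
#' @param points numeric matrix or data.frame with two columns.
#' @return list with `mean` (length 2) and `cov` (2 x 2 MLE covariance,
#'   i.e. divided by n).
#' @examples
#' fitGaussianMLE(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)))
#' @export
fitGaussianMLE <- function(points) {
    p <- as.matrix(points)
    if (nrow(p) < 3) stop("at least 3 points are required")
    mu <- colMeans(p)
    centered <- sweep(p, 2, mu)
    list(mean = mu, cov = crossprod(centered) / nrow(p))
}

#' Align per-stack synapse ensembles by their centroids
#'
#' Translates each stack's paired-synapse point cloud so its centroid (the
#' mean of a single-Gaussian ML fit) lands at the origin, then pools the
#' clouds with stack provenance retained. Alignment is a pure translation
#' and therefore preserves within-stack pairwise distances exactly. Stacks
#' with fewer than `minPairs` paired synapses are excluded with a warning.
#'
#' @param stackPoints named list of data.frames, one per stack, each with
#'   columns `u`, `v`, `volume` and `pair_id`.
#' @param minPairs minimum paired synapses per stack (>= 3, the minimum
#'   for a Gaussian fit).
#' @return An [EnsemblePoints-class].
#' @examples
#' s1 <- data.frame(u = c(-1, 0, 1), v = c(0, 1, -1), volume = 0.1,
#'                  pair_id = 1:3)
#' alignEnsemble(list(a = s1, b = transform(s1, u = u + 5)))
#' @export
alignEnsemble <- function(stackPoints, minPairs = 3L) {
    stopifnot(is.list(stackPoints), length(stackPoints) >= 1, minPairs >= 3)
    if (is.null(names(stackPoints)))
        names(stackPoints) <- paste0("stack", seq_along(stackPoints))
    pooled <- list()
    for (nm in names(stackPoints)) {
        p <- stackPoints[[nm]]
        if (nrow(p) < minPairs) {
            warning("stack '", nm, "' has fewer than ", minPairs,
                    " paired synapses and was excluded from the ensemble")
            next
        }
        fit <- fitGaussianMLE(p[, c("u", "v")])
        pooled[[nm]] <- data.frame(u = p$u - fit$mean[1],
                                   v = p$v - fit$mean[2],
                                   volume = p$volume, stack_id = nm,
                                   pair_id = p$pair_id)
    }
    if (!length(pooled))
        stop("no stack has enough paired synapses to align")
    pts <- do.call(rbind, pooled)
    rownames(pts) <- NULL
    new("EnsemblePoints", points = pts)
}
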