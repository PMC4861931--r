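## S4 classes for the ribbon-synapse quantification pipeline.
## Coordinate convention used throughout: axis order (z, y, x), physical
## units in micrometres, voxel indices 0-based, and the physical position of
## a voxel is (index + 0.5) * voxel_size.

#' Simulation preset for one experimental condition
#'
#' Bundles the per-IHC synapse count means, the ribbon/receptor volume
#' mixtures and the positional-cluster geometry that define one condition x
#' frequency-region combination of the noise-exposure study design. The
#' packaged presets (see [listPresets()]) carry the published per-IHC
#' paired/orphan ribbon means for each condition.
#'
#' @slot name preset label, e.g. `"control_12k"`.
#' @slot meanTotal mean total ribbons per IHC.
#' @slot meanPaired mean paired ribbons per IHC.
#' @slot meanOrphanRibbons mean orphan (unpaired) ribbons per IHC.
#' @slot orphanReceptorRate mean orphan receptor patches per IHC.
#' @slot volumeMixture numeric matrix with columns `weight`, `meanlog`,
#'   `sdlog`: log-normal mixture (micrometre^3) for ribbon volumes, one row
#'   per sub-population (small/medium/large).
#' @slot receptorVolumeMixture same structure for receptor patch volumes.
#' @slot clusterSeparation offset (micrometres) between the modiolar and
#'   pillar positional clusters along the modiolar-pillar axis.
#' @slot clusterMix fraction of synapses in the modiolar cluster.
#' @slot volumePositionCor rank coupling (between -1 and 1) of ribbon
#'   volume with position along the habenular-to-cuticular axis; positive
#'   values place large ribbons towards the cuticular plate.
#' @exportClass ConditionPreset
setClass("ConditionPreset",
    representation(
        name = "character",
        meanTotal = "numeric",
        meanPaired = "numeric",
        meanOrphanRibbons = "numeric",
        orphanReceptorRate = "numeric",
        volumeMixture = "matrix",
        receptorVolumeMixture = "matrix",
        clusterSeparation = "numeric",
        clusterMix = "numeric",
        volumePositionCor = "numeric"
    )
)

.validMixture <- function(m, what) {
    msgs <- character()
    need <- c("weight", "meanlog", "sdlog")
    if (!all(need %in% colnames(m)))
        return(sprintf("%s must have columns weight, meanlog, sdlog", what))
    if (abs(sum(m[, "weight"]) - 1) > 1e-9)
        msgs <- c(msgs, sprintf("%s weights must sum to 1", what))
    if (any(m[, "weight"] < 0))
        msgs <- c(msgs, sprintf("%s weights must be non-negative", what))
    if (any(m[, "sdlog"] <= 0))
        msgs <- c(msgs, sprintf("%s sdlog must be > 0", what))
    msgs
}

setValidity("ConditionPreset", function(object) {
    msgs <- character()
    if (abs(object@meanPaired + object@meanOrphanRibbons - object@meanTotal) > 1e-9)
        msgs <- c(msgs, "meanPaired + meanOrphanRibbons must equal meanTotal")
    if (object@meanTotal < 0 || object@meanPaired < 0 ||
        object@meanOrphanRibbons < 0 || object@orphanReceptorRate < 0)
        msgs <- c(msgs, "count means must be non-negative")
    msgs <- c(msgs, .validMixture(object@volumeMixture, "volumeMixture"),
              .validMixture(object@receptorVolumeMixture, "receptorVolumeMixture"))
    if (object@clusterSeparation < 0)
        msgs <- c(msgs, "clusterSeparation must be non-negative")
    if (object@clusterMix < 0 || object@clusterMix > 1)
        msgs <- c(msgs, "clusterMix must lie in [0, 1]")
    if (object@volumePositionCor < -1 || object@volumePositionCor > 1)
        msgs <- c(msgs, "volumePositionCor must lie in [-1, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Ground-truth synthetic IHC scene
#'
#' A simulated row of inner hair cells with known synapse positions,
#' volumes, ribbon-receptor pairings and positional cluster labels, plus the
#' stack geometry needed to render it. This is the "truth sidecar" the
#' analysis pipeline is validated against.
#'
#' @slot cells data.frame with one row per cell: `cell_id`, soma center
#'   `cz`, `cy`, `cx` (micrometres) and ellipsoid semi-axes `az`, `ay`, `ax`.
#' @slot axes list (one 3x3 matrix per cell) of orthonormal unit axis
#'   vectors as rows `mp` (modiolar-pillar), `ch` (habenular-to-cuticular)
#'   and `row` (third axis, along the cell row), columns in (z, y, x) order.
#' @slot ribbons data.frame: `cell`, position `z`, `y`, `x` (micrometres),
#'   `volume` (micrometre^3), `cluster` (`"modiolar"`/`"pillar"`), `paired`
#'   (logical), `receptor` (row index into `receptors`, NA for orphans).
#' @slot receptors data.frame: `cell`, `z`, `y`, `x`, `volume`, `ribbon`
#'   (row index into `ribbons`, NA for orphan receptors).
#' @slot voxelSize named numeric `(z, y, x)` voxel size in micrometres.
#' @slot stackShape integer `(z, y, x)` stack dimensions in voxels.
#' @slot seed integer seed the scene was drawn from.
#' @slot preset name of the generating preset.
#' @slot pairingDistance maximum ribbon-receptor separation (micrometres)
#'   used when placing paired receptors.
#' @exportClass GroundTruthScene
setClass("GroundTruthScene",
    representation(
        cells = "data.frame",
        axes = "list",
        ribbons = "data.frame",
        receptors = "data.frame",
        voxelSize = "numeric",
        stackShape = "integer",
        seed = "integer",
        preset = "character",
        pairingDistance = "numeric"
    )
)

setValidity("GroundTruthScene", function(object) {
    msgs <- character()
    bounds <- object@stackShape * object@voxelSize
    inb <- function(df) {
        nrow(df) == 0 ||
            (all(df$z >= 0 & df$z <= bounds[1]) &&
             all(df$y >= 0 & df$y <= bounds[2]) &&
             all(df$x >= 0 & df$x <= bounds[3]))
    }
    if (!inb(object@ribbons) || !inb(object@receptors))
        msgs <- c(msgs, "synapse positions must lie inside the stack bounds")
    rib <- object@ribbons; rec <- object@receptors
    pr <- which(!is.na(rib$receptor))
    if (length(pr)) {
        if (anyDuplicated(rib$receptor[pr]))
            msgs <- c(msgs, "a receptor is referenced by more than one ribbon")
        back <- rec$ribbon[rib$receptor[pr]]
        if (!identical(as.integer(back), as.integer(pr)))
            msgs <- c(msgs, "ribbon/receptor pairing is not mutual")
        d <- sqrt((rib$z[pr] - rec$z[rib$receptor[pr]])^2 +
                  (rib$y[pr] - rec$y[rib$receptor[pr]])^2 +
                  (rib$x[pr] - rec$x[rib$receptor[pr]])^2)
        if (any(d > object@pairingDistance + 1e-9))
            msgs <- c(msgs, "paired separation exceeds the generation pairing distance")
    }
    for (A in object@axes) {
        g <- A %*% t(A)
        if (max(abs(g - diag(3))) > 1e-8) {
            msgs <- c(msgs, "cell axes must be orthonormal")
            break
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Multi-channel 3D image stack with physical metadata
#'
#' @slot data 4D numeric array, dim `(z, y, x, channel)`, photon-count
#'   scale.
#' @slot channels character vector of channel roles (subset of `"ribbon"`,
#'   `"receptor"`, `"cell_body"`), one per channel.
#' @slot voxelSize named numeric `(z, y, x)` voxel size in micrometres.
#' @exportClass SynapseStack
setClass("SynapseStack",
    representation(data = "array", channels = "character", voxelSize = "numeric")
)

setValidity("SynapseStack", function(object) {
    msgs <- character()
    if (length(dim(object@data)) != 4)
        msgs <- c(msgs, "data must be a 4D (z, y, x, channel) array")
    else if (dim(object@data)[4] != length(object@channels))
        msgs <- c(msgs, "channels must name every channel plane")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
        msgs <- c(msgs, "voxelSize must be 3 strictly positive values (z, y, x)")
    if (length(msgs)) msgs else TRUE
})

#' Result of ribbon-receptor pairing
#'
#' Holds the input component tables together with the greedy
#' mutual-nearest-neighbor matching: every component is either in exactly
#' one pair or an orphan.
#'
#' @slot ribbons component data.frame for the ribbon channel (see
#'   [segmentComponents()]).
#' @slot receptors component data.frame for the receptor channel.
#' @slot pairs data.frame `ribbon_id`, `receptor_id`, `distance`
#'   (micrometres, centroid-to-centroid).
#' @slot maxPairDistance pairing distance threshold in micrometres.
#' @exportClass PairingResult
setClass("PairingResult",
    representation(ribbons = "data.frame", receptors = "data.frame",
                   pairs = "data.frame", maxPairDistance = "numeric")
)

setValidity("PairingResult", function(object) {
    msgs <- character()
    p <- object@pairs
    if (nrow(p)) {
        if (anyDuplicated(p$ribbon_id) || anyDuplicated(p$receptor_id))
            msgs <- c(msgs, "each component may appear in at most one pair")
        if (!all(p$ribbon_id %in% object@ribbons$id) ||
            !all(p$receptor_id %in% object@receptors$id))
            msgs <- c(msgs, "pair ids must reference input components")
        if (any(p$distance > object@maxPairDistance + 1e-9))
            msgs <- c(msgs, "pair distance exceeds maxPairDistance")
    }
    if (length(msgs)) msgs else TRUE
})

#' Centroid-aligned ensemble of paired synapse positions
#'
#' 2D projections (u along the modiolar-pillar axis, v along the
#' habenular-to-cuticular axis) of paired synapses pooled across stacks
#' after per-stack centroid alignment: each stack's point centroid is
#' translated to the origin, so stacks are comparable.
#'
#' @slot points data.frame with columns `u`, `v` (micrometres), `volume`
#'   (micrometre^3), `stack_id`, `pair_id`.
#' @exportClass EnsemblePoints
setClass("EnsemblePoints", representation(points = "data.frame"))

setValidity("EnsemblePoints", function(object) {
    p <- object@points
    need <- c("u", "v", "volume", "stack_id", "pair_id")
    if (!all(need %in% names(p)))
        return("points must have columns u, v, volume, stack_id, pair_id")
    if (nrow(p)) {
        cu <- tapply(p$u, p$stack_id, mean)
        cv <- tapply(p$v, p$stack_id, mean)
        if (max(abs(c(cu, cv))) > 1e-9)
            return("per-stack centroids must sit at the origin after alignment")
    }
    TRUE
})

#' Gaussian-mixture clustering of synapse positions
#'
#' Full-covariance Gaussian-mixture EM fit with BIC model selection over
#' candidate component counts.
#'
#' @slot k selected number of mixture components.
#' @slot weights mixture weights (length `k`, sum 1).
#' @slot means `k x 2` matrix of component means (u, v).
#' @slot covariances `2 x 2 x k` array of component covariances.
#' @slot responsibilities `n x k` posterior membership matrix (rows sum 1).
#' @slot labels hard assignment per point (argmax responsibility).
#' @slot logLik final log-likelihood of the selected model.
#' @slot logLikTrace per-iteration log-likelihood of the winning EM run
#'   (non-decreasing).
#' @slot bicByK named numeric, BIC = -2 logL + p log(n) per candidate k
#'   (lower is better).
#' @slot converged logical, EM tolerance reached for the selected model.
#' @exportClass ClusterResult
setClass("ClusterResult",
    representation(k = "integer", weights = "numeric", means = "matrix",
                   covariances = "array", responsibilities = "matrix",
                   labels = "integer", logLik = "numeric",
                   logLikTrace = "numeric", bicByK = "numeric",
                   converged = "logical")
)

setValidity("ClusterResult", function(object) {
    msgs <- character()
    if (abs(sum(object@weights) - 1) > 1e-6)
        msgs <- c(msgs, "weights must sum to 1")
    if (nrow(object@responsibilities) &&
        max(abs(rowSums(object@responsibilities) - 1)) > 1e-6)
        msgs <- c(msgs, "responsibilities must sum to 1 per point")
    for (j in seq_len(object@k)) {
        S <- object@covariances[, , j]
        if (max(abs(S - t(S))) > 1e-8 || any(eigen(S, symmetric = TRUE,
                                                   only.values = TRUE)$values <= 0)) {
            msgs <- c(msgs, "covariances must be symmetric positive-definite")
            break
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Acoustic exposure dose
#'
#' A noise exposure characterized by its sound pressure level and duration,
#' used for equal-intensity energy comparisons between exposure protocols.
#'
#' @slot level sound pressure level in dB SPL.
#' @slot duration exposure duration in minutes.
#' @exportClass ExposureDose
setClass("ExposureDose", representation(level = "numeric", duration = "numeric"))

setValidity("ExposureDose", function(object) {
    if (length(object@duration) != 1 || object@duration <= 0)
        return("duration must be a single positive number of minutes")
    if (length(object@level) != 1 || !is.finite(object@level))
        return("level must be a single finite dB SPL value")
    TRUE
})
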