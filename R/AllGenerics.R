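## Generics and accessors. Slot access from user code goes through these.

#' @name accessors
#' @title Accessors for ribbonQuant classes
#' @description Small accessor generics: `ribbons()`, `receptors()`,
#'   `synapsePairs()`, `orphanRibbons()`, `orphanReceptors()`,
#'   `voxelSize()`, `stackShape()`, `channelRoles()`, `cellTable()`,
#'   `cellAxes()`, `ensemblePoints()`, `clusterBIC()`, `clusterLabels()`.
#' @param object an object of the documented class.
#' @return The corresponding slot content (data.frame, numeric vector, ...).
NULL

#' @rdname accessors
#' @export
setGeneric("ribbons", function(object) standardGeneric("ribbons"))
#' @rdname accessors
#' @export
setGeneric("receptors", function(object) standardGeneric("receptors"))
#' @rdname accessors
#' @export
setGeneric("synapsePairs", function(object) standardGeneric("synapsePairs"))
#' @rdname accessors
#' @export
setGeneric("orphanRibbons", function(object) standardGeneric("orphanRibbons"))
#' @rdname accessors
#' @export
setGeneric("orphanReceptors", function(object) standardGeneric("orphanReceptors"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("stackShape", function(object) standardGeneric("stackShape"))
#' @rdname accessors
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))
#' @rdname accessors
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))
#' @rdname accessors
#' @export
setGeneric("cellAxes", function(object) standardGeneric("cellAxes"))
#' @rdname accessors
#' @export
setGeneric("ensemblePoints", function(object) standardGeneric("ensemblePoints"))
#' @rdname accessors
#' @export
setGeneric("clusterBIC", function(object) standardGeneric("clusterBIC"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("channelData", function(object, role) standardGeneric("channelData"))

setMethod("ribbons", "GroundTruthScene", function(object) object@ribbons)
setMethod("receptors", "GroundTruthScene", function(object) object@receptors)
setMethod("cellTable", "GroundTruthScene", function(object) object@cells)
setMethod("cellAxes", "GroundTruthScene", function(object) object@axes)
setMethod("voxelSize", "GroundTruthScene", function(object) object@voxelSize)
setMethod("stackShape", "GroundTruthScene", function(object) object@stackShape)

setMethod("voxelSize", "SynapseStack", function(object) object@voxelSize)
setMethod("stackShape", "SynapseStack",
          function(object) as.integer(dim(object@data)[1:3]))
setMethod("channelRoles", "SynapseStack", function(object) object@channels)
setMethod("channelData", "SynapseStack", function(object, role) {
    i <- match(role, object@channels)
    if (is.na(i)) stop("no channel with role '", role, "'")
    object@data[, , , i, drop = TRUE]
})

setMethod("ribbons", "PairingResult", function(object) object@ribbons)
setMethod("receptors", "PairingResult", function(object) object@receptors)
setMethod("synapsePairs", "PairingResult", function(object) object@pairs)
setMethod("orphanRibbons", "PairingResult", function(object)
    object@ribbons[!(object@ribbons$id %in% object@pairs$ribbon_id), , drop = FALSE])
setMethod("orphanReceptors", "PairingResult", function(object)
    object@receptors[!(object@receptors$id %in% object@pairs$receptor_id), , drop = FALSE])

setMethod("ensemblePoints", "EnsemblePoints", function(object) object@points)

setMethod("clusterBIC", "ClusterResult", function(object) object@bicByK)
setMethod("clusterLabels", "ClusterResult", function(object) object@labels)

setMethod("show", "ConditionPreset", function(object) {
    cat("ConditionPreset '", object@name, "'\n", sep = "")
    cat(sprintf("  ribbons/IHC: total %.2f = paired %.2f + orphan %.2f; orphan receptors %.2f\n",
                object@meanTotal, object@meanPaired, object@meanOrphanRibbons,
                object@orphanReceptorRate))
    cat(sprintf("  clusters: separation %.2f um, modiolar fraction %.2f\n",
                object@clusterSeparation, object@clusterMix))
    cat(sprintf("  ribbon volume mixture (weight | meanlog | sdlog):\n"))
    for (i in seq_len(nrow(object@volumeMixture)))
        cat(sprintf("    %.2f | %.3f | %.3f\n",
                    object@volumeMixture[i, "weight"],
                    object@volumeMixture[i, "meanlog"],
                    object@volumeMixture[i, "sdlog"]))
    invisible(NULL)
})

setMethod("show", "GroundTruthScene", function(object) {
    cat("GroundTruthScene (preset '", object@preset, "', seed ",
        object@seed, ")\n", sep = "")
    cat(sprintf("  %d cells, %d ribbons (%d paired), %d receptors\n",
                nrow(object@cells), nrow(object@ribbons),
                sum(object@ribbons$paired), nrow(object@receptors)))
    cat(sprintf("  stack %s voxels at (%s) um\n",
                paste(object@stackShape, collapse = " x "),
                paste(format(object@voxelSize), collapse = ", ")))
    invisible(NULL)
})

setMethod("show", "SynapseStack", function(object) {
    d <- dim(object@data)
    cat(sprintf("SynapseStack %d x %d x %d (z,y,x), channels: %s\n",
                d[1], d[2], d[3], paste(object@channels, collapse = ", ")))
    cat(sprintf("  voxel size (%s) um\n",
                paste(format(object@voxelSize), collapse = ", ")))
    invisible(NULL)
})

setMethod("show", "PairingResult", function(object) {
    cat(sprintf("PairingResult: %d pairs, %d orphan ribbons, %d orphan receptors (max distance %.2f um)\n",
                nrow(object@pairs), nrow(orphanRibbons(object)),
                nrow(orphanReceptors(object)), object@maxPairDistance))
    invisible(NULL)
})

setMethod("show", "EnsemblePoints", function(object) {
    p <- object@points
    cat(sprintf("EnsemblePoints: %d paired synapses from %d stacks\n",
                nrow(p), length(unique(p$stack_id))))
    invisible(NULL)
})

setMethod("show", "ClusterResult", function(object) {
    cat(sprintf("ClusterResult: k = %d selected by BIC (logLik %.3f, %s)\n",
                object@k, object@logLik,
                if (object@converged) "converged" else "not converged"))
    b <- object@bicByK
    cat("  BIC by k:", paste(sprintf("%s=%.2f", names(b), b), collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "ExposureDose", function(object) {
    cat(sprintf("ExposureDose: %.1f dB SPL for %.0f min\n",
                object@level, object@duration))
    invisible(NULL)
})
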