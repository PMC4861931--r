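## ribbon-receptor pairing, per-cell assignment and count summaries.

#' Pair ribbon and receptor components by proximity
#'
#' Greedy mutual-nearest-neighbor matching: the globally closest unmatched
#' ribbon-receptor pair with centroid distance at most `maxPairDistance`
#' is paired, repeatedly, until no admissible pair remains. Everything left
#' over is an orphan. Distance ties are broken by the lower `(ribbon_id,
#' receptor_id)` lexicographically, so the matching is deterministic.
#'
#' @param ribbons,receptors component data.frames from
#'   [segmentComponents()] (need `id`, `cz`, `cy`, `cx`).
#' @param maxPairDistance pairing distance threshold, micrometres (> 0).
#'   The default 1.0 reflects the sub-micron scale of an apposed
#'   ribbon/receptor-patch pair.
#' @return A [PairingResult-class].
#' @examples
#' rb <- data.frame(id = 1, cz = 0, cy = 0, cx = 0)
#' rc <- data.frame(id = 1:2, cz = 0, cy = c(0.3, 5), cx = 0)
#' pairComponents(rb, rc)
#' @export
pairComponents <- function(ribbons, receptors, maxPairDistance = 1.0) {
    if (maxPairDistance <= 0) stop("maxPairDistance must be > 0")
    emptyPairs <- data.frame(ribbon_id = integer(0), receptor_id = integer(0),
                             distance = numeric(0))
    nr <- nrow(ribbons); nc <- nrow(receptors)
    if (nr == 0 || nc == 0) {
        return(new("PairingResult", ribbons = ribbons, receptors = receptors,
                   pairs = emptyPairs, maxPairDistance = maxPairDistance))
    }
    ribbons <- ribbons[order(ribbons$id), , drop = FALSE]
    receptors <- receptors[order(receptors$id), , drop = FALSE]
    D <- sqrt(outer(ribbons$cz, receptors$cz, "-")^2 +
              outer(ribbons$cy, receptors$cy, "-")^2 +
              outer(ribbons$cx, receptors$cx, "-")^2)
    D[D > maxPairDistance] <- Inf
    pr <- integer(0); pc <- integer(0); pd <- numeric(0)
    while (any(is.finite(D))) {
        ## which.min on a matrix is column-major, i.e. ties resolve to the
        ## lowest receptor id then lowest ribbon id; rows/cols are sorted
        ## by id, so the tie-break is the documented lexicographic one
        best <- arrayInd(which.min(D), dim(D))
        i <- best[1]; j <- best[2]
        pr <- c(pr, i); pc <- c(pc, j); pd <- c(pd, D[i, j])
        D[i, ] <- Inf
        D[, j] <- Inf
    }
    o <- order(pr)
    pairs <- data.frame(ribbon_id = ribbons$id[pr[o]],
                        receptor_id = receptors$id[pc[o]],
                        distance = pd[o])
    new("PairingResult", ribbons = ribbons, receptors = receptors,
        pairs = pairs, maxPairDistance = maxPairDistance)
}

#' Assign components and pairs to inner hair cells
#'
#' Each component is assigned to the nearest soma centre; components
#' farther than `maxSomaDistance` from every soma are flagged unassigned
#' and excluded from per-cell counts. A pair is counted in its ribbon's
#' cell.
#'
#' @param pairing a [PairingResult-class].
#' @param cells data.frame with `cell_id` and soma centres `cz`, `cy`,
#'   `cx` (micrometres), e.g. `cellTable(scene)` renamed, or the `cells`
#'   slot of a scene (`cz/cy/cx` columns are used).
#' @param maxSomaDistance assignment cutoff, micrometres.
#' @return list with `ribbonCell` / `receptorCell` (cell id per component,
#'   NA if unassigned) and `perCell`: data.frame of per-cell counts
#'   `cell_id`, `total_ribbons`, `paired`, `orphan_ribbons`,
#'   `orphan_receptors` (total = paired + orphan by construction).
#' @examples
#' rb <- data.frame(id = 1, cz = 0, cy = 0, cx = 0)
#' rc <- data.frame(id = 1, cz = 0, cy = 0.3, cx = 0)
#' pr <- pairComponents(rb, rc)
#' assignToCells(pr, data.frame(cell_id = 1, cz = 0, cy = 0, cx = 0))$perCell
#' @export
assignToCells <- function(pairing, cells, maxSomaDistance = 6.0) {
    stopifnot(is(pairing, "PairingResult"), nrow(cells) >= 1)
    nearest <- function(df) {
        if (nrow(df) == 0) return(integer(0))
        vapply(seq_len(nrow(df)), function(i) {
            d2 <- (cells$cz - df$cz[i])^2 + (cells$cy - df$cy[i])^2 +
                (cells$cx - df$cx[i])^2
            j <- which.min(d2)
            if (sqrt(d2[j]) > maxSomaDistance) NA_integer_
            else as.integer(cells$cell_id[j])
        }, integer(1))
    }
    rib <- pairing@ribbons; rec <- pairing@receptors
    ribCell <- nearest(rib); recCell <- nearest(rec)
    pairedRib <- rib$id %in% pairing@pairs$ribbon_id
    pairedRec <- rec$id %in% pairing@pairs$receptor_id
    perCell <- data.frame(cell_id = cells$cell_id)
    cnt <- function(cellIds, sel) {
        vapply(cells$cell_id, function(cid)
            sum(!is.na(cellIds) & cellIds == cid & sel), numeric(1))
    }
    perCell$total_ribbons <- cnt(ribCell, rep(TRUE, length(ribCell)))
    perCell$paired <- cnt(ribCell, pairedRib)
    perCell$orphan_ribbons <- cnt(ribCell, !pairedRib)
    perCell$orphan_receptors <- cnt(recCell, !pairedRec)
    list(ribbonCell = ribCell, receptorCell = recCell, perCell = perCell)
}

#' Summarize per-cell synapse counts by condition and frequency
#'
#' @param perCell data.frame of per-cell counts (as from
#'   [assignToCells()]), with added `condition` and `frequency` columns
#'   (recycled scalars allowed).
#' @return data.frame with one row per condition x frequency: number of
#'   cells and mean and s.e.m. (sample SD / sqrt(n)) of total, paired and
#'   orphan ribbons per IHC; mean total equals mean paired + mean orphan by
#'   construction.
#' @examples
#' pc <- data.frame(total_ribbons = c(4, 5), paired = c(3, 4),
#'                  orphan_ribbons = c(1, 1), orphan_receptors = 0,
#'                  condition = "control", frequency = "12k")
#' countSummary(pc)
#' @export
countSummary <- function(perCell) {
    stopifnot(nrow(perCell) >= 1,
              all(c("total_ribbons", "paired", "orphan_ribbons") %in%
                  names(perCell)))
    if (is.null(perCell$condition)) perCell$condition <- "all"
    if (is.null(perCell$frequency)) perCell$frequency <- "all"
    sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    agg <- function(sub) {
        data.frame(condition = sub$condition[1], frequency = sub$frequency[1],
                   n_cells = nrow(sub),
                   total_mean = mean(sub$total_ribbons),
                   total_sem = sem(sub$total_ribbons),
                   paired_mean = mean(sub$paired),
                   paired_sem = sem(sub$paired),
                   orphan_mean = mean(sub$orphan_ribbons),
                   orphan_sem = sem(sub$orphan_ribbons))
    }
    groups <- split(perCell, interaction(perCell$condition, perCell$frequency,
                                         drop = TRUE))
    out <- do.call(rbind, lapply(groups, agg))
    rownames(out) <- NULL
    out
}
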