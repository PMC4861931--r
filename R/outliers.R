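## positional mapping of volumetric outliers.

#' Flag volumetric outliers by position
#'
#' A point is an outlier iff its volume strictly exceeds the empirical
#' `q`-quantile of the pooled volumes (linear-interpolation quantile,
#' R type 7). Returns the per-point flags together with the mean (u, v)
#' position of the outliers and non-outliers, which is how positional
#' enrichment of large components (e.g. large ribbons sitting towards the
#' cuticular plate) is summarized.
#'
#' @param x an [EnsemblePoints-class] or a data.frame with `u`, `v`,
#'   `volume`.
#' @param q quantile in (0, 1); 0.9 flags the largest decile.
#' @return list with `points` (input plus logical `outlier` column),
#'   `threshold` (the volume quantile) and `summary` (data.frame with mean
#'   u/v and n per group).
#' @examples
#' set.seed(1)
#' d <- data.frame(u = rnorm(50), v = rnorm(50), volume = rlnorm(50))
#' quantileOutlierMap(d, q = 0.9)$summary
#' @export
quantileOutlierMap <- function(x, q = 0.9) {
    if (is(x, "EnsemblePoints")) x <- x@points
    if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
    if (nrow(x) < 10)
        stop("fewer than 10 points: too few for a stable quantile")
    thr <- quantile(x$volume, q, type = 7, names = FALSE)
    x$outlier <- x$volume > thr
    grp <- function(sel, label) {
        data.frame(group = label, n = sum(sel),
                   mean_u = if (any(sel)) mean(x$u[sel]) else NA_real_,
                   mean_v = if (any(sel)) mean(x$v[sel]) else NA_real_)
    }
    list(points = x, threshold = thr,
         summary = rbind(grp(x$outlier, "outlier"),
                         grp(!x$outlier, "non_outlier")))
}
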