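## distributional statistics on volumes and counts, and the acoustic
## energy-dose utility.

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration of the U distribution when the combined sample size
#' is at most 12 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction. When every value in both
#' samples is identical the test is degenerate and p = 1 is returned with
#' a warning.
#'
#' @param a,b numeric samples (non-empty).
#' @return list with `statistic` (the Mann-Whitney U of sample `a`),
#'   `p.value` and `method`.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))
#' @export
rankSumTest <- function(a, b) {
    stopifnot(length(a) >= 1, length(b) >= 1)
    if (length(unique(c(a, b))) == 1) {
        warning("all values identical in both samples; returning p = 1")
        return(list(statistic = length(a) * length(b) / 2, p.value = 1,
                    method = "degenerate"))
    }
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- (length(a) + length(b) <= 12) && !ties
    wt <- suppressWarnings(
        wilcox.test(a, b, exact = exact, correct = !exact,
                    alternative = "two.sided"))
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         method = if (exact) "exact" else "normal approximation")
}

#' Compare per-cell counts against a baseline condition
#'
#' Welch two-sample t-test of every non-baseline condition against the
#' baseline, with Bonferroni adjustment (raw p times the number of
#' comparisons, capped at 1).
#'
#' @param counts data.frame with columns `condition` and `value` (one row
#'   per cell).
#' @param baseline name of the baseline condition.
#' @return data.frame with `condition`, `n`, `baseline_n`, `mean_diff`,
#'   `t`, `p_raw` and `p_adjusted`.
#' @examples
#' d <- data.frame(condition = rep(c("ctl", "noise"), each = 5),
#'                 value = c(17, 18, 16, 17, 18, 9, 10, 9, 8, 9))
#' compareCounts(d, baseline = "ctl")
#' @export
compareCounts <- function(counts, baseline) {
    stopifnot(all(c("condition", "value") %in% names(counts)),
              baseline %in% counts$condition)
    base <- counts$value[counts$condition == baseline]
    if (length(base) < 2) stop("need at least 2 cells in the baseline")
    others <- setdiff(unique(counts$condition), baseline)
    if (!length(others)) stop("no condition to compare against the baseline")
    rows <- lapply(others, function(cnd) {
        v <- counts$value[counts$condition == cnd]
        if (length(v) < 2) stop("need at least 2 cells in condition '", cnd, "'")
        if (var(v) == 0 && var(base) == 0)
            stop("zero variance in both '", cnd, "' and the baseline; ",
                 "the t statistic is undefined")
        tt <- t.test(v, base, var.equal = FALSE)
        data.frame(condition = cnd, n = length(v), baseline_n = length(base),
                   mean_diff = mean(v) - mean(base),
                   t = unname(tt$statistic), p_raw = tt$p.value)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- pmin(out$p_raw * length(others), 1)
    out
}

#' Distributional summary of component volumes
#'
#' Mean, unbiased sample variance, deciles and a Gaussian kernel density
#' estimate (Silverman's rule-of-thumb bandwidth by default, recorded in
#' the output) of a volume sample. Constant samples are reported as a
#' point mass with zero variance and no KDE.
#'
#' @param volumes numeric vector of volumes (micrometre^3), `n >= 10`.
#' @param condition,frequency labels carried through to the output.
#' @param bw bandwidth rule or value for [stats::density()].
#' @param gridN number of KDE grid points.
#' @return list with `condition`, `frequency`, `n`, `mean`, `variance`,
#'   `quantiles` (0.1 ... 0.9), `pointMass` flag and `kde` (list with `x`,
#'   `y`, `bw`; the density integrates to 1 on its grid, which extends 4
#'   bandwidths beyond the data).
#' @examples
#' volumeSummary(rlnorm(100, log(0.1), 0.4))$mean
#' @export
volumeSummary <- function(volumes, condition = "all", frequency = "all",
                          bw = "nrd0", gridN = 512L) {
    if (length(volumes) < 10)
        stop("fewer than 10 volumes: refusing to summarize")
    qs <- quantile(volumes, probs = seq(0.1, 0.9, by = 0.1), type = 7)
    if (is.unsorted(qs)) stop("internal error: quantiles must be non-decreasing")
    pointMass <- length(unique(volumes)) == 1
    kde <- NULL
    if (!pointMass) {
        d <- density(volumes, bw = bw, kernel = "gaussian", n = gridN,
                     cut = 4)
        kde <- list(x = d$x, y = d$y, bw = d$bw)
    }
    list(condition = condition, frequency = frequency,
         n = length(volumes), mean = mean(volumes),
         variance = if (pointMass) 0 else var(volumes),
         quantiles = qs, pointMass = pointMass, kde = kde)
}

#' Construct an acoustic exposure dose
#'
#' @param level sound pressure level, dB SPL.
#' @param duration exposure duration, minutes (> 0).
#' @return An [ExposureDose-class].
#' @examples
#' exposureDose(105, 30)
#' @export
exposureDose <- function(level, duration) {
    new("ExposureDose", level = as.numeric(level),
        duration = as.numeric(duration))
}

#' Acoustic energy ratio of two exposure doses
#'
#' Under the equal-intensity assumption (energy proportional to duration
#' times 10^(level/10)), the fold ratio of the energy delivered by dose a
#' relative to dose b:
#' ratio = (duration_a * 10^(level_a/10)) / (duration_b * 10^(level_b/10)).
#' For example, 30 min at 105 dB SPL carries about 0.79 of the energy of
#' 120 min at 100 dB SPL.
#'
#' @param a,b [ExposureDose-class] objects (see [exposureDose()]).
#' @return The fold ratio (a relative to b); `energyRatio(a, b) *
#'   energyRatio(b, a)` is exactly 1.
#' @examples
#' energyRatio(exposureDose(105, 30), exposureDose(100, 120))
#' @export
energyRatio <- function(a, b) {
    stopifnot(is(a, "ExposureDose"), is(b, "ExposureDose"))
    validObject(a); validObject(b)
    (a@duration * 10^(a@level / 10)) / (b@duration * 10^(b@level / 10))
}
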