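#' Photoactivation ratio of a cell
#'
#' The ratio of activated (red) to unactivated (green) Dendra2
#' fluorescence, the axis on which photoactivation-encoded cells are
#' recovered by FACS.
#'
#' @param activated Activated Dendra2 intensity, >= 0.
#' @param unactivated Unactivated Dendra2 intensity, > 0.
#' @return Numeric ratio(s).
#' @examples
#' photoactivationRatio(250, 100)
#' @export
photoactivationRatio <- function(activated, unactivated) {
    stopIfNot(all(is.finite(activated)) && all(is.finite(unactivated)),
              "intensities must be finite")
    stopIfNot(all(activated >= 0), "activated intensity must be >= 0")
    stopIfNot(all(unactivated > 0), "unactivated intensity must be > 0")
    activated / unactivated
}

#' Assign phenotype values to activation bins
#'
#' Places each value in the half-open interval \code{[lo, hi)} of the gate
#' configuration (lower bound inclusive) and returns the 1-based bin index.
#' \code{NA} values yield \code{NA} bins with a warning, mirroring cells a
#' segmentation pipeline could not measure.
#'
#' @param value Numeric phenotype vector (N:C ratio, photoactivation ratio
#'   or shape factor).
#' @param gates A [GateConfig-class].
#' @return Integer bin indices; \code{gateDurations(gates)[bin]} gives the
#'   pulse durations.
#' @examples
#' assignGate(c(0.90, 1.30), nlsGates())
#' @export
assignGate <- function(value, gates) {
    validObject(gates)
    if (anyNA(value))
        warning(sum(is.na(value)), " NA phenotype value(s) skipped")
    findInterval(value, gateBoundaries(gates), left.open = FALSE) + 1L
}

#' Sort cells into photoactivation bins by their Dendra2 ratio
#'
#' @param cells data.frame with columns \code{activated} and
#'   \code{unactivated} (or a precomputed \code{ratio} column).
#' @param gates A [GateConfig-class] on the photoactivation ratio.
#' @return The input with a \code{bin} column appended; splitting on it
#'   partitions the cells.
#' @export
sortCells <- function(cells, gates) {
    ratio <- if ("ratio" %in% names(cells)) cells$ratio
             else photoactivationRatio(cells$activated, cells$unactivated)
    cells$bin <- assignGate(ratio, gates)
    cells
}

#' Precision and recall of optical marking
#'
#' Compares binary activation calls against a per-cell truth label (e.g.
#' miRFP positivity). Precision is TP / (TP + FP) and recall
#' TP / (TP + FN); an undefined denominator yields \code{NA}.
#'
#' @param assigned Logical (or 0/1) vector of activation calls.
#' @param truth Logical (or 0/1) vector of true labels, same length.
#' @return Named numeric vector \code{c(precision, recall)}.
#' @examples
#' markingMetrics(c(rep(TRUE, 10), rep(FALSE, 2)),
#'                c(rep(TRUE, 8), FALSE, FALSE, TRUE, TRUE))
#' @export
markingMetrics <- function(assigned, truth) {
    stopIfNot(length(assigned) == length(truth),
              "assigned and truth must have equal length")
    assigned <- as.logical(assigned); truth <- as.logical(truth)
    tp <- sum(assigned & truth)
    fp <- sum(assigned & !truth)
    fn <- sum(!assigned & truth)
    c(precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
      recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
}

#' Count distinguishable photoactivation levels
#'
#' A set of consecutive encoded levels is distinguishable when 1-D
#' thresholds on the (log) photoactivation ratio can be placed so that
#' every level in the set is recovered with at least \code{threshold}
#' accuracy. Between each adjacent pair the optimal threshold is found by
#' scanning all cut points; the function returns the size of the largest
#' consecutive run of levels that is jointly separable.
#'
#' @param ratios Per-cell photoactivation ratios.
#' @param levels Integer encoded level per cell (>= 2 distinct values).
#' @param threshold Required per-level assignment accuracy (default 0.95).
#' @return Integer count of distinguishable consecutive levels.
#' @export
countSeparableLevels <- function(ratios, levels, threshold = 0.95) {
    stopIfNot(length(ratios) == length(levels), "length mismatch")
    lv <- sort(unique(levels))
    stopIfNot(length(lv) >= 2L, "need at least two encoded levels")
    x <- log(pmax(ratios, .Machine$double.xmin))

    # best cut between two samples: maximize balanced pairwise accuracy
    bestCut <- function(a, b) {
        cand <- sort(unique(c(a, b)))
        cuts <- c(cand[1L] - 1, (cand[-1L] + cand[-length(cand)]) / 2,
                  cand[length(cand)] + 1)
        acc <- vapply(cuts, function(cc)
            (mean(a < cc) + mean(b >= cc)) / 2, numeric(1L))
        cuts[which.max(acc)]
    }

    best <- 1L
    for (start in seq_along(lv)) {
        for (end in seq(start, length(lv))) {
            if (end - start + 1L <= best) next
            sub <- lv[start:end]
            cuts <- vapply(seq_len(length(sub) - 1L), function(i)
                bestCut(x[levels == sub[i]], x[levels == sub[i + 1L]]),
                numeric(1L))
            if (is.unsorted(cuts)) next
            ok <- all(vapply(seq_along(sub), function(i) {
                xi <- x[levels == sub[i]]
                mean(findInterval(xi, cuts) + 1L == i) >= threshold
            }, logical(1L)))
            if (ok) best <- max(best, end - start + 1L)
        }
    }
    best
}
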