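#' Marking-noise configuration for the sort simulator
#'
#' Cell-to-bin misassignment is modeled as (i) per-cell Gaussian jitter on
#' log N:C before gating, (ii) a marking miss rate (an activated cell left
#' unconverted, recovered in the unactivated bin; the complement of recall),
#' (iii) a false-mark rate (an unactivated cell weakly converted into the
#' adjacent bin) and (iv) a symmetric spillover probability to adjacent
#' bins at FACS, and (v) a stray rate (a cell recovered in a uniformly
#' random bin: doublets and sorter impurity). Defaults emulate the
#' imperfection of optical marking (recall about 80 percent) and the wide
#' per-cell N:C spread single-cell imaging shows, without modeling optics.
#'
#' @param ratio_spread SD of Gaussian jitter on log N:C (default 0.10).
#' @param miss_rate Probability an activated cell is missed (default 0.2).
#' @param false_mark_rate Probability an unactivated cell is marked at the
#'   lowest activated level (default 0.01).
#' @param spill_prob Probability of FACS spillover to an adjacent bin
#'   (default 0.02).
#' @param stray_rate Probability a cell lands in a uniformly random bin
#'   (default 0.02).
#' @return A named list.
#' @export
sortNoise <- function(ratio_spread = 0.10, miss_rate = 0.2,
                      false_mark_rate = 0.01, spill_prob = 0.02,
                      stray_rate = 0.02) {
    stopIfNot(ratio_spread >= 0 && miss_rate >= 0 && miss_rate <= 1 &&
              false_mark_rate >= 0 && false_mark_rate <= 1 &&
              spill_prob >= 0 && spill_prob <= 0.5 &&
              stray_rate >= 0 && stray_rate <= 1,
              "invalid noise configuration")
    list(ratio_spread = ratio_spread, miss_rate = miss_rate,
         false_mark_rate = false_mark_rate, spill_prob = spill_prob,
         stray_rate = stray_rate)
}

#' Simulate a photoactivation bin-sort of an NLS variant library
#'
#' Seeds \code{n_cells_per_variant} cells per nucleotide variant per
#' replicate, jitters each cell's log N:C around its variant's ground
#' truth, gates cells into photoactivation bins, applies the marking-noise
#' model, and converts per-bin cell tallies into sequencing read counts
#' (multinomial at a configurable per-bin depth, or the tallies themselves
#' when \code{depth_per_bin} is \code{NULL}).
#'
#' @param library An [NNKLibrary-class].
#' @param gates A [GateConfig-class] on the N:C ratio; default [nlsGates()].
#' @param n_cells_per_variant Cells seeded per variant per replicate.
#' @param noise A [sortNoise()] list; use
#'   \code{sortNoise(0, 0, 0, 0, 0)} for deterministic gating.
#' @param n_replicates Number of sort replicates.
#' @param depth_per_bin Reads sequenced per bin (default 200000, deep
#'   enough that sorter-impurity frequencies clear the count filter), or
#'   \code{NULL} to report cell tallies directly.
#' @param seed Integer seed.
#' @return A list with \code{counts} (data.frame \code{variant_nt},
#'   \code{aa_change}, \code{class}, \code{replicate}, \code{bin},
#'   \code{count}) and \code{truth} (per-variant per-replicate
#'   \code{cells_seeded} and per-bin cell tallies).
#' @examples
#' lib <- generateNNKLibrary(svNLSRegion())
#' sim <- simulateSortExperiment(lib, n_cells_per_variant = 50,
#'                               n_replicates = 2, seed = 7)
#' head(sim$counts)
#' @export
simulateSortExperiment <- function(library, gates = nlsGates(),
                                   n_cells_per_variant = 500,
                                   noise = sortNoise(), n_replicates = 2,
                                   depth_per_bin = 200000L, seed = 1L) {
    stopIfNot(is(library, "NNKLibrary"), "library must be an NNKLibrary")
    validObject(gates)
    stopIfNot(n_cells_per_variant >= 1, "need at least one cell per variant")
    stopIfNot(n_replicates >= 1, "need at least one replicate")
    v <- variants(library)
    nb <- nBins(gates)
    true_nc <- trueScores(library)[v$aa_change]

    withSeed(seed, {
        counts <- vector("list", n_replicates)
        truth <- vector("list", n_replicates)
        for (rep in seq_len(n_replicates)) {
            tallies <- matrix(0L, nrow(v), nb)
            for (i in seq_len(nrow(v))) {
                lognc <- log(true_nc[i]) +
                    if (noise$ratio_spread > 0)
                        stats::rnorm(n_cells_per_variant, 0, noise$ratio_spread)
                    else rep(0, n_cells_per_variant)
                bin <- findInterval(exp(lognc), gateBoundaries(gates)) + 1L
                if (noise$miss_rate > 0) {
                    act <- bin > 1L
                    miss <- act & stats::runif(n_cells_per_variant) < noise$miss_rate
                    bin[miss] <- 1L
                }
                if (noise$false_mark_rate > 0) {
                    fm <- bin == 1L &
                        stats::runif(n_cells_per_variant) < noise$false_mark_rate
                    bin[fm] <- 2L
                }
                if (noise$spill_prob > 0) {
                    sp <- stats::runif(n_cells_per_variant) < noise$spill_prob
                    dir <- sample(c(-1L, 1L), n_cells_per_variant, replace = TRUE)
                    bin[sp] <- pmin(pmax(bin[sp] + dir[sp], 1L), nb)
                }
                if (noise$stray_rate > 0) {
                    st <- stats::runif(n_cells_per_variant) < noise$stray_rate
                    bin[st] <- sample(seq_len(nb), sum(st), replace = TRUE)
                }
                tallies[i, ] <- tabulate(bin, nbins = nb)
            }
            reads <- tallies
            if (!is.null(depth_per_bin)) {
                reads <- matrix(0L, nrow(v), nb)
                for (b in seq_len(nb)) {
                    tot <- sum(tallies[, b])
                    if (tot > 0)
                        reads[, b] <- as.integer(stats::rmultinom(
                            1L, size = depth_per_bin,
                            prob = tallies[, b] / tot))
                }
            }
            counts[[rep]] <- data.frame(
                variant_nt = rep(v$nt_seq, nb),
                aa_change = rep(v$aa_change, nb),
                class = rep(v$class, nb),
                replicate = rep, bin = rep(seq_len(nb), each = nrow(v)),
                count = as.vector(reads), stringsAsFactors = FALSE)
            tr <- data.frame(variant_nt = v$nt_seq, aa_change = v$aa_change,
                replicate = rep, cells_seeded = n_cells_per_variant,
                stringsAsFactors = FALSE)
            colnames(tallies) <- paste0("cells_bin", seq_len(nb))
            truth[[rep]] <- cbind(tr, as.data.frame(tallies))
        }
        list(counts = do.call(rbind, counts), truth = do.call(rbind, truth))
    })
}

#' Simulate per-cell Dendra2 fluorescence for encoded activation levels
#'
#' Draws unactivated (green) and activated (red) Dendra2 intensities for
#' cells photoactivated with 405 nm pulses of the given durations. The
#' activated:unactivated ratio is log-normal around a per-duration mean;
#' the default means place four clearly separated ratio populations, as
#' four-level encoding produces.
#'
#' @param n_per_level Cells per encoded level.
#' @param durations Pulse durations in ms (default \code{c(0, 50, 200, 800)}).
#' @param ratio_means Mean photoactivation ratio per duration.
#' @param sd_log SD of the log ratio within a level (default 0.25).
#' @param unactivated_meanlog,unactivated_sdlog Log-normal parameters of
#'   the unactivated intensity (arbitrary units).
#' @param decay_halflife_h Optional half-life (hours) of the activated
#'   signal; with \code{hold_time_h} it attenuates ratios exponentially.
#'   Default \code{Inf} (off).
#' @param hold_time_h Hours between activation and sorting (default 0).
#' @param seed Integer seed.
#' @return data.frame with \code{unactivated}, \code{activated},
#'   \code{ratio}, \code{duration_ms}, \code{level}.
#' @export
simulatePhotoactivation <- function(n_per_level = 500,
                                    durations = c(0, 50, 200, 800),
                                    ratio_means = c(0.02, 0.35, 1.3, 4.8),
                                    sd_log = 0.25,
                                    unactivated_meanlog = log(5000),
                                    unactivated_sdlog = 0.3,
                                    decay_halflife_h = Inf,
                                    hold_time_h = 0, seed = 1L) {
    stopIfNot(length(durations) == length(ratio_means),
              "one ratio mean per duration")
    stopIfNot(!is.unsorted(durations, strictly = TRUE) &&
              !is.unsorted(ratio_means, strictly = TRUE),
              "durations and ratio means must increase together")
    withSeed(seed, {
        lev <- rep(seq_along(durations), each = n_per_level)
        mu <- ratio_means[lev] * 2^(-hold_time_h / decay_halflife_h)
        ratio <- mu * exp(stats::rnorm(length(lev), 0, sd_log))
        unact <- stats::rlnorm(length(lev), unactivated_meanlog,
                               unactivated_sdlog)
        data.frame(unactivated = unact, activated = ratio * unact,
                   ratio = ratio, duration_ms = durations[lev], level = lev)
    })
}

#' Default FACS gates on the photoactivation ratio
#'
#' Boundaries at the geometric midpoints of the default per-level ratio
#' means of [simulatePhotoactivation()].
#' @param ratio_means Per-level mean ratios.
#' @param durations Pulse durations (ms) labeling the bins.
#' @return A [GateConfig-class].
#' @export
photoactivationGates <- function(ratio_means = c(0.02, 0.35, 1.3, 4.8),
                                 durations = c(0, 50, 200, 800)) {
    k <- length(ratio_means)
    GateConfig(sqrt(ratio_means[-k] * ratio_means[-1L]), durations)
}
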