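#' Scoring configuration for the bin-sort localization score
#'
#' @param min_count Minimum read count a nucleotide variant must reach in
#'   every bin of every replicate (default 5).
#' @param nnk_filter Require mutant codons to be reachable by NNK
#'   mutagenesis (default \code{TRUE}).
#' @param frequency_floor Variants below this within-bin frequency in all
#'   four bins of a replicate are dropped from that replicate in the
#'   re-filtering pass (default 3e-5, i.e. 0.003 percent of reads).
#' @param bottom_fraction Fraction of lowest-scoring missense variants
#'   whose median raw score anchors the normalization at 0 (default 0.10).
#' @param min_replicates Variants scored in fewer replicates are flagged
#'   unreliable (default 2).
#' @param include_syn_in_bottom Include synonymous/WT variants in the
#'   bottom-decile set (default \code{FALSE}: missense only; recorded in
#'   the output metadata).
#' @return A named list.
#' @export
scoringConfig <- function(min_count = 5L, nnk_filter = TRUE,
                          frequency_floor = 3e-5, bottom_fraction = 0.10,
                          min_replicates = 2L,
                          include_syn_in_bottom = FALSE) {
    stopIfNot(min_count >= 0, "min_count must be >= 0")
    stopIfNot(frequency_floor >= 0 && frequency_floor < 1,
              "frequency_floor must be in [0, 1)")
    stopIfNot(bottom_fraction > 0 && bottom_fraction < 1,
              "bottom_fraction must be in (0, 1)")
    list(min_count = as.integer(min_count), nnk_filter = isTRUE(nnk_filter),
         frequency_floor = frequency_floor,
         bottom_fraction = bottom_fraction,
         min_replicates = as.integer(min_replicates),
         include_syn_in_bottom = isTRUE(include_syn_in_bottom))
}

# mutant codon of a single-codon variant relative to wt (NA for wildtype)
mutantCodon <- function(nt_seq, wt_dna) {
    vapply(nt_seq, function(s) {
        if (s == wt_dna) return(NA_character_)
        cs <- substring(s, seq(1L, nchar(s) - 2L, 3L), seq(3L, nchar(s), 3L))
        ws <- substring(wt_dna, seq(1L, 31L, 3L), seq(3L, 33L, 3L))
        d <- which(cs != ws)
        if (length(d) != 1L) return(NA_character_)
        cs[d]
    }, character(1L), USE.NAMES = FALSE)
}

#' Filter low-quality nucleotide variants
#'
#' Applies the two count-table filters: a variant must reach
#' \code{min_count} reads in every bin of every replicate (a missing
#' (variant, replicate, bin) combination counts as zero), and its mutant
#' codon must be reachable by NNK mutagenesis (third base G or T). The
#' wild-type sequence is exempt from the NNK requirement.
#'
#' @param counts data.frame with columns \code{variant_nt},
#'   \code{aa_change}, \code{replicate}, \code{bin}, \code{count}.
#' @param wt_dna The 33 nt wild-type sequence.
#' @param config A [scoringConfig()] list.
#' @return The filtered count table.
#' @export
filterVariants <- function(counts, wt_dna, config = scoringConfig()) {
    stopIfNot(all(c("variant_nt", "replicate", "bin", "count") %in%
                  names(counts)), "count table is missing columns")
    stopIfNot(all(counts$count >= 0), "counts must be non-negative")
    wt_dna <- toupper(wt_dna)
    bad_len <- nchar(counts$variant_nt) != nchar(wt_dna)
    if (any(bad_len))
        stop("variant sequence length differs from wt_dna", call. = FALSE)

    # count filter over the complete (replicate, bin) grid
    reps <- unique(counts$replicate); bins <- sort(unique(counts$bin))
    n_cells <- length(reps) * length(bins)
    min_by_var <- vapply(split(counts$count, counts$variant_nt), function(x)
        if (length(x) < n_cells) -1 else min(x), numeric(1L))
    keep_count <- names(min_by_var)[min_by_var >= config$min_count]

    keep <- counts$variant_nt %in% keep_count
    if (config$nnk_filter) {
        uv <- unique(counts$variant_nt)
        mc <- mutantCodon(uv, wt_dna)
        ok <- uv == wt_dna | (!is.na(mc) & isNNKCodon(mc))
        keep <- keep & counts$variant_nt %in% uv[ok]
    }
    out <- counts[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Collapse nucleotide variants to amino-acid changes
#'
#' Sums counts of nucleotide variants encoding the same amino-acid
#' substitution, per bin per replicate. Read totals per bin are conserved.
#'
#' @param counts A (filtered) variant count table with an
#'   \code{aa_change} column.
#' @return data.frame keyed by \code{aa_change}, \code{replicate},
#'   \code{bin} with summed \code{count} (and \code{class} carried along
#'   when present).
#' @export
collapseToAA <- function(counts) {
    stopIfNot("aa_change" %in% names(counts), "need an aa_change column")
    by <- list(aa_change = counts$aa_change, replicate = counts$replicate,
               bin = counts$bin)
    agg <- stats::aggregate(list(count = counts$count), by = by, FUN = sum)
    if ("class" %in% names(counts)) {
        cls <- counts$class[!duplicated(counts$aa_change)]
        names(cls) <- counts$aa_change[!duplicated(counts$aa_change)]
        agg$class <- unname(cls[agg$aa_change])
    }
    agg[order(agg$replicate, agg$bin, agg$aa_change), , drop = FALSE]
}

#' Within-bin variant frequencies
#'
#' Divides each variant's count by the total reads in its (replicate, bin).
#'
#' @param counts A collapsed count table.
#' @return The table with a \code{freq} column appended.
#' @export
binFrequencies <- function(counts) {
    key <- paste(counts$replicate, counts$bin)
    totals <- tapply(counts$count, key, sum)
    if (any(totals == 0))
        stop("bin with zero total reads in replicate ",
             paste(unique(counts$replicate[key %in% names(totals)[totals == 0]]),
                   collapse = ", "), call. = FALSE)
    counts$freq <- counts$count / as.numeric(totals[key])
    counts
}

#' Weighted-average raw localization score
#'
#' \deqn{S_{raw} = \frac{0.25 f_{b1} + 0.50 f_{b2} + 0.75 f_{b3} + f_{b4}}
#'                      {f_{b1} + f_{b2} + f_{b3} + f_{b4}}}
#' where \eqn{f_{bk}} is the variant's within-bin read frequency in sort
#' bin \eqn{k}. The score lies in \code{[0.25, 1]}: 0.25 when all mass is
#' in the least-activated bin, 1 when all mass is in the most-activated.
#'
#' @param freqs Numeric vector of four per-bin frequencies, or a matrix
#'   with four columns (one row per variant).
#' @return Numeric score(s); \code{NA} where all four frequencies are zero.
#' @examples
#' rawScore(c(0.1, 0, 0, 0))   # 0.25
#' rawScore(c(0, 0, 0, 0.2))   # 1
#' @export
rawScore <- function(freqs) {
    w <- c(0.25, 0.50, 0.75, 1.00)
    if (is.matrix(freqs)) {
        stopIfNot(ncol(freqs) == 4L, "need four bin frequencies")
        tot <- rowSums(freqs)
        out <- as.vector(freqs %*% w) / tot
        out[tot == 0] <- NA_real_
        return(out)
    }
    stopIfNot(length(freqs) == 4L, "need four bin frequencies")
    stopIfNot(all(freqs >= 0), "frequencies must be non-negative")
    tot <- sum(freqs)
    if (tot == 0) return(NA_real_)
    sum(w * freqs) / tot
}

#' Two-anchor score normalization
#'
#' Maps raw scores linearly so a wild-type raw score becomes 1 and the
#' median raw score of the bottom decile of variants becomes 0:
#' \deqn{S_{norm} = (S_{raw} - S_{P10}) / (S_{WT} - S_{P10})}
#'
#' @param s_raw Numeric raw score(s).
#' @param s_wt Wild-type raw score anchor.
#' @param s_p10 Bottom-decile median raw score anchor.
#' @return Normalized score(s).
#' @examples
#' normalizeScores(0.9, s_wt = 0.9, s_p10 = 0.3)  # 1
#' normalizeScores(0.3, s_wt = 0.9, s_p10 = 0.3)  # 0
#' @export
normalizeScores <- function(s_raw, s_wt, s_p10) {
    if (!is.finite(s_wt) || !is.finite(s_p10) || s_wt <= s_p10)
        stop("degenerate normalization: S_WT must exceed S_P10",
             call. = FALSE)
    (s_raw - s_p10) / (s_wt - s_p10)
}

# raw-score table for one replicate: aa_change, class, S_raw
replicateRawScores <- function(freq_tab) {
    wide <- tapply(freq_tab$freq, list(freq_tab$aa_change, freq_tab$bin), sum)
    wide[is.na(wide)] <- 0
    if (ncol(wide) < 4L) {
        miss <- setdiff(as.character(1:4), colnames(wide))
        for (m in miss) wide <- cbind(wide, 0)
        colnames(wide)[(ncol(wide) - length(miss) + 1L):ncol(wide)] <- miss
    }
    wide <- wide[, as.character(1:4), drop = FALSE]
    cls <- freq_tab$class[match(rownames(wide), freq_tab$aa_change)]
    data.frame(aa_change = rownames(wide), class = cls,
               S_raw = rawScore(wide), stringsAsFactors = FALSE,
               row.names = NULL)
}

# normalization anchors for one replicate's raw scores
computeAnchors <- function(raw_df, config) {
    s_wt <- raw_df$S_raw[raw_df$aa_change == "WT"]
    if (!length(s_wt) || is.na(s_wt)) {
        syn <- raw_df$S_raw[raw_df$class == "synonymous"]
        s_wt <- if (length(syn)) mean(syn, na.rm = TRUE) else NA_real_
    }
    pool <- if (config$include_syn_in_bottom) raw_df
            else raw_df[raw_df$class == "missense", , drop = FALSE]
    pool <- pool[!is.na(pool$S_raw), , drop = FALSE]
    if (!nrow(pool)) return(c(S_WT = s_wt, S_P10 = NA_real_))
    k <- max(1L, ceiling(config$bottom_fraction * nrow(pool)))
    bottom <- sort(pool$S_raw)[seq_len(k)]
    c(S_WT = unname(s_wt), S_P10 = stats::median(bottom))
}

#' Score an NLS variant library from bin-sort read counts
#'
#' The full scoring pipeline: (1) count/NNK filtering of nucleotide
#' variants; (2) collapse to amino-acid changes; (3) within-bin
#' frequencies and weighted-average raw scores per replicate;
#' (4) two-anchor normalization; (5) a frequency re-filter dropping, per
#' replicate, variants below \code{frequency_floor} in all four bins,
#' after which frequencies, raw and normalized scores are recomputed;
#' (6) aggregation to per-variant mean and standard error across the
#' replicates in which the variant scored, flagging variants scored in
#' fewer than \code{min_replicates}.
#'
#' @param counts Variant count table (\code{variant_nt}, \code{aa_change},
#'   \code{replicate}, \code{bin}, \code{count}; a \code{class} column is
#'   carried through).
#' @param wt_dna The 33 nt wild-type sequence.
#' @param config A [scoringConfig()] list.
#' @return A [ScoreTable-class].
#' @examples
#' lib <- generateNNKLibrary(svNLSRegion())
#' sim <- simulateSortExperiment(lib, n_cells_per_variant = 100,
#'                               noise = sortNoise(0, 0, 0, 0), seed = 3)
#' st <- scoreVariants(sim$counts, wtSequence(lib))
#' head(finalScores(st))
#' @export
scoreVariants <- function(counts, wt_dna, config = scoringConfig()) {
    filt <- filterVariants(counts, wt_dna, config)
    if (!nrow(filt)) stop("no variants survive filtering", call. = FALSE)
    aa <- collapseToAA(filt)

    perRep <- function(tab) {
        fr <- binFrequencies(tab)
        raw <- replicateRawScores(fr)
        list(freq = fr, raw = raw)
    }

    reps <- sort(unique(aa$replicate))
    rep_rows <- list(); anchor_rows <- list()
    for (r in reps) {
        tab <- aa[aa$replicate == r, , drop = FALSE]
        first <- perRep(tab)
        # frequency re-filter: below floor in ALL bins of this replicate
        fmax <- tapply(first$freq$freq, first$freq$aa_change, max)
        drop <- names(fmax)[fmax < config$frequency_floor]
        tab2 <- tab[!(tab$aa_change %in% drop), , drop = FALSE]
        if (!nrow(tab2)) next
        second <- perRep(tab2)
        anch <- computeAnchors(second$raw, config)
        if (!is.finite(anch["S_WT"]) || !is.finite(anch["S_P10"]) ||
            anch["S_WT"] <= anch["S_P10"])
            stop("degenerate normalization in replicate ", r, call. = FALSE)
        sc <- second$raw
        sc$S_norm <- normalizeScores(sc$S_raw, anch["S_WT"], anch["S_P10"])
        sc$replicate <- r
        rep_rows[[as.character(r)]] <- sc
        anchor_rows[[as.character(r)]] <- data.frame(replicate = r,
            S_WT = unname(anch["S_WT"]), S_P10 = unname(anch["S_P10"]))
    }
    rs <- do.call(rbind, rep_rows)
    rownames(rs) <- NULL
    anchors <- do.call(rbind, anchor_rows)
    rownames(anchors) <- NULL
    final <- aggregateReplicates(rs, min_replicates = config$min_replicates)
    new("ScoreTable", replicateScores = rs, anchors = anchors,
        final = final, config = config)
}

#' Aggregate normalized scores across replicates
#'
#' Mean and standard error (SD / sqrt(n)) of the normalized score over the
#' replicates in which a variant scored; variants scored in fewer than
#' \code{min_replicates} replicates are flagged unreliable.
#'
#' @param rep_scores data.frame with \code{aa_change}, \code{replicate},
#'   \code{S_norm} (and optionally \code{class}).
#' @param min_replicates Reliability threshold (default 2).
#' @return data.frame with \code{aa_change}, \code{class},
#'   \code{mean_score}, \code{se}, \code{n_replicates}, \code{unreliable}.
#' @export
aggregateReplicates <- function(rep_scores, min_replicates = 2L) {
    ok <- !is.na(rep_scores$S_norm)
    rs <- rep_scores[ok, , drop = FALSE]
    sp <- split(rs$S_norm, rs$aa_change)
    out <- data.frame(aa_change = names(sp),
        mean_score = vapply(sp, mean, numeric(1L)),
        se = vapply(sp, function(x)
            if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
            numeric(1L)),
        n_replicates = vapply(sp, length, integer(1L)),
        stringsAsFactors = FALSE, row.names = NULL)
    out$unreliable <- out$n_replicates < min_replicates
    if ("class" %in% names(rep_scores))
        out$class <- rep_scores$class[match(out$aa_change,
                                            rep_scores$aa_change)]
    out[order(out$aa_change), c("aa_change",
        intersect("class", names(out)), "mean_score", "se",
        "n_replicates", "unreliable")]
}
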