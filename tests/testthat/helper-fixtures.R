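# Shared fixtures and independent oracles used across the suite.

# A small wild-type region whose translation has no stop codons.
fixtureWT <- function() svNLSRegion()

# Toy preference matrix with known structure: at every position residue K
# is best (1), A worst (0), others in between deterministically.
toyPrefs <- function() {
    s <- matrix(0.5, 11, 20, dimnames = list(paste0("pos", 1:11),
        c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))
    s[, "K"] <- 1.0
    s[, "A"] <- 0.2
    s[, "G"] <- 0.6
    df <- expand.grid(position = 1:11,
                      aa = colnames(s), stringsAsFactors = FALSE)
    df$score <- s[cbind(df$position, match(df$aa, colnames(s)))]
    positionPreferences(df)
}

# Independent brute-force recomputation of the full scoring pipeline,
# written as plain nested loops over data.frames (no shared helpers with
# the implementation under test).
bruteForceScores <- function(counts, wt_dna, min_count = 5,
                             freq_floor = 3e-5, bottom_frac = 0.10) {
    reps <- sort(unique(counts$replicate))
    bins <- 1:4
    # (1) count filter: every bin of every replicate
    keep <- character(0)
    for (v in unique(counts$variant_nt)) {
        ok <- TRUE
        for (r in reps) for (b in bins) {
            cnt <- counts$count[counts$variant_nt == v &
                counts$replicate == r & counts$bin == b]
            if (length(cnt) == 0) cnt <- 0
            if (sum(cnt) < min_count) ok <- FALSE
        }
        if (ok) keep <- c(keep, v)
    }
    tab <- counts[counts$variant_nt %in% keep, ]
    # (2) NNK filter
    keep2 <- character(0)
    for (v in unique(tab$variant_nt)) {
        if (v == wt_dna) { keep2 <- c(keep2, v); next }
        diffs <- which(strsplit(v, "")[[1]] != strsplit(wt_dna, "")[[1]])
        cod <- unique(ceiling(diffs / 3))
        if (length(cod) != 1) next
        codon <- substr(v, cod * 3 - 2, cod * 3)
        if (substr(codon, 3, 3) %in% c("G", "T")) keep2 <- c(keep2, v)
    }
    tab <- tab[tab$variant_nt %in% keep2, ]
    out <- NULL
    for (r in reps) {
        # (3) collapse to aa
        sub <- tab[tab$replicate == r, ]
        aa <- unique(sub$aa_change)
        cnt <- matrix(0, length(aa), 4, dimnames = list(aa, NULL))
        for (i in seq_len(nrow(sub)))
            cnt[sub$aa_change[i], sub$bin[i]] <-
                cnt[sub$aa_change[i], sub$bin[i]] + sub$count[i]
        scoreOnce <- function(cnt) {
            f <- sweep(cnt, 2, colSums(cnt), "/")
            s <- numeric(nrow(f))
            for (i in seq_len(nrow(f))) {
                fi <- f[i, ]
                s[i] <- if (sum(fi) == 0) NA else
                    (0.25 * fi[1] + 0.5 * fi[2] + 0.75 * fi[3] + fi[4]) /
                    sum(fi)
            }
            list(f = f, s = s)
        }
        first <- scoreOnce(cnt)
        # (5) frequency re-filter: below floor in all four bins
        drop <- rownames(cnt)[apply(first$f, 1, max) < freq_floor]
        cnt <- cnt[!(rownames(cnt) %in% drop), , drop = FALSE]
        second <- scoreOnce(cnt)
        s <- second$s; names(s) <- rownames(cnt)
        cls <- sub$class[match(rownames(cnt), sub$aa_change)]
        s_wt <- if ("WT" %in% names(s)) s[["WT"]] else
            mean(s[cls == "synonymous"])
        mis <- sort(s[cls == "missense"])
        k <- max(1, ceiling(bottom_frac * length(mis)))
        s_p10 <- median(mis[1:k])
        out <- rbind(out, data.frame(aa_change = names(s), replicate = r,
            S_raw = unname(s),
            S_norm = (unname(s) - s_p10) / (s_wt - s_p10),
            stringsAsFactors = FALSE))
    }
    out
}

# Exhaustive confusion-matrix precision/recall oracle.
confusionOracle <- function(assigned, truth) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(assigned)) {
        if (assigned[i] && truth[i]) tp <- tp + 1
        if (assigned[i] && !truth[i]) fp <- fp + 1
        if (!assigned[i] && truth[i]) fn <- fn + 1
    }
    c(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
      recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

# Exhaustive rank-sum statistic: number of (x, y) pairs with x > y plus
# half the ties (the Mann-Whitney U for the first sample).
rankSumOracle <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y)
        u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
}

# Closed-form hypergeometric tail by direct enumeration.
hyperOracle <- function(overlap, set_size, universe_size, draw_size) {
    p <- 0
    for (k in overlap:min(set_size, draw_size))
        p <- p + choose(set_size, k) *
            choose(universe_size - set_size, draw_size - k) /
            choose(universe_size, draw_size)
    p
}
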