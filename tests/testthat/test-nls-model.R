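test_that("position preferences apply the min-max formula with imputation", {
    df <- data.frame(position = rep(1:2, each = 3),
                     aa = c("A", "K", "G", "A", "K", "G"),
                     score = c(0.2, 1.0, 0.6, 0.3, 0.9, 0.6))
    # pad so every position has >= 2 distinct scores (only 3 residues given)
    pm <- positionPreferences(df)
    p <- preferences(pm)
    expect_equal(unname(p[1, "A"]), 0)
    expect_equal(unname(p[1, "K"]), 1)
    expect_equal(unname(p[1, "G"]), 0.5)
    # missing residues imputed with the position median before scaling
    med1 <- median(c(0.2, 1.0, 0.6))
    expect_equal(unname(p[1, "W"]), (med1 - 0.2) / (1.0 - 0.2))
    expect_true(pm@imputed[1, match("W", colnames(p))])
    expect_false(pm@imputed[1, match("K", colnames(p))])
    # degenerate position: all scores equal
    dg <- data.frame(position = 1, aa = c("A", "K"), score = c(0.5, 0.5))
    expect_error(positionPreferences(dg), "degenerate")
})

test_that("preference scaling pins each position to [0, 1]", {
    prefs <- toyPrefs()
    p <- preferences(prefs)
    expect_true(all(apply(p, 1, min) == 0))
    expect_true(all(apply(p, 1, max) == 1))
})

test_that("peptide scoring sums per-position preferences", {
    prefs <- toyPrefs()
    expect_equal(scorePeptide(strrep("K", 11), prefs), 11)
    expect_equal(scorePeptide(strrep("A", 11), prefs), 0)
    expect_equal(scorePeptide(paste0(strrep("K", 5), strrep("G", 6)),
                              prefs), 5 + 6 * 0.5)
    expect_error(scorePeptide("KKK", prefs), "11 residues")
    expect_error(scorePeptide(strrep("B", 11), prefs), "invalid")
})

test_that("peptide scoring is additive under position permutation", {
    pm <- toyPrefs()
    # swap the preference columns of positions 2 and 7 and the peptide
    p <- preferences(pm)
    p2 <- p; p2[2, ] <- p[7, ]; p2[7, ] <- p[2, ]
    pm2 <- new("PreferenceMatrix", scores = p2, preferences = p2,
               imputed = pm@imputed)
    pep <- "KAGKAGKAGKA"
    pep2 <- paste0(substr(pep, 1, 1), substr(pep, 7, 7),
                   substr(pep, 3, 6), substr(pep, 2, 2),
                   substr(pep, 8, 11))
    expect_equal(scorePeptide(pep2, pm2), scorePeptide(pep, pm))
})

test_that("likely-NLS extraction picks the top overlapping window", {
    prefs <- toyPrefs()
    seq <- paste0(strrep("A", 20), strrep("K", 11), strrep("A", 20))
    hit <- extractLikelyNLS(seq, c(21, 31), prefs)
    expect_equal(hit$start, 21)
    expect_equal(hit$peptide, strrep("K", 11))
    # annotation near the start clips candidate windows at position 1
    hit2 <- extractLikelyNLS(seq, c(1, 7), prefs)
    expect_gte(hit2$start, 1)
    # ties resolve to the leftmost window
    flat <- strrep("G", 40)
    hit3 <- extractLikelyNLS(flat, c(10, 20), prefs)
    expect_equal(hit3$start, 1)  # all windows tie; leftmost overlapping
    expect_warning(out <- extractLikelyNLS("KKKK", c(1, 4), prefs),
                   "shorter")
    expect_null(out)
})

test_that("training sets label one likely NLS per annotation", {
    prefs <- toyPrefs()
    prot <- paste0(strrep("A", 10), strrep("K", 11), strrep("A", 9))
    stopifnot(nchar(prot) == 30)
    ann <- data.frame(protein_id = "p1", start = 11, end = 21)
    ts <- buildTrainingSet(c(p1 = prot), ann, prefs)
    expect_equal(nrow(ts), 20L)          # L - 10 windows
    expect_equal(sum(ts$label), 1L)
    expect_equal(ts$start[ts$label == 1], 11)
    feats <- as.matrix(ts[, paste0("x", 1:11)])
    expect_true(all(feats >= 0 & feats <= 1))
    # two annotations in one protein give two positives
    prot2 <- paste0(strrep("K", 11), strrep("A", 15), strrep("K", 11),
                    strrep("A", 5))
    ann2 <- data.frame(protein_id = c("p", "p"), start = c(1, 27),
                       end = c(11, 37))
    ts2 <- buildTrainingSet(c(p = prot2), ann2, prefs)
    expect_equal(sum(ts2$label), 2L)
})

test_that("the linear model separates separable training data", {
    prefs <- toyPrefs()
    pr <- simulateProteome(prefs, n_nuclear = 25, n_cytoplasmic = 25,
                           length = 120, motif_noise = 0, seed = 3)
    ts <- buildTrainingSet(pr$sequences, pr$annotations, prefs)
    # make labels exactly separable by the feature sum
    fsum <- rowSums(ts[, paste0("x", 1:11)])
    ts$label <- as.integer(fsum > quantile(fsum, 0.99))
    fit <- fitNLSModel(ts, seed = 7)
    expect_equal(length(coef(fit)), 12L)
    expect_gt(fit@cvAUC, 0.99)
    # degenerate features raise an error
    bad <- ts; bad[, paste0("x", 1:11)] <- 0.5
    expect_error(fitNLSModel(bad), "degenerate")
    one <- ts; one$label <- 0L
    expect_error(fitNLSModel(one), "both labels")
})

test_that("model fitting is deterministic given data and seed", {
    prefs <- toyPrefs()
    pr <- simulateProteome(prefs, n_nuclear = 10, n_cytoplasmic = 10,
                           length = 60, seed = 5)
    ts <- buildTrainingSet(pr$sequences, pr$annotations, prefs)
    f1 <- fitNLSModel(ts, seed = 11)
    f2 <- fitNLSModel(ts, seed = 11)
    expect_identical(coef(f1), coef(f2))
    expect_identical(f1@cvAUC, f2@cvAUC)
})

test_that("threshold calibration matches the confusion-matrix oracle", {
    set.seed(13)
    n <- 400
    labels <- as.integer(runif(n) < 0.3)
    scores <- labels + rnorm(n, 0, 0.8)
    thr <- calibrateThresholds(scores, labels)
    curve <- thr@curve
    for (i in sample(nrow(curve), 20)) {
        calls <- scores >= curve$cutoff[i]
        oracle <- confusionOracle(calls, labels == 1)
        expect_equal(curve$precision[i], unname(oracle["precision"]))
        expect_equal(curve$recall[i], unname(oracle["recall"]))
    }
    expect_gte(thr@highConfidence, thr@candidate)
    # raising the cutoff never increases recall
    expect_true(all(diff(curve$recall[order(curve$cutoff)]) <= 1e-12))
})

test_that("unreachable precision targets fall back with a warning", {
    set.seed(19)
    labels <- rep(0:1, each = 100)
    scores <- rnorm(200)           # uninformative scores
    expect_warning(thr <- calibrateThresholds(scores, labels),
                   "precision target unreachable")
    # precision hovers near prevalence at every cutoff except tiny tails
    pr <- thr@curve$precision[thr@curve$recall > 0.2]
    expect_lt(max(abs(pr - 0.5)), 0.25)
})

test_that("a perfectly separating model admits both cutoffs", {
    labels <- rep(c(0, 1), each = 50)
    scores <- c(rnorm(50, 0), rnorm(50, 10))
    thr <- calibrateThresholds(scores, labels)
    expect_gte(thr@highConfidence, thr@candidate)
    calls <- scores >= thr@highConfidence
    expect_gte(confusionOracle(calls, labels == 1)["precision"], 0.9)
})

test_that("proteome scanning scores every in-bounds window", {
    prefs <- toyPrefs()
    pr <- simulateProteome(prefs, n_nuclear = 6, n_cytoplasmic = 6,
                           length = 100, motif_noise = 0, top_k = 1,
                           seed = 9)
    ts <- buildTrainingSet(pr$sequences, pr$annotations, prefs)
    model <- fitNLSModel(ts, seed = 1)
    thr <- suppressWarnings(calibrateThresholds(predictNLS(model, ts),
                                                ts$label))
    scan <- scanProteome(pr$sequences, model, prefs, thr)
    expect_equal(sum(scan$windows$protein_id == "prot001"), 90L)  # L - 10
    # each nuclear protein's top window lands on its planted motif
    for (i in seq_len(nrow(pr$annotations))) {
        ann <- pr$annotations[i, ]
        top <- scan$top[scan$top$protein_id == ann$protein_id, ]
        overlap <- min(top$start + 10, ann$end) - max(top$start, ann$start) + 1
        expect_gte(overlap, 10)
    }
    # call monotonicity: high-confidence implies >= candidate cutoff
    hc <- scan$windows$score[scan$windows$call == "high-confidence"]
    expect_true(all(hc >= thr@candidate))
})

test_that("compartment comparison matches an exhaustive rank-sum oracle", {
    set.seed(23)
    x <- rnorm(30); y <- rnorm(20)
    out <- compareCompartments(x, y)
    expect_equal(out$statistic, rankSumOracle(x, y))
    # identical groups: no shift
    z <- rnorm(40)
    out2 <- compareCompartments(z, z)
    expect_gt(out2$p.value, 0.9)
    expect_equal(mean(out2$bins$prop_nuclear), 0.5, tolerance = 0.05)
    # a +1 shift at n = 200 is overwhelming
    a <- rnorm(200) + 1; b <- rnorm(200)
    expect_lt(compareCompartments(a, b)$p.value, 1e-10)
    expect_error(compareCompartments(numeric(0), z), "nonempty")
})
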