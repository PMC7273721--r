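#' Position-wise amino-acid preferences from variant raw scores
#'
#' Builds the 11 x 20 matrix of mean raw localization scores
#' \eqn{s_{r,a}} and min-max scales each position:
#' \eqn{x_{r,a} = (s_{r,a} - \min s_r) / (\max s_r - \min s_r)}, so the
#' best-tolerated residue at a position has preference 1 and the least 0.
#' Missing (position, residue) combinations are imputed with the median
#' raw score at that position before scaling and flagged. The wild-type
#' residue at each position receives the WT/synonymous raw score.
#'
#' @param x A [ScoreTable-class] (raw scores averaged over replicates) or
#'   a data.frame with columns \code{position}, \code{aa}, \code{score}.
#' @return A [PreferenceMatrix-class].
#' @export
positionPreferences <- function(x) {
    if (is(x, "ScoreTable")) {
        rs <- replicateScores(x)
        mean_raw <- tapply(rs$S_raw, rs$aa_change, mean, na.rm = TRUE)
        df <- data.frame(aa_change = names(mean_raw),
                         score = as.numeric(mean_raw),
                         stringsAsFactors = FALSE)
        wt_score <- df$score[df$aa_change == "WT"]
        m <- regmatches(df$aa_change,
                        regexec("^([A-Z])(\\d+)([A-Z*])$", df$aa_change))
        ok <- lengths(m) == 4L
        tab <- data.frame(
            position = as.integer(vapply(m[ok], `[`, "", 3L)),
            wt_aa = vapply(m[ok], `[`, "", 2L),
            aa = vapply(m[ok], `[`, "", 4L),
            score = df$score[ok], stringsAsFactors = FALSE)
        tab <- tab[tab$aa %in% AA20, , drop = FALSE]
        # wild-type residues take the WT (or synonymous mean) raw score
        if (length(wt_score)) {
            wt_rows <- unique(tab[, c("position", "wt_aa")])
            syn <- tab$position * 100 + match(tab$aa, AA20)
            for (i in seq_len(nrow(wt_rows))) {
                sel <- tab$position == wt_rows$position[i] &
                       tab$aa == wt_rows$wt_aa[i]
                if (!any(sel))
                    tab <- rbind(tab, data.frame(
                        position = wt_rows$position[i],
                        wt_aa = wt_rows$wt_aa[i], aa = wt_rows$wt_aa[i],
                        score = wt_score, stringsAsFactors = FALSE))
                else tab$score[sel] <- mean(c(tab$score[sel], wt_score))
            }
        }
        x <- tab[, c("position", "aa", "score")]
    }
    stopIfNot(all(c("position", "aa", "score") %in% names(x)),
              "need position, aa and score columns")
    positions <- sort(unique(x$position))
    s <- matrix(NA_real_, length(positions), 20L,
                dimnames = list(paste0("pos", positions), AA20))
    for (i in seq_len(nrow(x))) {
        r <- match(x$position[i], positions); a <- match(x$aa[i], AA20)
        if (!is.na(a)) s[r, a] <- x$score[i]
    }
    imputed <- is.na(s)
    for (r in seq_len(nrow(s))) {
        obs <- s[r, !is.na(s[r, ])]
        stopIfNot(length(obs) >= 2L, "need >= 2 scores per position")
        s[r, is.na(s[r, ])] <- stats::median(obs)
    }
    rng <- t(apply(s, 1L, range))
    if (any(rng[, 2L] - rng[, 1L] <= 0))
        stop("degenerate position: all scores equal", call. = FALSE)
    prefs <- (s - rng[, 1L]) / (rng[, 2L] - rng[, 1L])
    new("PreferenceMatrix", scores = s, preferences = prefs,
        imputed = imputed)
}

# feature matrix (n x 11) of per-position preferences for 11-mer peptides
peptideFeatures <- function(peptides, prefs) {
    p <- preferences(prefs)
    stopIfNot(all(nchar(peptides) == 11L), "peptides must be 11 residues")
    chars <- strsplit(peptides, "")
    bad <- vapply(chars, function(ch) any(!ch %in% AA20), logical(1L))
    stopIfNot(!any(bad), "peptides contain invalid residues")
    out <- t(vapply(chars, function(ch)
        p[cbind(1:11, match(ch, AA20))], numeric(11L)))
    colnames(out) <- paste0("x", 1:11)
    out
}

#' Preference sum of an 11-mer peptide
#'
#' Sums the per-position amino-acid preferences of the peptide:
#' \eqn{\sum_{r=1}^{11} x_{r, peptide[r]}}. Ranges from 0 (the worst
#' residue at every position) to 11 (the best at every position).
#'
#' @param peptide Character vector of 11-residue peptides.
#' @param prefs A [PreferenceMatrix-class].
#' @return Numeric preference sum per peptide.
#' @export
scorePeptide <- function(peptide, prefs) {
    rowSums(peptideFeatures(peptide, prefs))
}

#' Extract the likely NLS for an annotated span
#'
#' Scores every in-bounds 11-mer sharing at least \code{min_overlap}
#' residue(s) with the annotated NLS span by its preference sum and
#' returns the maximum-scoring window ("likely NLS"); ties go to the
#' leftmost window.
#'
#' @param sequence Protein sequence (single string).
#' @param span Integer \code{c(start, end)}, 1-based inclusive.
#' @param prefs A [PreferenceMatrix-class].
#' @param min_overlap Required overlap with the span (default 1).
#' @return List: \code{start}, \code{peptide}, \code{score}; or
#'   \code{NULL} with a warning for proteins shorter than 11 residues.
#' @export
extractLikelyNLS <- function(sequence, span, prefs, min_overlap = 1L) {
    L <- nchar(sequence)
    if (L < 11L) {
        warning("protein shorter than 11 residues; skipped")
        return(NULL)
    }
    stopIfNot(span[1L] >= 1L && span[2L] <= L && span[1L] <= span[2L],
              "annotation span out of bounds")
    starts <- seq_len(L - 10L)
    ends <- starts + 10L
    ov <- pmin(ends, span[2L]) - pmax(starts, span[1L]) + 1L
    starts <- starts[ov >= min_overlap]
    stopIfNot(length(starts) > 0L, "no window overlaps the annotation")
    peps <- substring(sequence, starts, starts + 10L)
    valid <- !grepl("[^ACDEFGHIKLMNPQRSTVWY]", peps)
    starts <- starts[valid]; peps <- peps[valid]
    stopIfNot(length(starts) > 0L, "all overlapping windows contain X")
    sc <- scorePeptide(peps, prefs)
    best <- which.max(sc)  # which.max takes the first (leftmost) tie
    list(start = starts[best], peptide = peps[best], score = sc[best])
}

# all valid 11-mer windows of a protein: start, peptide
proteinWindows <- function(sequence) {
    L <- nchar(sequence)
    if (L < 11L) return(NULL)
    starts <- seq_len(L - 10L)
    peps <- substring(sequence, starts, starts + 10L)
    valid <- !grepl("[^ACDEFGHIKLMNPQRSTVWY]", peps)
    data.frame(start = starts[valid], peptide = peps[valid],
               stringsAsFactors = FALSE)
}

#' Build the labeled 11-mer training table
#'
#' For each annotated NLS the maximum-preference overlapping window is
#' labeled 1 ("likely NLS"); every other 11-mer of every protein is
#' labeled 0. Feature columns \code{x1..x11} hold the per-position
#' preferences.
#'
#' @param proteome Named character vector of protein sequences (or an
#'   \code{AAStringSet}).
#' @param annotations data.frame: \code{protein_id}, \code{start},
#'   \code{end} (1-based inclusive).
#' @param prefs A [PreferenceMatrix-class].
#' @param min_overlap Overlap rule for likely-NLS extraction (default 1).
#' @return data.frame: \code{protein_id}, \code{start}, \code{peptide},
#'   \code{label}, \code{x1..x11}.
#' @export
buildTrainingSet <- function(proteome, annotations, prefs,
                             min_overlap = 1L) {
    if (is(proteome, "AAStringSet"))
        proteome <- stats::setNames(as.character(proteome),
                                    names(proteome))
    stopIfNot(nrow(annotations) >= 1L, "need at least one annotated NLS")
    stopIfNot(all(annotations$protein_id %in% names(proteome)),
              "annotation references an unknown protein")
    tabs <- lapply(names(proteome), function(id) {
        w <- proteinWindows(proteome[[id]])
        if (is.null(w)) return(NULL)
        w$protein_id <- id
        w$label <- 0L
        w
    })
    tab <- do.call(rbind, tabs)
    for (i in seq_len(nrow(annotations))) {
        id <- annotations$protein_id[i]
        hit <- extractLikelyNLS(proteome[[id]],
            c(annotations$start[i], annotations$end[i]), prefs,
            min_overlap)
        if (is.null(hit)) next
        tab$label[tab$protein_id == id & tab$start == hit$start] <- 1L
    }
    feats <- peptideFeatures(tab$peptide, prefs)
    colnames(feats) <- paste0("x", 1:11)
    cbind(tab[, c("protein_id", "start", "peptide", "label")],
          as.data.frame(feats))
}

#' Fit the linear NLS model
#'
#' Least squares of the 0/1 label on the 11 positional preference
#' features plus an intercept (a linear probability model, fit as
#' printed rather than logistic regression). K-fold cross-validation
#' (seeded fold assignment) reports the out-of-fold AUC; the returned
#' coefficients are fit on all data.
#'
#' @param training data.frame from [buildTrainingSet()] (columns
#'   \code{label}, \code{x1..x11}).
#' @param folds Number of CV folds (default 8).
#' @param seed Integer seed for fold assignment.
#' @return An [NLSModel-class].
#' @export
fitNLSModel <- function(training, folds = 8L, seed = 1L) {
    stopIfNot(length(unique(training$label)) == 2L,
              "both labels must be present")
    feats <- paste0("x", 1:11)
    X <- as.matrix(training[, feats])
    if (any(apply(X, 2L, stats::sd) == 0))
        stop("degenerate features: a position is constant over samples",
             call. = FALSE)
    form <- stats::as.formula(paste("label ~", paste(feats, collapse = "+")))
    fit <- stats::lm(form, data = training)
    if (anyNA(stats::coef(fit)))
        stop("degenerate fit: collinear features", call. = FALSE)
    n <- nrow(training)
    fold <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
    oof <- numeric(n)
    for (k in seq_len(folds)) {
        f <- stats::lm(form, data = training[fold != k, , drop = FALSE])
        oof[fold == k] <- stats::predict(f,
            newdata = training[fold == k, , drop = FALSE])
    }
    cv_auc <- aucScore(oof, training$label == 1L)
    cf <- stats::coef(fit)
    names(cf) <- c("(Intercept)", paste0("pos", 1:11))
    new("NLSModel", coefficients = cf, cvAUC = cv_auc,
        folds = as.integer(folds), seed = as.integer(seed))
}

#' Predict NLS scores for 11-mer windows
#'
#' @param model An [NLSModel-class].
#' @param x Either a feature data.frame/matrix with columns
#'   \code{x1..x11}, or a character vector of 11-mer peptides (then
#'   \code{prefs} is required).
#' @param prefs A [PreferenceMatrix-class] when \code{x} holds peptides.
#' @return Numeric model score per window.
#' @export
predictNLS <- function(model, x, prefs = NULL) {
    if (is.character(x)) {
        stopIfNot(!is.null(prefs), "prefs required to score peptides")
        x <- peptideFeatures(x, prefs)
    }
    X <- as.matrix(as.data.frame(x)[, paste0("x", 1:11)])
    cf <- coef(model)
    as.vector(cf[1L] + X %*% cf[-1L])
}

#' Label windows by overlap with test-set NLS annotations
#'
#' A window is a positive when it overlaps an annotated NLS of its
#' protein by at least \code{min_overlap} residues (default 6, a majority
#' of the 11-mer).
#'
#' @param windows data.frame with \code{protein_id} and \code{start}.
#' @param annotations data.frame: \code{protein_id}, \code{start},
#'   \code{end}.
#' @param min_overlap Overlap (residues) required for a positive label.
#' @return Integer 0/1 labels.
#' @export
labelWindowsByOverlap <- function(windows, annotations, min_overlap = 6L) {
    lab <- integer(nrow(windows))
    for (i in seq_len(nrow(annotations))) {
        sel <- windows$protein_id == annotations$protein_id[i]
        ov <- pmin(windows$start + 10L, annotations$end[i]) -
              pmax(windows$start, annotations$start[i]) + 1L
        lab[sel & ov >= min_overlap] <- 1L
    }
    lab
}

#' Calibrate high-confidence and candidate call thresholds
#'
#' Sweeps every distinct model score as a cutoff on a labeled held-out
#' test set and records precision and recall at each. The
#' high-confidence cutoff is the smallest achieving precision >= 0.9;
#' the candidate cutoff the largest achieving recall >= 0.9. When a
#' target is unreachable the nearest achievable cutoff is returned with
#' a warning.
#'
#' @param scores Model scores of the test windows.
#' @param labels 0/1 labels of the test windows.
#' @param precision_target,recall_target Calibration targets
#'   (default 0.9).
#' @return A [CallThresholds-class] with the full PR curve.
#' @export
calibrateThresholds <- function(scores, labels, precision_target = 0.9,
                                recall_target = 0.9) {
    stopIfNot(length(scores) == length(labels), "length mismatch")
    y <- as.integer(labels)
    stopIfNot(any(y == 1L) && any(y == 0L), "both labels must be present")
    ord <- order(scores, decreasing = TRUE)
    ys <- y[ord]; ss <- scores[ord]
    tp <- cumsum(ys)
    fp <- cumsum(1L - ys)
    # evaluate at the last index of each distinct score (calls = score >= cutoff)
    last <- which(c(ss[-1L] != ss[-length(ss)], TRUE))
    curve <- data.frame(cutoff = ss[last],
                        precision = tp[last] / (tp[last] + fp[last]),
                        recall = tp[last] / sum(ys))
    hi_ok <- curve$precision >= precision_target
    hi <- if (any(hi_ok)) min(curve$cutoff[hi_ok]) else {
        warning("precision target unreachable; using cutoff with best precision")
        curve$cutoff[which.max(curve$precision)]
    }
    ca_ok <- curve$recall >= recall_target
    ca <- if (any(ca_ok)) max(curve$cutoff[ca_ok]) else {
        warning("recall target unreachable; using cutoff with best recall")
        curve$cutoff[which.max(curve$recall)]
    }
    if (ca > hi) ca <- hi
    new("CallThresholds", highConfidence = hi, candidate = ca,
        curve = curve[order(curve$cutoff), , drop = FALSE])
}

#' Scan a proteome for NLS candidates
#'
#' Scores every in-bounds 11-mer of every protein with the linear model,
#' calls windows at the calibrated thresholds (every high-confidence
#' call is by construction also above the candidate cutoff), and
#' records each protein's top-scoring window. Proteins shorter than 11
#' residues are skipped and counted.
#'
#' @param proteome Named character vector or \code{AAStringSet}.
#' @param model An [NLSModel-class].
#' @param prefs A [PreferenceMatrix-class].
#' @param thresholds A [CallThresholds-class].
#' @return List: \code{windows} (per-window \code{protein_id},
#'   \code{start}, \code{peptide}, \code{score}, \code{call}),
#'   \code{top} (per-protein maximum window), \code{n_skipped}.
#' @export
scanProteome <- function(proteome, model, prefs, thresholds) {
    if (is(proteome, "AAStringSet"))
        proteome <- stats::setNames(as.character(proteome),
                                    names(proteome))
    skipped <- 0L
    tabs <- lapply(names(proteome), function(id) {
        w <- proteinWindows(proteome[[id]])
        if (is.null(w) || !nrow(w)) return(NULL)
        w$protein_id <- id
        w
    })
    skipped <- sum(vapply(tabs, is.null, logical(1L)))
    tab <- do.call(rbind, tabs)
    stopIfNot(!is.null(tab), "no protein is long enough to scan")
    tab$score <- predictNLS(model, peptideFeatures(tab$peptide, prefs))
    tab$call <- ifelse(tab$score >= thresholds@highConfidence,
                       "high-confidence",
                ifelse(tab$score >= thresholds@candidate, "candidate",
                       "none"))
    top <- do.call(rbind, lapply(split(tab, tab$protein_id), function(d)
        d[which.max(d$score), , drop = FALSE]))
    rownames(top) <- NULL
    list(windows = tab[, c("protein_id", "start", "peptide", "score",
                           "call")], top = top, n_skipped = skipped)
}

#' Compare per-protein top NLS scores between compartments
#'
#' Two-sided Wilcoxon rank-sum test of nuclear versus cytoplasmic
#' proteins' top-scoring windows, plus the proportion of nuclear
#' proteins in equal-count bins of the pooled score ranking.
#'
#' @param nuclear_scores,cytoplasmic_scores Numeric vectors of
#'   per-protein top window scores.
#' @param n_bins Number of equal-count score bins (default 10).
#' @return List: \code{statistic} (rank-sum W), \code{p.value},
#'   \code{bins} (data.frame \code{bin}, \code{n},
#'   \code{prop_nuclear}).
#' @export
compareCompartments <- function(nuclear_scores, cytoplasmic_scores,
                                n_bins = 10L) {
    stopIfNot(length(nuclear_scores) > 0L && length(cytoplasmic_scores) > 0L,
              "both compartments must be nonempty")
    wt <- stats::wilcox.test(nuclear_scores, cytoplasmic_scores,
                             alternative = "two.sided", exact = FALSE)
    pooled <- c(nuclear_scores, cytoplasmic_scores)
    is_nuc <- rep(c(TRUE, FALSE),
                  c(length(nuclear_scores), length(cytoplasmic_scores)))
    r <- rank(pooled, ties.method = "first")
    bin <- ceiling(r / (length(pooled) / n_bins))
    bins <- data.frame(bin = sort(unique(bin)),
        n = as.integer(table(bin)),
        prop_nuclear = as.numeric(tapply(is_nuc, bin, mean)))
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         bins = bins)
}
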