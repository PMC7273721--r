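#' @import methods
NULL

#' Gate configuration for photoactivation sorting
#'
#' A set of strictly increasing boundaries partitioning a scalar phenotype
#' (N:C ratio, photoactivation ratio or nuclear shape factor) into half-open
#' intervals \code{[lo, hi)}, each mapped to a 405 nm pulse duration in
#' milliseconds. The interval index is the sort-bin index.
#'
#' @slot boundaries Numeric vector, strictly increasing; \code{k} boundaries
#'   define \code{k + 1} intervals covering the real line.
#' @slot durations Numeric vector of length \code{k + 1}; pulse duration (ms)
#'   applied to cells falling in each interval.
#'
#' @seealso [GateConfig()], [assignGate()], [nlsGates()], [morphologyGates()]
#' @export
setClass("GateConfig",
    representation(boundaries = "numeric", durations = "numeric"))

setValidity("GateConfig", function(object) {
    b <- object@boundaries
    if (length(b) < 1L || anyNA(b)) return("need at least one finite boundary")
    if (is.unsorted(b, strictly = TRUE)) return("boundaries must be strictly increasing")
    if (length(object@durations) != length(b) + 1L)
        return("need one duration per interval (length(boundaries) + 1)")
    if (anyNA(object@durations) || any(object@durations < 0))
        return("durations must be non-negative")
    TRUE
})

#' Construct a GateConfig
#'
#' @param boundaries Strictly increasing numeric boundaries.
#' @param durations Pulse durations (ms), one per interval; defaults to the
#'   four-level encoding 0/50/200/800 ms when three boundaries are given.
#' @return A [GateConfig-class] object.
#' @examples
#' GateConfig(c(0.964, 1.079, 1.244))
#' @export
GateConfig <- function(boundaries,
                       durations = if (length(boundaries) == 3L)
                           c(0, 50, 200, 800)
                       else stop("supply durations", call. = FALSE)) {
    new("GateConfig", boundaries = as.numeric(boundaries),
        durations = as.numeric(durations))
}

#' Standard N:C ratio gates for the NLS library sort
#'
#' Cells below N:C 0.964 are not activated; 0.964-1.079 get 50 ms,
#' 1.079-1.244 get 200 ms and above 1.244 get 800 ms.
#' @return A four-bin [GateConfig-class].
#' @export
nlsGates <- function() GateConfig(c(0.964, 1.079, 1.244), c(0, 50, 200, 800))

#' Shape-factor gates for the nuclear morphology sort
#'
#' Nuclei with shape factor below the cutoff (lobulated) are activated for
#' 800 ms; rounder nuclei for 200 ms.
#' @param cutoff Shape-factor boundary, default 0.65.
#' @return A two-bin [GateConfig-class].
#' @export
morphologyGates <- function(cutoff = 0.65) GateConfig(cutoff, c(800, 200))

#' NNK site-saturation variant library
#'
#' All single-codon variants of an 11-codon (33 nt) mutagenized region that
#' are reachable with NNK degenerate codons (positions 1-2 any base, position
#' 3 G or T), together with a ground-truth nucleus-to-cytoplasm ratio per
#' amino-acid change used by the sort simulator.
#'
#' @slot wtDna Character, the 33 nt wild-type coding sequence.
#' @slot variants data.frame with one row per unique nucleotide variant
#'   (plus the wild-type row): \code{nt_seq}, \code{codon_position},
#'   \code{wt_codon}, \code{mut_codon}, \code{wt_aa}, \code{mut_aa},
#'   \code{aa_change}, \code{class} in
#'   \code{{missense, synonymous, nonsense, wildtype}}.
#' @slot trueScore Named numeric, true N:C ratio per \code{aa_change}.
#'
#' @seealso [generateNNKLibrary()]
#' @export
setClass("NNKLibrary",
    representation(wtDna = "character", variants = "data.frame",
                   trueScore = "numeric"))

setValidity("NNKLibrary", function(object) {
    if (length(object@wtDna) != 1L || nchar(object@wtDna) != 33L)
        return("wtDna must be a single 33 nt sequence")
    v <- object@variants
    need <- c("nt_seq", "codon_position", "wt_codon", "mut_codon",
              "wt_aa", "mut_aa", "aa_change", "class")
    if (!all(need %in% names(v))) return("variants is missing columns")
    if (anyDuplicated(v$nt_seq)) return("nucleotide variants must be unique")
    if (!all(v$class %in% c("missense", "synonymous", "nonsense", "wildtype")))
        return("unknown variant class")
    mut <- v[v$class != "wildtype", , drop = FALSE]
    if (nrow(mut)) {
        if (!all(mut$codon_position %in% 1:11))
            return("codon_position out of 1..11")
        third <- substr(mut$mut_codon, 3L, 3L)
        if (!all(third %in% c("G", "T")))
            return("mutant codons must match the NNK pattern")
    }
    if (!all(unique(v$aa_change) %in% names(object@trueScore)))
        return("trueScore must cover every aa_change")
    if (any(object@trueScore <= 0)) return("true N:C ratios must be positive")
    TRUE
})

#' Position-wise amino-acid preference matrix
#'
#' Mean raw localization scores per (position, amino acid), min-max scaled
#' within each position so the best-tolerated residue has preference 1 and
#' the least-tolerated 0. Missing (position, residue) combinations are
#' imputed with the median raw score at that position before scaling.
#'
#' @slot scores 11 x 20 numeric matrix of mean raw scores \code{s[r, a]}
#'   (rows = positions, columns = amino acids) after imputation.
#' @slot preferences 11 x 20 matrix of scaled preferences \code{x[r, a]} in
#'   \code{[0, 1]}.
#' @slot imputed Logical matrix flagging imputed entries.
#'
#' @seealso [positionPreferences()], [scorePeptide()]
#' @export
setClass("PreferenceMatrix",
    representation(scores = "matrix", preferences = "matrix",
                   imputed = "matrix"))

setValidity("PreferenceMatrix", function(object) {
    p <- object@preferences
    if (!identical(dim(p), dim(object@scores)) ||
        !identical(dim(p), dim(object@imputed)))
        return("slot dimensions disagree")
    if (ncol(p) != 20L) return("need 20 amino-acid columns")
    if (anyNA(p)) return("preferences must be fully defined after imputation")
    if (any(p < 0 | p > 1)) return("preferences must lie in [0, 1]")
    rng <- apply(p, 1L, range)
    if (any(abs(rng[1L, ]) > 1e-8) || any(abs(rng[2L, ] - 1) > 1e-8))
        return("each position must attain preference 0 and 1")
    TRUE
})

#' Linear NLS prediction model
#'
#' Least-squares fit of the 0/1 likely-NLS label on the 11 positional
#' preference features (linear probability model): an intercept plus one
#' weight per window position.
#'
#' @slot coefficients Named numeric of length 12: intercept then
#'   \code{pos1..pos11}.
#' @slot cvAUC Out-of-fold area under the ROC curve from k-fold
#'   cross-validation.
#' @slot folds Number of cross-validation folds used.
#' @slot seed Integer seed that fixed the fold assignment.
#'
#' @seealso [fitNLSModel()], [predictNLS()], [scanProteome()]
#' @export
setClass("NLSModel",
    representation(coefficients = "numeric", cvAUC = "numeric",
                   folds = "integer", seed = "integer"))

setValidity("NLSModel", function(object) {
    if (length(object@coefficients) != 12L)
        return("model has an intercept plus 11 position weights")
    if (anyNA(object@coefficients)) return("coefficients must be finite")
    TRUE
})

#' Score cutoffs for NLS calls
#'
#' Two cutoffs on the linear model prediction: a high-confidence cutoff
#' calibrated to precision of about 0.9 and a candidate cutoff calibrated to
#' recall of about 0.9, derived from a held-out test set.
#'
#' @slot highConfidence Numeric cutoff for high-confidence calls.
#' @slot candidate Numeric cutoff for candidate calls.
#' @slot curve data.frame of the full precision-recall sweep
#'   (\code{cutoff}, \code{precision}, \code{recall}).
#'
#' @seealso [calibrateThresholds()]
#' @export
setClass("CallThresholds",
    representation(highConfidence = "numeric", candidate = "numeric",
                   curve = "data.frame"))

setValidity("CallThresholds", function(object) {
    if (length(object@highConfidence) != 1L || length(object@candidate) != 1L)
        return("cutoffs must be scalars")
    if (!is.na(object@highConfidence) && !is.na(object@candidate) &&
        object@highConfidence < object@candidate)
        return("high-confidence cutoff must be >= candidate cutoff")
    TRUE
})

#' Variant localization score table
#'
#' Raw and normalized localization scores per amino-acid variant and
#' replicate, the per-replicate normalization anchors, and the final
#' replicate-aggregated scores.
#'
#' @slot replicateScores data.frame: \code{aa_change}, \code{class},
#'   \code{replicate}, \code{S_raw}, \code{S_norm}.
#' @slot anchors data.frame per replicate: \code{replicate}, \code{S_WT},
#'   \code{S_P10} (median raw score of the bottom decile).
#' @slot final data.frame per variant: \code{aa_change}, \code{class},
#'   \code{mean_score}, \code{se}, \code{n_replicates}, \code{unreliable}.
#' @slot config List of the scoring parameters used.
#'
#' @seealso [scoreVariants()], [finalScores()]
#' @export
setClass("ScoreTable",
    representation(replicateScores = "data.frame", anchors = "data.frame",
                   final = "data.frame", config = "list"))

setValidity("ScoreTable", function(object) {
    rs <- object@replicateScores
    if (!all(c("aa_change", "replicate", "S_raw", "S_norm") %in% names(rs)))
        return("replicateScores is missing columns")
    sr <- rs$S_raw[!is.na(rs$S_raw)]
    if (any(sr < 0.25 - 1e-9 | sr > 1 + 1e-9))
        return("raw scores must lie in [0.25, 1]")
    if (!all(c("S_WT", "S_P10") %in% names(object@anchors)))
        return("anchors is missing columns")
    ok <- stats::complete.cases(object@anchors[, c("S_WT", "S_P10")])
    if (any(object@anchors$S_WT[ok] <= object@anchors$S_P10[ok]))
        return("degenerate normalization: S_WT must exceed S_P10")
    TRUE
})
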