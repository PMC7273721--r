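#' @rdname GateConfig-class
#' @param object,x A \code{GateConfig}, \code{NNKLibrary},
#'   \code{PreferenceMatrix}, \code{NLSModel} or \code{ScoreTable} object.
#' @export
setGeneric("gateBoundaries", function(x) standardGeneric("gateBoundaries"))

#' @rdname GateConfig-class
#' @export
setGeneric("gateDurations", function(x) standardGeneric("gateDurations"))

#' @rdname GateConfig-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname NNKLibrary-class
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname NNKLibrary-class
#' @export
setGeneric("trueScores", function(x) standardGeneric("trueScores"))

#' @rdname NNKLibrary-class
#' @export
setGeneric("wtSequence", function(x) standardGeneric("wtSequence"))

#' @rdname PreferenceMatrix-class
#' @export
setGeneric("preferences", function(x) standardGeneric("preferences"))

#' @rdname PreferenceMatrix-class
#' @export
setGeneric("rawPreferenceScores",
    function(x) standardGeneric("rawPreferenceScores"))

#' @rdname ScoreTable-class
#' @export
setGeneric("replicateScores", function(x) standardGeneric("replicateScores"))

#' @rdname ScoreTable-class
#' @export
setGeneric("finalScores", function(x) standardGeneric("finalScores"))

#' @rdname ScoreTable-class
#' @export
setGeneric("scoreAnchors", function(x) standardGeneric("scoreAnchors"))

setMethod("gateBoundaries", "GateConfig", function(x) x@boundaries)
setMethod("gateDurations", "GateConfig", function(x) x@durations)
setMethod("nBins", "GateConfig", function(x) length(x@durations))

setMethod("variants", "NNKLibrary", function(x) x@variants)
setMethod("trueScores", "NNKLibrary", function(x) x@trueScore)
setMethod("wtSequence", "NNKLibrary", function(x) x@wtDna)

setMethod("preferences", "PreferenceMatrix", function(x) x@preferences)
setMethod("rawPreferenceScores", "PreferenceMatrix", function(x) x@scores)

setMethod("replicateScores", "ScoreTable", function(x) x@replicateScores)
setMethod("finalScores", "ScoreTable", function(x) x@final)
setMethod("scoreAnchors", "ScoreTable", function(x) x@anchors)

#' @describeIn NLSModel-class Model coefficients (intercept, pos1..pos11).
#' @param object An \code{NLSModel}.
#' @param ... Ignored.
#' @export
setMethod("coef", "NLSModel", function(object, ...) object@coefficients)

setMethod("show", "GateConfig", function(object) {
    cat("GateConfig with", nBins(object), "bins\n")
    lo <- c(-Inf, object@boundaries)
    hi <- c(object@boundaries, Inf)
    for (i in seq_along(object@durations))
        cat(sprintf("  bin %d: [%.4g, %.4g) -> %g ms\n",
                    i, lo[i], hi[i], object@durations[i]))
})

setMethod("show", "NNKLibrary", function(object) {
    v <- object@variants
    cat("NNKLibrary over", nchar(object@wtDna) / 3L, "codons\n")
    cat("  wt:", object@wtDna, "\n")
    tab <- table(factor(v$class,
        levels = c("wildtype", "synonymous", "missense", "nonsense")))
    cat(sprintf("  %d nucleotide variants (%s)\n", nrow(v),
        paste(names(tab), tab, sep = ": ", collapse = ", ")))
    cat(sprintf("  %d distinct amino-acid changes with true N:C in [%.2f, %.2f]\n",
        length(unique(v$aa_change)), min(object@trueScore),
        max(object@trueScore)))
})

setMethod("show", "PreferenceMatrix", function(object) {
    cat(sprintf("PreferenceMatrix: %d positions x %d amino acids (%d imputed)\n",
        nrow(object@preferences), ncol(object@preferences),
        sum(object@imputed)))
})

setMethod("show", "NLSModel", function(object) {
    cat("NLSModel (linear probability model, 11 positions)\n")
    cat(sprintf("  %d-fold CV AUC: %.3f\n", object@folds, object@cvAUC))
    print(round(object@coefficients, 4))
})

setMethod("show", "CallThresholds", function(object) {
    cat(sprintf("CallThresholds: high-confidence >= %.4g, candidate >= %.4g\n",
        object@highConfidence, object@candidate))
})

setMethod("show", "ScoreTable", function(object) {
    f <- object@final
    cat(sprintf("ScoreTable: %d amino-acid variants, %d replicates\n",
        nrow(f), length(unique(object@replicateScores$replicate))))
    if (nrow(f))
        cat(sprintf("  %d unreliable (scored in < %d replicates)\n",
            sum(f$unreliable),
            object@config$min_replicates %||% 2L))
})
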