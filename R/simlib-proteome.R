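#' Simulate an annotated proteome with planted NLS motifs
#'
#' Generates random protein sequences from background amino-acid
#' frequencies; "nuclear" proteins receive one planted 11-mer sampled
#' from the high-preference residues of each position (with a tunable
#' per-position corruption probability), annotated as an NLS span.
#' Cytoplasmic proteins carry no planted motif. Used to exercise
#' training-set construction, threshold calibration and proteome
#' scanning with known ground truth.
#'
#' @param prefs A [PreferenceMatrix-class] defining the motif.
#' @param n_nuclear,n_cytoplasmic Protein counts per compartment.
#' @param length Protein length (residues).
#' @param motif_noise Probability a planted position is replaced by a
#'   random residue (default 0.15).
#' @param top_k Residues per position the motif samples from, ranked by
#'   preference (default 2).
#' @param seed Integer seed.
#' @return List: \code{sequences} (named character),
#'   \code{annotations} (data.frame \code{protein_id}, \code{start},
#'   \code{end}), \code{compartment} (named character,
#'   \code{"nuclear"} or \code{"cytoplasmic"}).
#' @export
simulateProteome <- function(prefs, n_nuclear = 30L, n_cytoplasmic = 30L,
                             length = 200L, motif_noise = 0.15,
                             top_k = 2L, seed = 1L) {
    stopIfNot(length >= 15L, "proteins must be at least 15 residues")
    p <- preferences(prefs)
    withSeed(seed, {
        n <- n_nuclear + n_cytoplasmic
        ids <- sprintf("prot%03d", seq_len(n))
        comp <- rep(c("nuclear", "cytoplasmic"),
                    c(n_nuclear, n_cytoplasmic))
        seqs <- vapply(seq_len(n), function(i)
            paste(sample(AA20, length, replace = TRUE), collapse = ""),
            character(1L))
        ann <- NULL
        for (i in which(comp == "nuclear")) {
            motif <- vapply(1:11, function(r) {
                ranked <- AA20[order(p[r, ], decreasing = TRUE)]
                if (stats::runif(1) < motif_noise) sample(AA20, 1L)
                else sample(ranked[seq_len(top_k)], 1L)
            }, character(1L))
            start <- sample(seq_len(length - 10L), 1L)
            substr(seqs[i], start, start + 10L) <-
                paste(motif, collapse = "")
            ann <- rbind(ann, data.frame(protein_id = ids[i],
                start = start, end = start + 10L,
                stringsAsFactors = FALSE))
        }
        list(sequences = stats::setNames(seqs, ids), annotations = ann,
             compartment = stats::setNames(comp, ids))
    })
}
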