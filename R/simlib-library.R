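#' Enumerate an NNK site-saturation library over an 11-codon region
#'
#' Builds every single-codon substitution of the 33 nt wild-type region that
#' is reachable with an NNK degenerate codon (first two positions any base,
#' third position G or T), collapses duplicate nucleotide sequences, assigns
#' each variant a class by translation, and attaches a ground-truth
#' nucleus-to-cytoplasm (N:C) ratio per amino-acid change for use by the
#' sort simulator. For a generic 11-mer the missense amino-acid change set
#' has exactly 11 x 19 = 209 members.
#'
#' Ground truth: the wild type and all synonymous variants share
#' \code{wt_nc}; nonsense variants get the bottom of \code{nc_range}
#' (a truncated reporter that no longer concentrates in the nucleus);
#' missense changes draw independently and uniformly from \code{nc_range},
#' reproducing the broad range of localization phenotypes a saturation
#' mutagenesis of a strong NLS produces.
#'
#' @param wt_dna 33 nt coding sequence (11 codons) of the mutagenized
#'   region; must not contain an in-frame stop codon.
#' @param wt_nc True N:C ratio of the wild-type NLS (default 1.40, above the
#'   top sort gate).
#' @param nc_range Range from which missense true N:C ratios are drawn.
#' @param seed Integer seed fixing the missense ground truth.
#' @return An [NNKLibrary-class] object.
#' @examples
#' lib <- generateNNKLibrary(svNLSRegion())
#' table(variants(lib)$class)
#' @export
generateNNKLibrary <- function(wt_dna, wt_nc = 1.40,
                               nc_range = c(0.85, 1.55), seed = 1L) {
    stopIfNot(is.character(wt_dna) && length(wt_dna) == 1L,
              "wt_dna must be a single character string")
    wt_dna <- toupper(wt_dna)
    stopIfNot(nchar(wt_dna) == 33L, "wt_dna must be 33 nucleotides (11 codons)")
    stopIfNot(!grepl("[^ACGT]", wt_dna), "wt_dna contains invalid bases")
    wt_codons <- substring(wt_dna, seq(1L, 31L, 3L), seq(3L, 33L, 3L))
    wt_aas <- translateCodon(wt_codons)
    stopIfNot(!any(wt_aas == "*"), "wt_dna contains an in-frame stop codon")

    nnk <- nnkCodons()
    rows <- vector("list", 11L)
    for (pos in 1:11) {
        mut <- setdiff(nnk, wt_codons[pos])
        aa <- translateCodon(mut)
        nt <- vapply(mut, function(cd) {
            cs <- wt_codons; cs[pos] <- cd; paste(cs, collapse = "")
        }, character(1L))
        cls <- ifelse(aa == "*", "nonsense",
               ifelse(aa == wt_aas[pos], "synonymous", "missense"))
        aa_change <- ifelse(cls == "synonymous",
            paste0(wt_aas[pos], pos, wt_aas[pos]),
            paste0(wt_aas[pos], pos, aa))
        rows[[pos]] <- data.frame(nt_seq = unname(nt), codon_position = pos,
            wt_codon = wt_codons[pos], mut_codon = mut, wt_aa = wt_aas[pos],
            mut_aa = aa, aa_change = aa_change, class = cls,
            stringsAsFactors = FALSE, row.names = NULL)
    }
    v <- do.call(rbind, rows)
    v <- rbind(data.frame(nt_seq = wt_dna, codon_position = NA_integer_,
        wt_codon = NA_character_, mut_codon = NA_character_,
        wt_aa = NA_character_, mut_aa = NA_character_, aa_change = "WT",
        class = "wildtype", stringsAsFactors = FALSE), v)
    v <- v[!duplicated(v$nt_seq), , drop = FALSE]
    rownames(v) <- NULL

    aa_changes <- unique(v$aa_change)
    truth <- withSeed(seed, {
        ts <- stats::setNames(rep(NA_real_, length(aa_changes)), aa_changes)
        cls1 <- v$class[match(aa_changes, v$aa_change)]
        ts[cls1 %in% c("wildtype", "synonymous")] <- wt_nc
        ts[cls1 == "nonsense"] <- min(nc_range)
        nm <- cls1 == "missense"
        ts[nm] <- stats::runif(sum(nm), nc_range[1L], nc_range[2L])
        ts
    })
    new("NNKLibrary", wtDna = wt_dna, variants = v, trueScore = truth)
}

#' Default wild-type sequence for the mutagenized NLS region
#'
#' A documented stand-in 33 nt sequence encoding the 11-residue region
#' around the classic monopartite SV40 large-T NLS
#' (\code{S-T-P-P-K-K-K-R-K-V-E}), built from common human codons. The
#' screen's exact construct sequence is a cloning detail; every generator
#' takes \code{wt_dna} as input, so real construct sequences drop in
#' directly.
#'
#' @return A 33-character DNA string.
#' @examples
#' Biostrings::translate(Biostrings::DNAString(svNLSRegion()))
#' @export
svNLSRegion <- function() {
    # S   T   P   P   K   K   K   R   K   V   E
    paste0("AGC", "ACC", "CCT", "CCT", "AAG", "AAG", "AAG",
           "CGG", "AAG", "GTG", "GAG")
}
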