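`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression under a local RNG state; NULL seed leaves the global
# stream untouched so callers can manage randomness themselves.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
    expr
}

# Derive a reproducible child seed from a parent seed and a stage tag,
# keeping the result inside the 32-bit integer range.
deriveSeed <- function(seed, tag) {
    if (is.null(seed)) return(NULL)
    h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
    as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

translateCodon <- function(codon) {
    unname(Biostrings::GENETIC_CODE[codon])
}

# All 32 NNK codons: N at positions 1-2, K = G/T at position 3.
nnkCodons <- function() {
    b <- c("A", "C", "G", "T")
    as.vector(outer(outer(b, b, paste0), c("G", "T"), paste0))
}

isNNKCodon <- function(codon) {
    nchar(codon) == 3L &
        substr(codon, 3L, 3L) %in% c("G", "T") &
        !grepl("[^ACGT]", codon)
}

# Rank-based AUC of scores for a binary label.
aucScore <- function(score, label) {
    label <- as.logical(label)
    n1 <- sum(label); n0 <- sum(!label)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(score)
    (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
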