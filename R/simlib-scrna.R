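#' Specification for a synthetic single-cell RNA-seq experiment
#'
#' Defines a negative-binomial UMI count simulation with log-normal
#' library sizes, cell-cycle gene programs, and a planted
#' lobulation-linked program: per-gene counts have mean
#' \code{library_size x gene_rate x 2^(effect x lobulation_score) x
#' cycle_multiplier}.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param median_umi Median per-cell total UMI count (default 9249,
#'   matching a downsampled 10x experiment).
#' @param libsize_sdlog SD of log library size.
#' @param rate_sdlog SD of log baseline gene rates.
#' @param dispersion NB dispersion (1/size); variance is
#'   \code{mu + dispersion * mu^2}.
#' @param fraction_lobulated Fraction of cells with lobulated nuclei
#'   (default 0.3).
#' @param lob_score_sd SD of the continuous true lobulation score around
#'   its class mean (0 for normal, 1 for lobulated cells).
#' @param effect_log2 Per-gene log2 effect of the lobulation score, or
#'   \code{NULL} to plant \code{n_program_genes} genes at alternating
#'   \code{+/- program_log2fc} (remaining genes 0).
#' @param n_program_genes,program_log2fc Default planted program.
#' @param n_cycle_genes Genes per cell-cycle program (G1, S, G2M).
#' @param cycle_log2fc log2 elevation of a program in its phase.
#' @param phase_prob Phase probabilities for G1, S, G2M.
#' @param seed Integer seed.
#' @return A validated spec list.
#' @export
scSimSpec <- function(n_cells = 2000L, n_genes = 2000L, median_umi = 9249,
                      libsize_sdlog = 0.35, rate_sdlog = 1.5,
                      dispersion = 0.4, fraction_lobulated = 0.3,
                      lob_score_sd = 0.15, effect_log2 = NULL,
                      n_program_genes = 40L, program_log2fc = 0.5,
                      n_cycle_genes = 25L, cycle_log2fc = 1.5,
                      phase_prob = c(G1 = 0.5, S = 0.25, G2M = 0.25),
                      seed = 1L) {
    stopIfNot(median_umi > 0 && dispersion > 0 && rate_sdlog >= 0,
              "rates and dispersion must be positive")
    stopIfNot(fraction_lobulated >= 0 && fraction_lobulated <= 1,
              "fraction_lobulated must be in [0, 1]")
    if (!is.null(effect_log2))
        stopIfNot(length(effect_log2) == n_genes,
                  "effect_log2 must have one entry per gene")
    stopIfNot(3L * n_cycle_genes + n_program_genes <= n_genes,
              "programs exceed the gene count")
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         median_umi = median_umi, libsize_sdlog = libsize_sdlog,
         rate_sdlog = rate_sdlog, dispersion = dispersion,
         fraction_lobulated = fraction_lobulated,
         lob_score_sd = lob_score_sd, effect_log2 = effect_log2,
         n_program_genes = as.integer(n_program_genes),
         program_log2fc = program_log2fc,
         n_cycle_genes = as.integer(n_cycle_genes),
         cycle_log2fc = cycle_log2fc, phase_prob = phase_prob,
         seed = as.integer(seed))
}

#' Simulate UMI counts with a planted lobulation program
#'
#' Generates a [SingleCellExperiment::SingleCellExperiment] whose
#' \code{counts} assay holds NB-distributed UMIs. Column data carry the
#' per-cell ground truth (\code{lobulated}, \code{true_lob_score},
#' \code{phase}, \code{total_umi}); row data the planted per-gene
#' \code{effect_log2} and cycle-program membership; metadata the cycle
#' gene sets and the spec.
#'
#' @param spec An [scSimSpec()] list; its \code{seed} drives all draws.
#' @return A \code{SingleCellExperiment}.
#' @examples
#' sce <- simulateScRNA(scSimSpec(n_cells = 50, n_genes = 100,
#'                                median_umi = 500))
#' table(sce$phase)
#' @export
simulateScRNA <- function(spec) {
    withSeed(spec$seed, {
        ng <- spec$n_genes; nc <- spec$n_cells
        genes <- sprintf("gene%04d", seq_len(ng))
        rate <- stats::rlnorm(ng, 0, spec$rate_sdlog)
        rate <- rate / sum(rate)
        lib <- stats::rlnorm(nc, 0, spec$libsize_sdlog)
        lib <- lib / stats::median(lib) * spec$median_umi

        cyc_idx <- list(
            G1 = seq_len(spec$n_cycle_genes),
            S = spec$n_cycle_genes + seq_len(spec$n_cycle_genes),
            G2M = 2L * spec$n_cycle_genes + seq_len(spec$n_cycle_genes))
        prog_idx <- 3L * spec$n_cycle_genes + seq_len(spec$n_program_genes)

        effect <- spec$effect_log2
        if (is.null(effect)) {
            effect <- numeric(ng)
            if (spec$n_program_genes > 0L)
                effect[prog_idx] <- spec$program_log2fc *
                    rep_len(c(1, -1), spec$n_program_genes)
        }

        lob <- stats::runif(nc) < spec$fraction_lobulated
        lob_score <- as.numeric(lob) + stats::rnorm(nc, 0, spec$lob_score_sd)
        phase <- sample(names(spec$phase_prob), nc, replace = TRUE,
                        prob = spec$phase_prob)

        cyc_mult <- matrix(1, ng, nc)
        for (ph in names(cyc_idx))
            cyc_mult[cyc_idx[[ph]], phase == ph] <- 2^spec$cycle_log2fc

        mu <- outer(rate, lib) * 2^(outer(effect, lob_score)) * cyc_mult
        counts <- matrix(stats::rnbinom(ng * nc, mu = mu,
                                        size = 1 / spec$dispersion), ng, nc)
        dimnames(counts) <- list(genes, sprintf("cell%04d", seq_len(nc)))

        cycle_sets <- lapply(cyc_idx, function(i) genes[i])
        sce <- SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(
                lobulated = lob, true_lob_score = lob_score, phase = phase,
                total_umi = colSums(counts)),
            rowData = S4Vectors::DataFrame(
                effect_log2 = effect,
                cycle_program = {
                    cp <- rep(NA_character_, ng)
                    for (ph in names(cyc_idx)) cp[cyc_idx[[ph]]] <- ph
                    cp
                },
                lob_program = seq_len(ng) %in% prog_idx))
        S4Vectors::metadata(sce) <- list(cycle_sets = cycle_sets,
                                         spec = spec)
        sce
    })
}
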