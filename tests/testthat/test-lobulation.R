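test_that("PCA coordinates are deterministic and ordered by variance", {
    sce <- simulateScRNA(scSimSpec(n_cells = 120, n_genes = 200,
                                   median_umi = 800, seed = 4))
    pca <- normalizePCA(sce, n_pcs = 10)
    expect_true(all(diff(pca$var_explained) <= 1e-12))
    # two identical cells map to identical coordinates
    counts <- SummarizedExperiment::assay(sce)
    counts <- cbind(counts, dup1 = counts[, 1], dup2 = counts[, 1])
    p2 <- normalizePCA(counts, n_pcs = 5)
    expect_equal(p2$pcs["dup1", ], p2$pcs["dup2", ])
    expect_error(normalizePCA(matrix(3, 10, 10)), "constant")
})

test_that("planted expression programs separate along the leading PCs", {
    sce <- simulateScRNA(scSimSpec(n_cells = 600, n_genes = 300,
        median_umi = 3000, n_program_genes = 40L, program_log2fc = 1,
        n_cycle_genes = 0L, phase_prob = c(G1 = 1, S = 0, G2M = 0),
        seed = 8))
    pca <- normalizePCA(sce, n_pcs = 5)
    auc <- max(vapply(1:2, function(j)
        max(vcsort:::aucScore(pca$pcs[, j], sce$lobulated),
            1 - vcsort:::aucScore(pca$pcs[, j], sce$lobulated)),
        numeric(1)))
    expect_gt(auc, 0.95)
})

test_that("cell-cycle scores track the simulated phase programs", {
    sce <- simulateScRNA(scSimSpec(n_cells = 900, n_genes = 300,
                                   median_umi = 2500, seed = 10))
    sets <- S4Vectors::metadata(sce)$cycle_sets
    cyc <- cellCycleScores(sce, sets)
    g2m_cells <- sce$phase == "G2M"
    expect_gte(mean(cyc$scores[g2m_cells, "G2M"] >
                    cyc$scores[g2m_cells, "G1"]), 0.9)
    # phase proportions on a 50/50 G1/G2M mix recover the mix
    sce2 <- simulateScRNA(scSimSpec(n_cells = 900, n_genes = 300,
        median_umi = 2500, phase_prob = c(G1 = 0.5, S = 0, G2M = 0.5),
        seed = 11))
    cyc2 <- cellCycleScores(sce2, S4Vectors::metadata(sce2)$cycle_sets)
    expect_equal(mean(cyc2$phase == "G2M"), 0.5, tolerance = 0.1)
    # a set with expression matching its control scores near zero
    flat <- matrix(rpois(300 * 100, 20), 300, 100,
                   dimnames = list(sprintf("g%03d", 1:300), NULL))
    sc <- cellCycleScores(flat, list(S = sprintf("g%03d", 1:20)))
    expect_lt(mean(abs(sc$scores[, "S"])), 0.05)
    expect_error(cellCycleScores(flat, list(S = sprintf("h%03d", 1:20))),
                 "missing")
})

test_that("the logistic lobulation model recovers known coefficients", {
    set.seed(15)
    n <- 5000
    pcs <- matrix(rnorm(n * 4), n, 4)
    beta <- c(-0.5, 1.2, -0.8, 0.5, 0)
    p <- 1 / (1 + exp(-(beta[1] + pcs %*% beta[-1])))
    y <- runif(n) < p
    fit <- fitLobulationModel(pcs, y)
    se <- sqrt(diag(vcov(fit$fit)))
    expect_true(all(abs(fit$coefficients - beta) <= 2 * se))
})

test_that("null labels give near-zero slope coefficients", {
    set.seed(16)
    pcs <- matrix(rnorm(800 * 4), 800, 4)
    y <- runif(800) < 0.4
    fit <- fitLobulationModel(pcs, y)
    z <- summary(fit$fit)$coefficients[-1, "z value"]
    expect_gte(sum(abs(z) < 2), 3)
})

test_that("separable labels trigger the ridge fallback cleanly", {
    pcs <- matrix(rnorm(200 * 4), 200, 4)
    y <- pcs[, 1] > 0
    expect_warning(fit <- fitLobulationModel(pcs, y), "separation")
    expect_true(fit$ridge)
    expect_gt(fit$auc, 0.99)
})

test_that("lobulation scores order classes and ignore unused PCs", {
    set.seed(18)
    pcs <- matrix(rnorm(600 * 6), 600, 6)
    y <- runif(600) < 1 / (1 + exp(-2 * pcs[, 2]))
    fit <- fitLobulationModel(pcs[, 1:4], y)
    s4 <- lobulationScore(fit, pcs[, 1:4])
    s6 <- lobulationScore(fit, pcs)          # extra PCs ignored
    expect_equal(s4, s6)
    expect_gt(mean(s4[y]), mean(s4[!y]))
    expect_error(lobulationScore(fit, pcs[, 1:3]), "four")
})

test_that("the NB test absorbs sequencing depth through its offset", {
    set.seed(20)
    n <- 500
    tot <- round(rlnorm(n, log(2000), 0.5))
    lob <- rnorm(n)
    # one gene proportional to depth only, one truly lobulation-linked
    g_depth <- rpois(n, 0.01 * tot)
    g_lob <- rnbinom(n, mu = 0.01 * tot * 2^(0.5 * lob), size = 5)
    filler <- t(sapply(1:30, function(i) rpois(n, 0.03 * tot)))
    mat <- rbind(depth_gene = g_depth, lob_gene = g_lob, filler)
    rownames(mat) <- c("depth_gene", "lob_gene",
                       sprintf("f%02d", 1:30))
    de <- lobulationDE(mat, lob, rnorm(n, 0, 0.1), rnorm(n, 0, 0.1))
    expect_lt(abs(de$effect_size[de$gene == "depth_gene"]), 0.05)
    expect_equal(de$effect_size[de$gene == "lob_gene"], 0.5,
                 tolerance = 0.15)
    expect_true(all(de$q >= de$p, na.rm = TRUE))
})

test_that("DE results are invariant to gene order and BH is monotone", {
    sce <- simulateScRNA(scSimSpec(n_cells = 300, n_genes = 120,
                                   median_umi = 1000, seed = 21))
    cyc <- cellCycleScores(sce, S4Vectors::metadata(sce)$cycle_sets)
    mat <- SummarizedExperiment::assay(sce)
    de1 <- lobulationDE(mat, sce$true_lob_score, cyc$scores[, "G1"],
                        cyc$scores[, "G2M"])
    perm <- sample(nrow(mat))
    de2 <- lobulationDE(mat[perm, ], sce$true_lob_score,
                        cyc$scores[, "G1"], cyc$scores[, "G2M"])
    m <- merge(de1, de2, by = "gene")
    expect_equal(m$effect_size.x, m$effect_size.y)
    ok <- de1$converged
    expect_true(all(diff(de1$q[ok][order(de1$p[ok])]) >= -1e-12))
})

test_that("over-representation matches the closed-form hypergeometric", {
    universe <- sprintf("g%02d", 1:25)
    deg <- universe[1:5]
    sets <- list(inside = universe[1:8], outside = universe[20:25],
                 disjoint = universe[10:15])
    out <- overrepresentation(deg, sets, universe)
    expect_equal(out$p[out$set == "inside"],
                 hyperOracle(5, 8, 25, 5))
    expect_equal(out$p[out$set == "disjoint"], 1)
    # DEG list fully inside one small set: minimum achievable p
    expect_lt(out$p[out$set == "inside"], out$p[out$set == "outside"])
    expect_error(overrepresentation(c("zz"), sets, universe), "universe")
    expect_warning(out0 <- overrepresentation(character(0), sets,
                                              universe), "empty")
    expect_equal(nrow(out0), 0L)
})

test_that("over-representation p-values match brute-force enumeration", {
    set.seed(25)
    universe <- sprintf("u%02d", 1:20)
    for (i in 1:10) {
        deg <- sample(universe, sample(3:8, 1))
        set <- sample(universe, sample(3:10, 1))
        out <- overrepresentation(deg, list(s = set), universe)
        expect_equal(out$p,
                     hyperOracle(out$overlap, length(set), 20,
                                 length(deg)))
    }
})

test_that("the full expression stage recovers planted effect ordering", {
    sce <- simulateScRNA(scSimSpec(n_cells = 1200, n_genes = 200,
        median_umi = 4000,
        effect_log2 = round(seq(-0.8, 0.8, length.out = 200), 3),
        n_program_genes = 0L, n_cycle_genes = 20L, seed = 28))
    pca <- normalizePCA(sce)
    cyc <- cellCycleScores(sce, S4Vectors::metadata(sce)$cycle_sets)
    half <- seq_len(600)
    fit <- suppressWarnings(fitLobulationModel(
        pca$pcs[half, , drop = FALSE], sce$lobulated[half]))
    lsc <- lobulationScore(fit, pca$pcs)
    # scale the score to the truth's units before effect comparison
    lsc <- (lsc - mean(lsc[!sce$lobulated])) /
        (mean(lsc[sce$lobulated]) - mean(lsc[!sce$lobulated]))
    de <- lobulationDE(sce, lsc, cyc$scores[, "G1"], cyc$scores[, "G2M"])
    ok <- de$converged
    planted <- SummarizedExperiment::rowData(sce)$effect_log2
    expect_gt(cor(planted[ok], de$effect_size[ok], method = "spearman"),
              0.8)
})
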