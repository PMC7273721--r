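test_that("NNK library enumeration has the expected combinatorics", {
    lib <- generateNNKLibrary(fixtureWT())
    v <- variants(lib)
    # 11 positions x 19 substitutions
    expect_equal(length(unique(v$aa_change[v$class == "missense"])), 209L)
    # wt codons that are themselves NNK-patterned: 32 NNK codons minus wt
    wt_nnk <- paste(rep("AAG", 11), collapse = "")
    v2 <- variants(generateNNKLibrary(wt_nnk))
    expect_equal(sum(v2$class != "wildtype"), 11L * 31L)
    # Lys codon AAA admits a single synonymous NNK codon (AAG) per position
    v3 <- variants(generateNNKLibrary(paste(rep("AAA", 11), collapse = "")))
    expect_equal(sum(v3$class == "synonymous"), 11L)
})

test_that("NNK library variants obey the single-codon NNK invariants", {
    lib <- generateNNKLibrary(fixtureWT())
    v <- variants(lib)
    mut <- v[v$class != "wildtype", ]
    expect_false(anyDuplicated(v$nt_seq) > 0)
    expect_true(all(substr(mut$mut_codon, 3, 3) %in% c("G", "T")))
    wt_codons <- substring(fixtureWT(), seq(1, 31, 3), seq(3, 33, 3))
    for (i in sample(nrow(mut), 25)) {
        cs <- substring(mut$nt_seq[i], seq(1, 31, 3), seq(3, 33, 3))
        expect_equal(sum(cs != wt_codons), 1L)
        expect_equal(which(cs != wt_codons), mut$codon_position[i])
    }
    expect_setequal(unique(v$class),
                    c("wildtype", "synonymous", "missense", "nonsense"))
})

test_that("library generation rejects invalid input", {
    expect_error(generateNNKLibrary("ACGT"), "33 nucleotides")
    expect_error(generateNNKLibrary(paste(rep("ACX", 11), collapse = "")),
                 "invalid bases")
    expect_error(generateNNKLibrary(paste(c("TAA", rep("AAA", 10)),
                                          collapse = "")), "stop codon")
})

test_that("generators are pure functions of spec and seed", {
    a <- generateNNKLibrary(fixtureWT(), seed = 42)
    b <- generateNNKLibrary(fixtureWT(), seed = 42)
    expect_identical(trueScores(a), trueScores(b))
    lib <- generateNNKLibrary(fixtureWT())
    s1 <- simulateSortExperiment(lib, n_cells_per_variant = 30, seed = 9)
    s2 <- simulateSortExperiment(lib, n_cells_per_variant = 30, seed = 9)
    expect_identical(s1, s2)
    e1 <- simulateScRNA(scSimSpec(n_cells = 30, n_genes = 120,
                                  median_umi = 300, seed = 3))
    e2 <- simulateScRNA(scSimSpec(n_cells = 30, n_genes = 120,
                                  median_umi = 300, seed = 3))
    expect_identical(SummarizedExperiment::assay(e1),
                     SummarizedExperiment::assay(e2))
})

test_that("sort simulation conserves cells and reads", {
    lib <- generateNNKLibrary(fixtureWT())
    sim <- simulateSortExperiment(lib, n_cells_per_variant = 40,
        n_replicates = 2, depth_per_bin = 5000, seed = 2)
    # reads per bin sum to configured depth
    per_bin <- tapply(sim$counts$count,
                      paste(sim$counts$replicate, sim$counts$bin), sum)
    expect_true(all(per_bin == 5000))
    # cells per variant sum to cells seeded
    cell_cols <- grep("cells_bin", names(sim$truth))
    expect_true(all(rowSums(sim$truth[, cell_cols]) == 40))
})

test_that("zero-noise cells land deterministically below the lowest gate", {
    lib <- generateNNKLibrary(fixtureWT(), wt_nc = 0.5,
                              nc_range = c(0.5, 0.5))
    sim <- simulateSortExperiment(lib, n_cells_per_variant = 25,
        noise = sortNoise(0, 0, 0, 0, 0), depth_per_bin = NULL, seed = 1)
    expect_true(all(sim$truth$cells_bin1 == 25))
    expect_true(all(sim$counts$count[sim$counts$bin > 1] == 0))
})

test_that("sort gates reject non-increasing boundaries", {
    expect_error(GateConfig(c(1.2, 1.0, 1.4)), "strictly increasing")
    expect_error(GateConfig(c(1, 2), durations = c(0, 50)),
                 "one duration per interval")
})

test_that("rendered nuclei match their configured intensities exactly", {
    nuc <- data.frame(cx = c(40, 110, 180, 40, 120),
                      cy = c(40, 60, 40, 150, 160),
                      shape = "ellipse", a = 14, b = 10, angle = 0,
                      nc = 1.5)
    spec <- syntheticImageSpec(width = 224, height = 224, nuclei = nuc,
                               noise_sd = 0)
    img <- renderNucleiImage(spec, seed = 1)
    expect_equal(max(img$mask), 5L)
    expect_equal(nrow(img$truth), 5L)
    for (i in 1:5) {
        nucmean <- mean(img$reporter[img$mask == i])
        expect_equal(nucmean / spec$reporter_cyt_mean, 1.5)
    }
})

test_that("four-lobed generating outlines score below the lobulation gate", {
    nuc <- data.frame(cx = 60, cy = 60, shape = "lobed", n_lobes = 4,
                      core_r = 7, lobe_r = 4.5, lobe_d = 10, nc = 1)
    spec <- syntheticImageSpec(width = 120, height = 120, nuclei = nuc)
    img <- renderNucleiImage(spec, seed = 1)
    expect_lt(img$truth$true_sf, 0.65)
})

test_that("a blank image spec yields an empty truth table", {
    spec <- syntheticImageSpec(width = 64, height = 64,
                               nuclei = data.frame())
    img <- renderNucleiImage(spec, seed = 1)
    expect_equal(nrow(img$truth), 0L)
    expect_true(all(img$mask == 0L))
    expect_true(all(abs(img$nuclear - spec$background_mean) < 1e-9))
})

test_that("overlapping nuclei are a generation error", {
    nuc <- data.frame(cx = c(50, 55), cy = c(50, 52), shape = "ellipse",
                      a = 14, b = 10, angle = 0, nc = 1)
    spec <- syntheticImageSpec(width = 120, height = 120, nuclei = nuc)
    expect_error(renderNucleiImage(spec), "overlap")
})

test_that("doubling library size doubles expected total counts", {
    s1 <- simulateScRNA(scSimSpec(n_cells = 150, n_genes = 150,
                                  median_umi = 400, seed = 5))
    s2 <- simulateScRNA(scSimSpec(n_cells = 150, n_genes = 150,
                                  median_umi = 800, seed = 5))
    ratio <- mean(s2$total_umi) / mean(s1$total_umi)
    expect_gt(ratio, 1.85)
    expect_lt(ratio, 2.15)
})

test_that("null single-cell simulations give uniform DE p-values", {
    sce <- simulateScRNA(scSimSpec(n_cells = 600, n_genes = 500,
        median_umi = 1500, effect_log2 = rep(0, 500),
        n_program_genes = 0L, seed = 17))
    cyc <- cellCycleScores(sce, S4Vectors::metadata(sce)$cycle_sets)
    de <- lobulationDE(sce, sce$true_lob_score, cyc$scores[, "G1"],
                       cyc$scores[, "G2M"])
    p <- de$p[de$converged]
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted expression programs dominate the DE ranking", {
    sce <- simulateScRNA(scSimSpec(n_cells = 2000, n_genes = 500,
        median_umi = 5000, rate_sdlog = 1.0, n_program_genes = 20L,
        program_log2fc = 0.5, seed = 23))
    cyc <- cellCycleScores(sce, S4Vectors::metadata(sce)$cycle_sets)
    de <- lobulationDE(sce, sce$true_lob_score, cyc$scores[, "G1"],
                       cyc$scores[, "G2M"])
    planted <- SummarizedExperiment::rowData(sce)$lob_program
    qr <- rank(de$q) / nrow(de)
    expect_true(all(qr[planted] <= 0.05))
})

test_that("simulated proteomes plant annotated high-preference motifs", {
    prefs <- toyPrefs()
    pr <- simulateProteome(prefs, n_nuclear = 5, n_cytoplasmic = 5,
                           length = 80, motif_noise = 0, seed = 2)
    expect_equal(nrow(pr$annotations), 5L)
    for (i in seq_len(nrow(pr$annotations))) {
        ann <- pr$annotations[i, ]
        pep <- substr(pr$sequences[[ann$protein_id]], ann$start, ann$end)
        # top-2 residues of toyPrefs score 1 or 0.5 per position
        expect_gte(scorePeptide(pep, prefs), 5.5)
    }
})
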