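# write a tsv artifact and return its manifest row
.writeArtifact <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    data.frame(file = basename(path),
               md5 = unname(tools::md5sum(path)),
               stringsAsFactors = FALSE)
}

#' Run the variant-screen pipeline end to end
#'
#' Generates (or loads) an NNK library, simulates the photoactivation
#' bin-sort, scores variants, derives position-wise preferences, fits
#' the linear NLS model on a simulated annotated proteome, calibrates
#' call thresholds on a held-out proteome and scans it. All stage seeds
#' derive from the global seed, so identical configs give byte-identical
#' artifacts; a manifest with MD5 hashes is written alongside them.
#'
#' @param config Named list (or path to a YAML file readable by
#'   [readRunConfig()]). Recognized entries, all optional except
#'   \code{seed}: \code{wt_dna}, \code{n_cells_per_variant},
#'   \code{n_replicates}, \code{depth_per_bin}, \code{noise} (list for
#'   [sortNoise()]), \code{gates} (boundaries), \code{scoring} (list for
#'   [scoringConfig()]), \code{proteome} (list for
#'   [simulateProteome()]), \code{out_dir}.
#' @return List: \code{library}, \code{sim}, \code{scores}
#'   ([ScoreTable-class]), \code{prefs}, \code{model}, \code{thresholds},
#'   \code{scan}, \code{manifest} (when \code{out_dir} is set).
#' @export
runScreenPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    seed <- config$seed %||% 1L
    wt <- config$wt_dna %||% svNLSRegion()
    gates <- if (!is.null(config$gates)) GateConfig(config$gates)
             else nlsGates()
    noise <- do.call(sortNoise, config$noise %||% list())
    sconf <- do.call(scoringConfig, config$scoring %||% list())

    lib <- generateNNKLibrary(wt, seed = deriveSeed(seed, "library"))
    sim <- simulateSortExperiment(lib, gates = gates,
        n_cells_per_variant = config$n_cells_per_variant %||% 500L,
        noise = noise, n_replicates = config$n_replicates %||% 2L,
        depth_per_bin = config$depth_per_bin %||% 200000L,
        seed = deriveSeed(seed, "sort"))
    scores <- scoreVariants(sim$counts, wt, sconf)
    prefs <- positionPreferences(scores)

    pargs <- config$proteome %||% list()
    pargs$prefs <- prefs
    pargs$seed <- deriveSeed(seed, "proteome-train")
    ptrain <- do.call(simulateProteome, pargs)
    train <- buildTrainingSet(ptrain$sequences, ptrain$annotations, prefs)
    model <- fitNLSModel(train, seed = deriveSeed(seed, "cv"))

    pargs$seed <- deriveSeed(seed, "proteome-test")
    ptest <- do.call(simulateProteome, pargs)
    test <- buildTrainingSet(ptest$sequences, ptest$annotations, prefs)
    test$label <- labelWindowsByOverlap(test, ptest$annotations)
    thr <- suppressWarnings(calibrateThresholds(
        predictNLS(model, test), test$label))
    scan <- scanProteome(ptest$sequences, model, prefs, thr)

    out <- list(library = lib, sim = sim, scores = scores, prefs = prefs,
                model = model, thresholds = thr, scan = scan)
    if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        man <- rbind(
            .writeArtifact(sim$counts,
                file.path(config$out_dir, "variant_counts.tsv")),
            .writeArtifact(finalScores(scores),
                file.path(config$out_dir, "final_scores.tsv")),
            .writeArtifact(scan$windows,
                file.path(config$out_dir, "scan_windows.tsv")))
        writeNLSModel(model, file.path(config$out_dir, "nls_model.json"))
        man <- rbind(man, data.frame(file = "nls_model.json",
            md5 = unname(tools::md5sum(
                file.path(config$out_dir, "nls_model.json")))))
        utils::write.table(man,
            file.path(config$out_dir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        out$manifest <- man
    }
    out
}

#' Run the morphology pipeline end to end
#'
#' Renders a field of elliptical and lobulated nuclei, segments them,
#' measures N:C ratios and shape factors, gates nuclei on shape factor
#' (800 ms below the lobulation cutoff), then simulates single-cell
#' RNA-seq with a planted lobulation program and runs the full
#' expression stage: normalization/PCA, cell-cycle scores, the logistic
#' lobulation model on PCs 1-4, the NB differential expression test and
#' over-representation of the planted program.
#'
#' @param config Named list or YAML path. Recognized entries:
#'   \code{seed}, \code{n_normal}, \code{n_lobulated},
#'   \code{shape_cutoff}, \code{sc} (list for [scSimSpec()]),
#'   \code{out_dir}.
#' @return List: \code{image}, \code{measurements}, \code{gated},
#'   \code{sce}, \code{pca}, \code{cycle}, \code{lob_model},
#'   \code{lob_scores}, \code{de}, \code{enrichment}, \code{manifest}
#'   (when \code{out_dir} is set).
#' @export
runMorphologyPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    seed <- config$seed %||% 1L
    cutoff <- config$shape_cutoff %||% 0.65

    spec <- randomNucleiSpec(n_normal = config$n_normal %||% 12L,
        n_lobulated = config$n_lobulated %||% 12L,
        seed = deriveSeed(seed, "image"))
    img <- renderNucleiImage(spec, seed = deriveSeed(seed, "noise"))
    labels <- segmentNuclei(img$nuclear)
    meas <- measureCells(img$reporter, labels)
    ok <- !meas$excluded
    meas$morphology <- NA_character_
    meas$morphology[ok] <- classifyMorphology(meas$shape_factor[ok], cutoff)
    meas$bin <- NA_integer_
    meas$bin[ok] <- assignGate(meas$shape_factor[ok],
                               morphologyGates(cutoff))

    scargs <- config$sc %||% list()
    scargs$seed <- deriveSeed(seed, "scrna")
    sce <- simulateScRNA(do.call(scSimSpec, scargs))
    pca <- normalizePCA(sce)
    cyc <- cellCycleScores(sce, S4Vectors::metadata(sce)$cycle_sets)
    half <- seq_len(floor(ncol(sce) / 2))
    lm_ <- suppressWarnings(fitLobulationModel(pca$pcs[half, ,
        drop = FALSE], sce$lobulated[half]))
    lsc <- lobulationScore(lm_, pca$pcs)
    de <- lobulationDE(sce, lsc, cyc$scores[, "G1"],
                       cyc$scores[, "G2M"])
    planted <- rownames(sce)[SummarizedExperiment::rowData(sce)$lob_program]
    deg <- de$gene[de$converged & !is.na(de$q) & de$q < 0.01 &
                   abs(de$effect_size) > 0.1]
    enr <- if (length(deg))
        overrepresentation(deg, list(planted_program = planted),
                           universe = de$gene[de$converged])
    else NULL

    out <- list(image = img, measurements = meas, gated = meas$bin,
                sce = sce, pca = pca, cycle = cyc, lob_model = lm_,
                lob_scores = lsc, de = de, enrichment = enr)
    if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        man <- rbind(
            .writeArtifact(meas,
                file.path(config$out_dir, "measurements.tsv")),
            .writeArtifact(de, file.path(config$out_dir, "de_results.tsv")))
        utils::write.table(man,
            file.path(config$out_dir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        out$manifest <- man
    }
    out
}
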