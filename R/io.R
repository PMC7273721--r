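#' Read and write variant count tables
#'
#' Tab-separated tables with columns \code{variant_nt}, \code{aa_change},
#' \code{replicate}, \code{bin} (1-4), \code{count}; extra columns (e.g.
#' \code{class}) are preserved. Sequence positions in all user-facing
#' files are 1-based inclusive.
#'
#' @param path File path.
#' @param counts Count table data.frame.
#' @return \code{readVariantCounts} returns the data.frame;
#'   \code{writeVariantCounts} returns \code{path} invisibly.
#' @export
readVariantCounts <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("variant_nt", "aa_change", "replicate", "bin", "count")
    stopIfNot(all(need %in% names(tab)),
              "count table is missing required columns")
    tab
}

#' @rdname readVariantCounts
#' @export
writeVariantCounts <- function(counts, path) {
    utils::write.table(counts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an Enrich2-style two-column count table
#'
#' Tab-separated \code{variant<TAB>count} export (one file per bin); the
#' variant column holds the nucleotide sequence of the mutagenized
#' region.
#'
#' @param path File path.
#' @param replicate,bin Labels attached to the rows.
#' @param wt_dna Wild-type sequence used to derive \code{aa_change}
#'   annotations (optional).
#' @return A count table data.frame compatible with [scoreVariants()].
#' @export
readEnrich2Counts <- function(path, replicate = 1L, bin, wt_dna = NULL) {
    tab <- utils::read.delim(path, header = TRUE,
                             stringsAsFactors = FALSE)
    stopIfNot(ncol(tab) >= 2L, "expected variant and count columns")
    names(tab)[1:2] <- c("variant_nt", "count")
    out <- data.frame(variant_nt = toupper(tab$variant_nt),
                      aa_change = NA_character_, replicate = replicate,
                      bin = bin, count = tab$count,
                      stringsAsFactors = FALSE)
    if (!is.null(wt_dna)) {
        wt_dna <- toupper(wt_dna)
        wtc <- substring(wt_dna, seq(1L, 31L, 3L), seq(3L, 33L, 3L))
        wta <- translateCodon(wtc)
        out$aa_change <- vapply(out$variant_nt, function(s) {
            if (s == wt_dna) return("WT")
            cs <- substring(s, seq(1L, 31L, 3L), seq(3L, 33L, 3L))
            d <- which(cs != wtc)
            if (length(d) != 1L) return(NA_character_)
            paste0(wta[d], d, translateCodon(cs[d]))
        }, character(1L), USE.NAMES = FALSE)
    }
    out
}

#' Write a UMI matrix as MatrixMarket with feature and barcode lists
#'
#' @param x A \code{SingleCellExperiment} or genes x cells matrix.
#' @param dir Output directory (created if needed); writes
#'   \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}.
#' @return The directory path, invisibly.
#' @export
writeUMIMatrix <- function(x, dir) {
    counts <- .countsMatrix(x)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' Read a MatrixMarket UMI matrix with feature and barcode lists
#'
#' @param dir Directory holding \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}.
#' @return A dense genes x cells integer matrix.
#' @export
readUMIMatrix <- function(dir) {
    m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
    rownames(m) <- readLines(file.path(dir, "features.tsv"))
    colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
    storage.mode(m) <- "integer"
    m
}

#' Write a rendered two-channel image as 16-bit TIFF
#'
#' @param img A [renderNucleiImage()] result.
#' @param nuclear_path,reporter_path Output file paths.
#' @param bit_depth Bit depth used for scaling (default 16).
#' @return Invisibly, the two paths.
#' @export
writeImagePair <- function(img, nuclear_path, reporter_path,
                           bit_depth = 16L) {
    maxval <- 2^bit_depth - 1
    EBImage::writeImage(EBImage::Image(img$nuclear / maxval),
                        nuclear_path, type = "tiff", bits.per.sample = 16L)
    EBImage::writeImage(EBImage::Image(img$reporter / maxval),
                        reporter_path, type = "tiff",
                        bits.per.sample = 16L)
    invisible(c(nuclear_path, reporter_path))
}

#' Read a single-channel TIFF/PNG as an intensity matrix
#'
#' @param path Image file.
#' @param bit_depth Bit depth for rescaling to integer intensities.
#' @return Numeric matrix indexed \code{[x, y]}.
#' @export
readChannelImage <- function(path, bit_depth = 16L) {
    img <- EBImage::readImage(path)
    EBImage::imageData(img)[, , drop = TRUE][, ] * (2^bit_depth - 1)
}

#' Serialize an NLS model to JSON
#'
#' Twelve named coefficients plus fit metadata (CV folds, seed, CV AUC).
#'
#' @param model An [NLSModel-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeNLSModel <- function(model, path) {
    jsonlite::write_json(list(
        coefficients = as.list(coef(model)),
        cv_auc = model@cvAUC, folds = model@folds, seed = model@seed),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeNLSModel
#' @export
readNLSModel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("NLSModel", coefficients = unlist(x$coefficients),
        cvAUC = x$cv_auc, folds = as.integer(x$folds),
        seed = as.integer(x$seed))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, member genes per line).
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
    names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
    sets
}

#' Read a run configuration from YAML
#'
#' A single YAML file with a global \code{seed} and per-stage parameter
#' blocks; every stochastic stage derives its own seed from the global
#' one, so a config plus seed fully determines a run.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    stopIfNot(!is.null(cfg$seed), "config must set a global seed")
    cfg
}
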