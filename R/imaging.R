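#' Crofton perimeter of a binary mask
#'
#' Multi-direction (Cauchy-Crofton) perimeter estimate from the counts of
#' the sixteen 2 x 2 pixel configurations, using intercepts in four
#' directions (0, 45, 90, 135 degrees). Unlike a naive boundary-pixel
#' count, this estimator is nearly unbiased for smooth shapes: a digitized
#' circle of radius 30 px scores a shape factor of about 0.98.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Estimated perimeter in pixel units.
#' @export
croftonPerimeter <- function(mask) {
    m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
    m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) + 0L
    nr <- nrow(m); nc <- ncol(m)
    # 2x2 configuration code over all block positions
    a <- m[-nr, -nc]; b <- m[-nr, -1L]; cc <- m[-1L, -nc]; d <- m[-1L, -1L]
    code <- 8L * a + 2L * b + 4L * cc + 1L * d
    h <- tabulate(code + 1L, nbins = 16L)
    s2 <- sqrt(2)
    coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
               0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
               pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
               pi / 4, pi / 2, 0, 0)
    sum(coefs * h)
}

#' Shape factor (circularity) of a nuclear mask
#'
#' \eqn{4\pi A / P^2} with the area in pixels and the perimeter from the
#' Crofton multi-direction estimator, so an ideal circle approaches 1 and
#' lobulated outlines fall well below. Values are capped only by
#' discretization: up to about 1.03 for very small regions.
#'
#' @param mask Logical or 0/1 matrix containing a single connected region.
#' @param min_area Smallest region area accepted (default 9 px).
#' @return Dimensionless shape factor.
#' @export
shapeFactor <- function(mask, min_area = 9L) {
    bin <- (mask > 0) + 0
    area <- sum(bin)
    stopIfNot(area >= min_area, "region smaller than min_area")
    lab <- EBImage::bwlabel(bin)
    stopIfNot(max(lab) == 1L, "mask must be a single connected region")
    p <- croftonPerimeter(bin)
    4 * pi * area / p^2
}

#' Shape factor of a continuous closed outline
#'
#' Computes \eqn{4\pi A / P^2} on a polygonal outline (e.g. the generating
#' outline of a simulated nucleus, sampled at high resolution), free of
#' rasterization error: a circle gives 1 in the limit and a square gives
#' \eqn{\pi/4}.
#'
#' @param x,y Vertex coordinates of a closed polygon (first vertex need
#'   not be repeated).
#' @return Dimensionless shape factor.
#' @examples
#' polygonShapeFactor(c(0, 1, 1, 0), c(0, 0, 1, 1))  # pi/4
#' @export
polygonShapeFactor <- function(x, y) {
    stopIfNot(length(x) == length(y) && length(x) >= 3L,
              "need at least three vertices")
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    area <- abs(sum(x * yn - xn * y)) / 2
    per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
    4 * pi * area / per^2
}

#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing SD in px before thresholding.
#' @param min_area,max_area Area bounds (px) for accepted nuclei.
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed (default \code{TRUE}).
#' @param watershed_tolerance Minimum object-height tolerance passed to the
#'   watershed; larger values merge shallow splits, keeping the lobes of a
#'   single lobulated nucleus together while still separating nuclei that
#'   touch at a thin neck.
#' @return A named list.
#' @export
segmentationParams <- function(smooth_sigma = 1.5, min_area = 60,
                               max_area = Inf, split_touching = TRUE,
                               watershed_tolerance = 3) {
    list(smooth_sigma = smooth_sigma, min_area = min_area,
         max_area = max_area, split_touching = isTRUE(split_touching),
         watershed_tolerance = watershed_tolerance)
}

#' Segment nuclei from a nuclear-marker image
#'
#' Gaussian smoothing, Otsu threshold, hole filling, optional
#' distance-transform watershed to split touching nuclei, then an area
#' filter. This is the package's nuclear segmentation; vendor pipelines
#' tuned for bleb detection can be substituted upstream by supplying label
#' masks directly to the measurement functions.
#'
#' @param img Numeric matrix of nuclear-marker intensities.
#' @param params A [segmentationParams()] list.
#' @return Integer label matrix (0 = background); blank images give zero
#'   labels.
#' @export
segmentNuclei <- function(img, params = segmentationParams()) {
    stopIfNot(length(dim(img)) == 2L && all(dim(img) > 0), "empty image")
    if (stats::sd(img) == 0) return(matrix(0L, nrow(img), ncol(img)))
    x <- img / max(img)
    if (params$smooth_sigma > 0)
        x <- EBImage::gblur(x, sigma = params$smooth_sigma)
    thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
    bin <- EBImage::fillHull(x > thr)
    if (sum(bin) == 0) return(matrix(0L, nrow(img), ncol(img)))
    if (params$split_touching) {
        dm <- EBImage::distmap(bin)
        lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
    } else {
        lab <- EBImage::bwlabel(bin)
    }
    lab <- EBImage::imageData(lab)
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    bad <- which(sizes < params$min_area | sizes > params$max_area)
    lab[lab %in% bad] <- 0L
    # relabel 1..n
    keep <- sort(unique(lab[lab > 0]))
    out <- matrix(0L, nrow(lab), ncol(lab))
    for (i in seq_along(keep)) out[lab == keep[i]] <- i
    out
}

#' Cytoplasm ring mask around one nucleus
#'
#' Dilates the nuclear mask by \code{radius} pixels (Euclidean
#' distance-transform dilation, i.e. every pixel within \code{radius} of
#' the nucleus) and removes the nucleus itself and every other nucleus.
#' Pixels contested by a neighboring nucleus's ring should be resolved
#' with [cytoplasmRings()], which drops them from both.
#'
#' @param nucleus_mask Logical matrix of the nucleus of interest.
#' @param all_nuclei_mask Logical matrix of all nuclei (including this one).
#' @param radius Ring radius in pixels (>= 1, default 8).
#' @return Logical ring mask, clipped to the image bounds.
#' @export
cytoplasmRing <- function(nucleus_mask, all_nuclei_mask = nucleus_mask,
                          radius = 8L) {
    stopIfNot(radius >= 1, "radius must be >= 1")
    stopIfNot(sum(nucleus_mask) > 0, "empty nucleus mask")
    # distance of each background pixel to the nucleus region
    d <- EBImage::distmap((nucleus_mask == 0) + 0)
    dil <- EBImage::imageData(d) <= radius
    dil & !(all_nuclei_mask > 0)
}

#' Cytoplasm rings for all nuclei in a label mask
#'
#' Builds per-nucleus dilate-and-subtract rings and drops pixels claimed
#' by more than one ring from all claimants, so rings are pairwise
#' disjoint and never overlap any nucleus.
#'
#' @param labels Integer label matrix from [segmentNuclei()].
#' @param radius Ring radius in pixels (default 8).
#' @return Integer label matrix of rings (same labels as the nuclei).
#' @export
cytoplasmRings <- function(labels, radius = 8L) {
    n <- max(labels)
    out <- matrix(0L, nrow(labels), ncol(labels))
    if (n == 0L) return(out)
    allnuc <- labels > 0
    claims <- matrix(0L, nrow(labels), ncol(labels))
    rings <- vector("list", n)
    for (i in seq_len(n)) {
        r <- cytoplasmRing(labels == i, allnuc, radius)
        rings[[i]] <- r
        claims <- claims + r
    }
    for (i in seq_len(n)) out[rings[[i]] & claims == 1L] <- i
    out
}

#' Per-nucleus reporter measurements and N:C ratios
#'
#' Measures mean reporter intensity in each nuclear mask
#' (\eqn{I_{nuc}}) and its cytoplasm ring (\eqn{I_{cyt}}), the N:C ratio
#' \eqn{I_{nuc}/I_{cyt}}, area, Crofton perimeter and shape factor.
#' Cells whose nuclear or cytoplasmic mean falls below
#' \code{intensity_floor} are flagged excluded rather than scored, as are
#' cells with an empty ring. Optional background subtraction removes the
#' median intensity of pixels outside all nuclei and rings from both
#' compartment means first.
#'
#' @param reporter Numeric matrix of reporter intensities.
#' @param labels Nuclear label matrix.
#' @param rings Ring label matrix from [cytoplasmRings()]; built at
#'   \code{ring_radius} when \code{NULL}.
#' @param intensity_floor Minimum compartment mean (default 0; use 11000
#'   for 12-16 bit acquisitions following the screen's filter).
#' @param ring_radius Ring radius used when \code{rings} is \code{NULL}.
#' @param background_subtract Subtract median non-cell intensity first
#'   (default \code{FALSE}; enable for real images).
#' @return data.frame, one row per nucleus: \code{id}, \code{cx},
#'   \code{cy} (0-based pixel centroid, origin top-left), \code{area},
#'   \code{perimeter}, \code{shape_factor}, \code{I_nuc}, \code{I_cyt},
#'   \code{NC}, \code{excluded}, \code{reason}.
#' @export
measureCells <- function(reporter, labels, rings = NULL,
                         intensity_floor = 0, ring_radius = 8L,
                         background_subtract = FALSE) {
    stopIfNot(all(dim(reporter) == dim(labels)), "image/mask size mismatch")
    if (is.null(rings)) rings <- cytoplasmRings(labels, ring_radius)
    n <- max(labels)
    bg <- 0
    if (background_subtract) {
        free <- labels == 0 & rings == 0
        bg <- if (any(free)) stats::median(reporter[free]) else 0
    }
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        nm <- labels == i
        rm_ <- rings == i
        area <- sum(nm)
        idx <- which(nm, arr.ind = TRUE)
        per <- croftonPerimeter(nm)
        sf <- 4 * pi * area / per^2
        inuc <- max(mean(reporter[nm]) - bg, 0)
        icyt <- if (any(rm_)) max(mean(reporter[rm_]) - bg, 0) else NA_real_
        excluded <- FALSE; reason <- ""
        if (!any(rm_)) { excluded <- TRUE; reason <- "empty_ring" }
        else if (inuc < intensity_floor || icyt < intensity_floor) {
            excluded <- TRUE; reason <- "below_intensity_floor"
        }
        rows[[i]] <- data.frame(id = i,
            cx = mean(idx[, 1L]) - 1, cy = mean(idx[, 2L]) - 1,
            area = area, perimeter = per, shape_factor = sf,
            I_nuc = inuc, I_cyt = icyt,
            NC = if (!excluded && is.finite(icyt) && icyt > 0) inuc / icyt
                 else NA_real_,
            excluded = excluded, reason = reason, stringsAsFactors = FALSE)
    }
    if (!n) return(data.frame(id = integer(), cx = numeric(),
        cy = numeric(), area = integer(), perimeter = numeric(),
        shape_factor = numeric(), I_nuc = numeric(), I_cyt = numeric(),
        NC = numeric(), excluded = logical(), reason = character()))
    do.call(rbind, rows)
}

#' Classify nuclear morphology by shape factor
#'
#' A nucleus is lobulated when its shape factor falls below the cutoff
#' (default 0.65).
#'
#' @param shape_factors Numeric vector (or a [measureCells()] data.frame).
#' @param cutoff Shape-factor cutoff in (0, 1), default 0.65.
#' @return Character vector, \code{"lobulated"} or \code{"normal"}.
#' @examples
#' classifyMorphology(c(0.64, 0.66))
#' @export
classifyMorphology <- function(shape_factors, cutoff = 0.65) {
    if (is.data.frame(shape_factors))
        shape_factors <- shape_factors$shape_factor
    stopIfNot(cutoff > 0 && cutoff < 1, "cutoff must be in (0, 1)")
    ifelse(shape_factors < cutoff, "lobulated", "normal")
}
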