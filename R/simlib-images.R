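#' Specification for a synthetic two-channel nuclei image
#'
#' Describes an image of elliptical and/or lobulated nuclei with known
#' geometry and channel intensities. Lobulated nuclei are unions of
#' overlapping discs around a center: a core disc of radius \code{core_r}
#' plus \code{n_lobes} discs of radius \code{lobe_r} placed at distance
#' \code{lobe_d} from the nucleus center, giving deep clefts between
#' lobes; elliptical nuclei use semi-axes \code{a}, \code{b} and
#' orientation \code{angle} (radians).
#'
#' @param width,height Image size in pixels.
#' @param nuclei data.frame, one row per nucleus: \code{cx}, \code{cy}
#'   (0-based pixel center), \code{shape} in \code{{"ellipse", "lobed"}},
#'   \code{a}, \code{b}, \code{angle}, \code{n_lobes}, \code{core_r},
#'   \code{lobe_r}, \code{lobe_d}, \code{nc} (true reporter N:C ratio).
#'   Missing geometry columns get defaults.
#' @param background_mean Background intensity of both channels.
#' @param noise_sd Gaussian pixel noise SD (0 for noise-free fixtures).
#' @param bit_depth Bit depth, 12-16; intensities are clipped to
#'   \code{[0, 2^bit_depth - 1]}.
#' @param nuclear_marker_mean Nuclear-channel intensity inside nuclei.
#' @param reporter_cyt_mean Reporter intensity in the cytoplasm; the
#'   nuclear reporter intensity is \code{nc * reporter_cyt_mean}.
#' @param cyt_width Width (px) of the rendered cytoplasm collar.
#' @return A validated spec list.
#' @export
syntheticImageSpec <- function(width = 256L, height = 256L, nuclei,
                               background_mean = 200, noise_sd = 0,
                               bit_depth = 16L,
                               nuclear_marker_mean = 20000,
                               reporter_cyt_mean = 8000,
                               cyt_width = 12L) {
    stopIfNot(bit_depth >= 12L && bit_depth <= 16L,
              "bit depth must be 12-16 bits")
    maxval <- 2^bit_depth - 1
    defaults <- list(shape = "ellipse", a = 18, b = 12, angle = 0,
                     n_lobes = 4L, core_r = 7, lobe_r = 4.5, lobe_d = 10,
                     nc = 1)
    if (nrow(nuclei)) {
        for (nm in names(defaults))
            if (is.null(nuclei[[nm]])) nuclei[[nm]] <- defaults[[nm]]
        stopIfNot(all(nuclei$shape %in% c("ellipse", "lobed")),
                  "unknown nucleus shape")
    }
    stopIfNot(max(background_mean, nuclear_marker_mean,
                  reporter_cyt_mean) <= maxval,
              "channel means exceed bit-depth range")
    list(width = as.integer(width), height = as.integer(height),
         nuclei = nuclei, background_mean = background_mean,
         noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
         nuclear_marker_mean = nuclear_marker_mean,
         reporter_cyt_mean = reporter_cyt_mean,
         cyt_width = as.integer(cyt_width))
}

# high-resolution generating outline of one nucleus row; returns list(x, y)
nucleusOutline <- function(row, n = 4096L) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    if (row$shape == "ellipse") {
        x0 <- row$a * cos(th); y0 <- row$b * sin(th)
        x <- row$cx + x0 * cos(row$angle) - y0 * sin(row$angle)
        y <- row$cy + x0 * sin(row$angle) + y0 * cos(row$angle)
    } else {
        stopIfNot(row$lobe_d < row$core_r + row$lobe_r,
                  "lobes must overlap the core disc")
        k <- row$n_lobes
        centers <- row$angle + 2 * pi * (seq_len(k) - 1L) / k
        r <- vapply(th, function(t) {
            dd <- t - centers
            disc <- row$lobe_r^2 - row$lobe_d^2 * sin(dd)^2
            cand <- row$lobe_d * cos(dd) + sqrt(pmax(disc, 0))
            cand[disc < 0 | cand <= 0] <- -Inf
            max(row$core_r, cand)
        }, numeric(1L))
        x <- row$cx + r * cos(th); y <- row$cy + r * sin(th)
    }
    list(x = x, y = y)
}

# pixel mask of one nucleus on a width x height grid (matrix [x, y])
nucleusMask <- function(row, width, height) {
    px <- matrix(seq_len(width) - 1L, width, height)
    py <- matrix(rep(seq_len(height) - 1L, each = width), width, height)
    if (row$shape == "ellipse") {
        dx <- px - row$cx; dy <- py - row$cy
        u <- dx * cos(row$angle) + dy * sin(row$angle)
        v <- -dx * sin(row$angle) + dy * cos(row$angle)
        (u / row$a)^2 + (v / row$b)^2 <= 1
    } else {
        k <- row$n_lobes
        angs <- row$angle + 2 * pi * (seq_len(k) - 1L) / k
        acc <- (px - row$cx)^2 + (py - row$cy)^2 <= row$core_r^2
        for (j in seq_len(k)) {
            lcx <- row$cx + row$lobe_d * cos(angs[j])
            lcy <- row$cy + row$lobe_d * sin(angs[j])
            acc <- acc | ((px - lcx)^2 + (py - lcy)^2 <= row$lobe_r^2)
        }
        acc
    }
}

#' Render a synthetic two-channel nuclei image with ground truth
#'
#' Paints each nucleus into a nuclear-marker channel and a reporter
#' channel (nuclear reporter intensity \code{nc x reporter_cyt_mean},
#' cytoplasm collar at \code{reporter_cyt_mean}), adds Gaussian noise and
#' clips to the bit depth. The truth table carries each nucleus's
#' analytic shape factor, computed on the high-resolution generating
#' outline, and its configured N:C ratio. Nuclei whose masks (including
#' collars) would overlap raise a generation error.
#'
#' @param spec A [syntheticImageSpec()].
#' @param seed Integer seed for the pixel noise.
#' @return List: \code{nuclear} and \code{reporter} intensity matrices
#'   (indexed \code{[x, y]}), \code{mask} (integer truth labels), and
#'   \code{truth} data.frame (\code{id}, \code{shape}, \code{true_sf},
#'   \code{true_nc}, \code{area_px}).
#' @examples
#' nuc <- data.frame(cx = c(60, 160), cy = c(80, 90),
#'                   shape = c("ellipse", "lobed"), nc = c(1.4, 1.0))
#' img <- renderNucleiImage(syntheticImageSpec(nuclei = nuc), seed = 1)
#' img$truth
#' @export
renderNucleiImage <- function(spec, seed = 1L) {
    w <- spec$width; h <- spec$height
    nuclear <- matrix(spec$background_mean, w, h)
    reporter <- matrix(spec$background_mean, w, h)
    mask <- matrix(0L, w, h)
    occupied <- matrix(FALSE, w, h)
    truth <- NULL
    nuc <- spec$nuclei
    brush <- EBImage::makeBrush(2L * spec$cyt_width + 1L, shape = "disc")
    for (i in seq_len(nrow(nuc))) {
        row <- as.list(nuc[i, , drop = FALSE])
        nm <- nucleusMask(row, w, h)
        if (!any(nm)) stop("nucleus ", i, " lies outside the image",
                           call. = FALSE)
        cellm <- EBImage::dilate(nm + 0, brush) > 0
        if (any(cellm & occupied))
            stop("nuclei overlap by construction; respace nucleus ", i,
                 call. = FALSE)
        occupied <- occupied | cellm
        collar <- cellm & !nm
        reporter[collar] <- spec$reporter_cyt_mean
        reporter[nm] <- row$nc * spec$reporter_cyt_mean
        nuclear[nm] <- spec$nuclear_marker_mean
        mask[nm] <- i
        ol <- nucleusOutline(row)
        truth <- rbind(truth, data.frame(id = i, shape = row$shape,
            true_sf = polygonShapeFactor(ol$x, ol$y), true_nc = row$nc,
            area_px = sum(nm), stringsAsFactors = FALSE))
    }
    if (spec$noise_sd > 0) {
        withSeed(seed, {
            nuclear <- nuclear + stats::rnorm(w * h, 0, spec$noise_sd)
            reporter <- reporter + stats::rnorm(w * h, 0, spec$noise_sd)
        })
    }
    maxval <- 2^spec$bit_depth - 1
    nuclear <- pmin(pmax(nuclear, 0), maxval)
    reporter <- pmin(pmax(reporter, 0), maxval)
    list(nuclear = nuclear, reporter = reporter, mask = mask,
         truth = truth %||% data.frame(id = integer(),
             shape = character(), true_sf = numeric(),
             true_nc = numeric(), area_px = integer()))
}

#' Randomly place a mixed field of elliptical and lobulated nuclei
#'
#' Draws nucleus centers uniformly with bounded retries until all cells
#' (nucleus plus cytoplasm collar) are pairwise disjoint, mixing round
#' ellipses with four-lobed nuclei.
#'
#' @param n_normal,n_lobulated Numbers of elliptical and lobed nuclei.
#' @param width,height Image size (px).
#' @param nc_normal,nc_lobulated Reporter N:C ratio per morphology class.
#' @param seed Integer seed.
#' @param max_tries Placement retries before a generation error.
#' @param ... Passed to [syntheticImageSpec()].
#' @return A [syntheticImageSpec()] with randomized nucleus geometry.
#' @export
randomNucleiSpec <- function(n_normal = 5L, n_lobulated = 5L,
                             width = 512L, height = 512L,
                             nc_normal = 1.4, nc_lobulated = 1.4,
                             seed = 1L, max_tries = 2000L, ...) {
    withSeed(seed, {
        n <- n_normal + n_lobulated
        rows <- NULL
        margin <- 34
        tries <- 0L
        placed_x <- numeric(0); placed_y <- numeric(0)
        min_dist <- 2 * margin + 6
        while (length(placed_x) < n) {
            tries <- tries + 1L
            if (tries > max_tries)
                stop("could not place non-overlapping nuclei", call. = FALSE)
            cx <- stats::runif(1, margin, width - 1 - margin)
            cy <- stats::runif(1, margin, height - 1 - margin)
            if (length(placed_x) &&
                min((placed_x - cx)^2 + (placed_y - cy)^2) < min_dist^2)
                next
            placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
        }
        lob <- c(rep(FALSE, n_normal), rep(TRUE, n_lobulated))
        rows <- data.frame(cx = placed_x, cy = placed_y,
            shape = ifelse(lob, "lobed", "ellipse"),
            a = stats::runif(n, 14, 18), b = stats::runif(n, 12, 15),
            angle = stats::runif(n, 0, pi),
            n_lobes = 4L, core_r = stats::runif(n, 6, 8),
            lobe_r = stats::runif(n, 4, 5.5), lobe_d = NA_real_,
            nc = ifelse(lob, nc_lobulated, nc_normal),
            stringsAsFactors = FALSE)
        rows$lobe_d <- rows$core_r + rows$lobe_r * stats::runif(n, 0.5, 0.8)
        syntheticImageSpec(width = width, height = height, nuclei = rows, ...)
    })
}
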