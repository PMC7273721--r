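# counts matrix from either a SingleCellExperiment or a genes x cells matrix
.countsMatrix <- function(x) {
    if (is(x, "SummarizedExperiment"))
        return(as.matrix(SummarizedExperiment::assay(x, "counts")))
    as.matrix(x)
}

# library-size-normalized log1p expression (target = median library size)
.logNormalize <- function(counts) {
    tot <- colSums(counts)
    stopIfNot(all(tot > 0), "cells with zero total counts")
    log1p(t(t(counts) / tot * stats::median(tot)))
}

#' Log-normalization and PCA of a UMI matrix
#'
#' Size-factor scales counts to the median library size, log1p-transforms,
#' selects the most variable genes, and runs centered PCA over cells.
#' Component signs follow a deterministic convention (the loading with the
#' largest magnitude is positive), so identical inputs give identical
#' coordinates.
#'
#' @param x A \code{SingleCellExperiment} (counts assay) or genes x cells
#'   count matrix.
#' @param n_hvg Number of highly variable genes kept (default 2000; capped
#'   at the gene count).
#' @param n_pcs Number of principal components (default 30).
#' @return List: \code{pcs} (cells x components), \code{var_explained},
#'   \code{rotation}, \code{hvg} (gene names used).
#' @export
normalizePCA <- function(x, n_hvg = 2000L, n_pcs = 30L) {
    counts <- .countsMatrix(x)
    stopIfNot(nrow(counts) >= 2L && ncol(counts) >= 2L,
              "need at least 2 genes and 2 cells")
    lg <- .logNormalize(counts)
    v <- apply(lg, 1L, stats::var)
    stopIfNot(any(v > 0), "constant expression matrix")
    hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvg, sum(v > 0)))]
    n_pcs <- min(n_pcs, length(hvg) - 1L, ncol(counts) - 1L)
    pc <- stats::prcomp(t(lg[hvg, , drop = FALSE]), center = TRUE,
                        scale. = FALSE, rank. = n_pcs)
    flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
        r <- pc$rotation[, j]
        sign(r[which.max(abs(r))])
    }, numeric(1L))
    pcs <- sweep(pc$x, 2L, flip, `*`)
    rot <- sweep(pc$rotation, 2L, flip, `*`)
    list(pcs = pcs, var_explained = pc$sdev[seq_len(ncol(pcs))]^2 /
             sum(pc$sdev^2), rotation = rot, hvg = hvg)
}

#' Cell-cycle module scores and phase calls
#'
#' For each phase gene set the score is the mean log-normalized expression
#' of the set minus the mean of an expression-matched control: genes are
#' binned by average expression and the control value is the per-bin mean
#' expression (set genes excluded), averaged over the bins the set
#' occupies. The phase call is the highest-scoring program, falling back
#' to G1 when no score is positive.
#'
#' @param x Counts matrix or \code{SingleCellExperiment}.
#' @param gene_sets Named list of character vectors (typically
#'   \code{G1}, \code{S}, \code{G2M}).
#' @param n_bins Expression bins for control matching (default 25).
#' @return List: \code{scores} (cells x sets) and \code{phase}
#'   (character per cell).
#' @export
cellCycleScores <- function(x, gene_sets, n_bins = 25L) {
    counts <- .countsMatrix(x)
    lg <- .logNormalize(counts)
    avg <- rowMeans(lg)
    br <- unique(stats::quantile(avg, probs = seq(0, 1,
        length.out = n_bins + 1L)))
    bin <- cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
    scores <- sapply(names(gene_sets), function(nm) {
        set <- gene_sets[[nm]]
        present <- intersect(set, rownames(lg))
        if (length(present) < length(set) / 2)
            stop("fewer than half of the ", nm, " genes are present; ",
                 "missing: ", paste(setdiff(set, rownames(lg)),
                                    collapse = ", "), call. = FALSE)
        idx <- match(present, rownames(lg))
        setmean <- colMeans(lg[idx, , drop = FALSE])
        ctrl <- rowsum(lg[-idx, , drop = FALSE], group = bin[-idx])
        cnt <- table(factor(bin[-idx], levels = rownames(ctrl)))
        ctrl <- ctrl / as.numeric(cnt)
        use <- match(as.character(bin[idx]), rownames(ctrl))
        ctrlmean <- colMeans(ctrl[use[!is.na(use)], , drop = FALSE])
        setmean - ctrlmean
    })
    best <- max.col(scores, ties.method = "first")
    phase <- colnames(scores)[best]
    none <- apply(scores, 1L, max) <= 0
    phase[none] <- if ("G1" %in% colnames(scores)) "G1"
                   else colnames(scores)[1L]
    list(scores = scores, phase = phase)
}

# ridge-penalized logistic IRLS (intercept unpenalized)
.ridgeLogistic <- function(X, y, lambda, maxit = 50L, tol = 1e-8) {
    X1 <- cbind(1, X)
    beta <- numeric(ncol(X1))
    pen <- diag(c(0, rep(lambda, ncol(X))))
    for (it in seq_len(maxit)) {
        eta <- as.vector(X1 %*% beta)
        p <- 1 / (1 + exp(-eta))
        w <- pmax(p * (1 - p), 1e-10)
        z <- eta + (y - p) / w
        new <- solve(crossprod(X1, w * X1) + pen, crossprod(X1, w * z))
        if (max(abs(new - beta)) < tol) { beta <- new; break }
        beta <- as.vector(new)
    }
    as.vector(beta)
}

#' Fit a logistic lobulation model on principal components 1-4
#'
#' Maximum-likelihood logistic regression of the binary morphology label
#' on the first four PCs. Under complete separation the ML fit diverges;
#' the function then refits with a small ridge penalty and records that it
#' did.
#'
#' @param pcs Cells x components matrix (at least four columns).
#' @param labels Logical (or coercible) per-cell lobulated labels.
#' @param ridge_lambda Penalty used on the separation fallback.
#' @return List: \code{coefficients} (intercept + PC1..PC4), \code{ridge}
#'   (logical), \code{fit} (the \code{glm} object when ML converged
#'   cleanly) and \code{auc} (training AUC).
#' @export
fitLobulationModel <- function(pcs, labels, ridge_lambda = 1e-3) {
    stopIfNot(ncol(pcs) >= 4L, "need at least four principal components")
    y <- as.numeric(as.logical(labels))
    stopIfNot(length(unique(y)) == 2L, "both labels must be present")
    X <- pcs[, 1:4, drop = FALSE]
    df <- data.frame(y = y, X)
    colnames(df) <- c("y", paste0("PC", 1:4))
    sep <- FALSE
    fit <- withCallingHandlers(
        stats::glm(y ~ ., data = df, family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (sep || !fit$converged) {
        beta <- .ridgeLogistic(X, y, ridge_lambda)
        names(beta) <- c("(Intercept)", paste0("PC", 1:4))
        warning("complete separation; refit with ridge penalty lambda = ",
                ridge_lambda)
        lp <- beta[1L] + as.vector(X %*% beta[-1L])
        return(list(coefficients = beta, ridge = TRUE, fit = NULL,
                    auc = aucScore(lp, y == 1)))
    }
    lp <- stats::predict(fit)
    list(coefficients = stats::coef(fit), ridge = FALSE, fit = fit,
         auc = aucScore(lp, y == 1))
}

#' Per-cell lobulation score
#'
#' The linear predictor (log-odds) of the fitted logistic model over PCs
#' 1-4: high in lobulated cells, low in normal cells, monotone in the
#' predicted probability. Extra PC columns beyond the first four are
#' ignored.
#'
#' @param model A [fitLobulationModel()] result.
#' @param pcs Cells x components matrix.
#' @return Numeric score per cell.
#' @export
lobulationScore <- function(model, pcs) {
    stopIfNot(ncol(pcs) >= 4L, "need at least four principal components")
    beta <- model$coefficients
    beta[1L] + as.vector(pcs[, 1:4, drop = FALSE] %*% beta[-1L])
}

#' Negative-binomial differential expression against the lobulation score
#'
#' For each gene expressed in at least \code{min_cells} cells, fits an NB
#' regression of counts on the lobulation score with the G1 and G2M
#' cell-cycle scores as covariates and log total UMIs as offset. The NB
#' dispersion is a per-gene method-of-moments estimate from Poisson
#' residuals, with a Poisson fallback when the moment estimate is
#' non-positive. Reports the Wald p-value of the lobulation coefficient,
#' the effect size as expected log2 fold change per unit lobulation score
#' (coefficient / ln 2), and BH-adjusted q-values over genes that
#' converged.
#'
#' @param x Counts matrix or \code{SingleCellExperiment}.
#' @param lob_score Per-cell lobulation score.
#' @param g1_score,g2m_score Per-cell cell-cycle covariates.
#' @param min_cells Minimum cells with a nonzero count (default 10).
#' @return data.frame: \code{gene}, \code{coefficient},
#'   \code{effect_size}, \code{p}, \code{q}, \code{n_cells_tested},
#'   \code{converged}.
#' @export
lobulationDE <- function(x, lob_score, g1_score, g2m_score,
                         min_cells = 10L) {
    counts <- .countsMatrix(x)
    stopIfNot(all(is.finite(lob_score)) && all(is.finite(g1_score)) &&
              all(is.finite(g2m_score)), "covariates must be finite")
    stopIfNot(length(lob_score) == ncol(counts), "covariate length mismatch")
    tot <- colSums(counts)
    off <- log(tot)
    test_idx <- which(rowSums(counts > 0) >= min_cells)
    res <- data.frame(gene = rownames(counts) %||%
                          as.character(seq_len(nrow(counts))),
                      coefficient = NA_real_, effect_size = NA_real_,
                      p = NA_real_, q = NA_real_,
                      n_cells_tested = ncol(counts), converged = FALSE,
                      stringsAsFactors = FALSE)
    dat <- data.frame(lob = lob_score, g1 = g1_score, g2m = g2m_score)
    for (i in test_idx) {
        y <- counts[i, ]
        out <- tryCatch({
            pois <- suppressWarnings(stats::glm(y ~ lob + g1 + g2m,
                data = dat, family = stats::poisson(), offset = off))
            mu <- stats::fitted(pois)
            alpha <- sum((y - mu)^2 - mu) / sum(mu^2)
            fit <- if (alpha > 0)
                suppressWarnings(stats::glm(y ~ lob + g1 + g2m, data = dat,
                    family = MASS::negative.binomial(theta = 1 / alpha),
                    offset = off))
            else pois
            cf <- summary(fit)$coefficients
            list(beta = cf["lob", "Estimate"],
                 p = cf["lob", ncol(cf)], ok = fit$converged)
        }, error = function(e) NULL)
        if (is.null(out) || !out$ok || !is.finite(out$p)) next
        res$coefficient[i] <- out$beta
        res$effect_size[i] <- out$beta / log(2)
        res$p[i] <- out$p
        res$converged[i] <- TRUE
    }
    ok <- res$converged
    res$q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
    res
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric test of each gene set's overlap with a list
#' of differentially expressed genes, BH-adjusted across sets. Set
#' members outside the universe are ignored.
#'
#' @param deg Character vector of significant genes (must be a subset of
#'   \code{universe}).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all tested genes.
#' @return data.frame: \code{set}, \code{set_size}, \code{overlap},
#'   \code{p}, \code{p_adj}.
#' @export
overrepresentation <- function(deg, gene_sets, universe) {
    stopIfNot(all(deg %in% universe), "DEG list must lie in the universe")
    if (!length(deg)) {
        warning("empty DEG list")
        return(data.frame(set = character(), set_size = integer(),
                          overlap = integer(), p = numeric(),
                          p_adj = numeric()))
    }
    deg <- unique(deg); universe <- unique(universe)
    rows <- lapply(names(gene_sets), function(nm) {
        set <- intersect(gene_sets[[nm]], universe)
        ov <- length(intersect(set, deg))
        p <- stats::phyper(ov - 1L, length(set),
                           length(universe) - length(set),
                           length(deg), lower.tail = FALSE)
        data.frame(set = nm, set_size = length(set), overlap = ov, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out
}
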