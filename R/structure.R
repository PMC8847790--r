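# Population structure: PCA of standardized genotypes and supervised
# two-way ancestry estimation against founder allele-frequency panels.

#' Principal component analysis of genotypes
#'
#' Standard genotype PCA: each SNP is centered at \eqn{2\hat p} and scaled by
#' \eqn{\sqrt{2\hat p(1-\hat p)}} (Patterson standardization with the plain
#' frequency estimate); missing genotypes are imputed to the SNP mean.  SNPs
#' monomorphic after subsetting are dropped with a warning.  Scores are the
#' projections onto the top \code{k} eigenvectors of the sample covariance;
#' \code{explained} is eigenvalue / trace.
#'
#' Each PC is optionally sign-oriented so that the cohort named by
#' \code{orientPopulation} has a negative mean score, which makes plots
#' reproducible across runs.
#'
#' @param ds a [GenotypeData-class] object (typically the LD-pruned
#'   structure subset).
#' @param k number of components (default 10, capped at the data rank).
#' @param orientPopulation population label used for the sign convention,
#'   or NULL to leave signs as returned by the decomposition.
#' @return list (class \code{"rohscanPCA"}) with \code{scores}
#'   (samples x k, rownames = sample ids), \code{explained} (length-k
#'   fractions of total variance), \code{populations}, and \code{nSnpsUsed}.
#' @export
runPCA <- function(ds, k = 10L, orientPopulation = NULL) {
    d <- dosages(ds)
    p <- rowMeans(d, na.rm = TRUE) / 2
    keep <- is.finite(p) & p > 0 & p < 1
    if (any(!keep))
        warning(sum(!keep), " monomorphic/empty SNPs dropped before PCA")
    d <- d[keep, , drop = FALSE]; p <- p[keep]
    X <- (d - 2 * p) / sqrt(2 * p * (1 - p))
    X[is.na(X)] <- 0
    X <- t(X)                                   # samples x snps
    k <- min(as.integer(k), nrow(X) - 1L, ncol(X))
    if (k < 1L) stop("k must be >= 1 and <= min(n_samples - 1, n_snps)")
    sv <- svd(X, nu = k, nv = 0L)
    scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
    rownames(scores) <- sampleIds(ds)
    colnames(scores) <- paste0("PC", seq_len(k))
    explained <- sv$d^2 / sum(sv$d^2)
    pops <- populations(ds)
    if (!is.null(orientPopulation)) {
        sel <- pops == orientPopulation
        if (any(sel)) {
            flip <- colMeans(scores[sel, , drop = FALSE]) > 0
            scores[, flip] <- -scores[, flip, drop = FALSE]
        }
    }
    structure(list(scores = scores, explained = explained[seq_len(k)],
                   populations = pops, nSnpsUsed = ncol(X)),
              class = "rohscanPCA")
}

#' @export
print.rohscanPCA <- function(x, ...) {
    cat("Genotype PCA:", nrow(x$scores), "samples,", x$nSnpsUsed, "SNPs\n")
    cat("  explained:",
        paste(sprintf("PC%d %.1f%%", seq_along(x$explained),
                      100 * x$explained), collapse = ", "), "\n")
    invisible(x)
}

#' Allele frequencies of one population (an ancestry panel)
#'
#' @param ds a [GenotypeData-class] object.
#' @param population population label; NULL pools all samples.
#' @return numeric vector of allele-b frequencies per SNP, named by snp_id.
#' @export
panelFreqs <- function(ds, population = NULL) {
    d <- dosages(ds)
    if (!is.null(population)) {
        sel <- populations(ds) == population
        if (!any(sel)) stop("no samples in population ", population)
        d <- d[, sel, drop = FALSE]
    }
    setNames(rowMeans(d, na.rm = TRUE) / 2, snpInfo(ds)$snp_id)
}

#' Supervised two-way ancestry estimation
#'
#' Estimates, for every sample, the fraction q of its genome derived from
#' ancestry panel A (versus panel B) by maximizing the binomial likelihood
#' \deqn{\sum_j \log {\rm Binom}(g_j \mid 2,\; q p_{Aj} + (1-q) p_{Bj})}
#' with an EM algorithm on the per-allele ancestry indicators.  This is the
#' two-ancestral-population (K = 2) admixture question posed against two
#' known founder panels: with the panels fixed the likelihood is concave in
#' q and the EM log-likelihood is non-decreasing at every step.
#'
#' @param ds a [GenotypeData-class] object.
#' @param panelA,panelB per-SNP allele-b frequencies aligned with
#'   \code{snpInfo(ds)} (e.g. from [panelFreqs()]); clamped to
#'   \code{[1e-6, 1 - 1e-6]}.
#' @param tol EM convergence tolerance on |dq| (default 1e-6).
#' @param maxIter maximum EM iterations (default 1000).
#' @param traceLoglik if TRUE, attach the per-iteration log-likelihood of
#'   every sample as attribute \code{"loglikTrace"} (a list), so the EM
#'   monotonicity can be audited.
#' @return data.frame (sample_id, population, q_a, loglik, n_iter,
#'   converged); \code{q_a} is NA for samples without genotypes.
#' @export
supervisedAdmixture <- function(ds, panelA, panelB, tol = 1e-6,
                                maxIter = 1000L, traceLoglik = FALSE) {
    d <- dosages(ds)
    m <- nrow(d)
    if (length(panelA) != m || length(panelB) != m)
        stop("panel frequencies must align with the dataset variants")
    pA <- pmin(pmax(as.numeric(panelA), 1e-6), 1 - 1e-6)
    pB <- pmin(pmax(as.numeric(panelB), 1e-6), 1 - 1e-6)
    n <- ncol(d)
    qv <- numeric(n); ll <- numeric(n); it <- integer(n); cv <- logical(n)
    traces <- if (traceLoglik) vector("list", n) else NULL
    for (i in seq_len(n)) {
        g <- d[, i]
        ok <- !is.na(g)
        if (!any(ok)) { qv[i] <- NA_real_; ll[i] <- NA_real_; next }
        gg <- g[ok]; a <- pA[ok]; b <- pB[ok]
        q <- 0.5; iter <- 0L; conv <- FALSE
        trace <- numeric(0)
        repeat {
            iter <- iter + 1L
            pi_ <- q * a + (1 - q) * b
            llNow <- sum(gg * log(pi_) + (2 - gg) * log(1 - pi_))
            if (traceLoglik) trace <- c(trace, llNow)
            expA <- gg * q * a / pi_ + (2 - gg) * q * (1 - a) / (1 - pi_)
            qNew <- sum(expA) / (2 * length(gg))
            done <- abs(qNew - q) < tol || iter >= maxIter
            conv <- abs(qNew - q) < tol
            q <- qNew
            if (done) break
        }
        pi_ <- q * a + (1 - q) * b
        qv[i] <- q
        ll[i] <- sum(gg * log(pi_) + (2 - gg) * log(1 - pi_))
        if (traceLoglik) traces[[i]] <- c(trace, ll[i])
        it[i] <- iter; cv[i] <- conv
    }
    out <- data.frame(sample_id = sampleIds(ds), population = populations(ds),
                      q_a = qv, loglik = ll, n_iter = it, converged = cv,
                      stringsAsFactors = FALSE)
    if (traceLoglik) attr(out, "loglikTrace") <- traces
    out
}
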