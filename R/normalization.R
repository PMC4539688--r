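#' Offset matrix constructor
#'
#' Offsets enter the GLM on the natural-log scale:
#' `o_bi = log(library size_i) + adjustment_bi`, where the adjustment encodes
#' whatever bias a normalization scheme removes. Offsets are only determined
#' up to a per-bin-pair additive constant, so adjustments are stored
#' mean-centred across libraries.
#'
#' @param adjust Numeric matrix (bin pairs x libraries) of natural-log
#'   adjustments; will be mean-centred per row.
#' @param totals Library sizes.
#' @return A numeric matrix of class `"OffsetMatrix"`.
#' @export
offset_matrix <- function(adjust, totals) {
    adjust <- as.matrix(adjust)
    if (ncol(adjust) != length(totals)) stop("adjustment and totals must align")
    if (any(!is.finite(adjust))) stop("offsets must be finite")
    adjust <- adjust - rowMeans(adjust)
    out <- sweep(adjust, 2, log(totals), "+")
    structure(out, class = c("OffsetMatrix", class(out)), totals = totals)
}

#' Library-size-only offsets
#' @param cm A [bin_pair_counts()] object.
#' @return An `"OffsetMatrix"` holding only `log(library size)`.
#' @export
libsize_offsets <- function(cm) {
    stopifnot(inherits(cm, "BinPairCounts"))
    offset_matrix(matrix(0, nrow(cm$counts), ncol(cm$counts)), cm$totals)
}

#' MA statistics between two libraries
#'
#' @param cm A [bin_pair_counts()] object.
#' @param lib1,lib2 Column indices or names.
#' @param prior Prior count.
#' @param offsets Optional `"OffsetMatrix"`; when supplied, M is computed
#'   from offset-corrected counts (used to verify that a normalization
#'   removed its trend).
#' @return data.frame with `A` (average abundance, log2 CPM) and `M`
#'   (library-size-adjusted log2 fold change of `lib2` over `lib1`).
#' @export
ma_statistics <- function(cm, lib1 = 1, lib2 = 2, prior = 2, offsets = NULL) {
    stopifnot(inherits(cm, "BinPairCounts"))
    A <- average_abundance(cm, prior = prior)
    l <- adjusted_log_cpm(cm, prior = prior, offsets = offsets)
    data.frame(A = A, M = l[, lib2] - l[, lib1])
}

# Per-library log2 CPM with library-size-proportional prior; when offsets are
# given, their adjustment component replaces the plain library size.
adjusted_log_cpm <- function(cm, prior = 2, offsets = NULL) {
    y <- cm$counts
    totals <- cm$totals
    prior_i <- prior * totals / mean(totals)
    if (is.null(offsets)) {
        eff <- matrix(rep(totals, each = nrow(y)), nrow(y))
    } else {
        eff <- exp(unclass(offsets))     # per-observation effective size
    }
    log2((sweep(y, 2, prior_i, "+")) / (eff + 2 * mean(prior_i))) + log2(1e6)
}

#' Loess offsets for trended biases
#'
#' Removes abundance-dependent (trended) differences between libraries.
#' For each library, the library-size-adjusted log2 fold change over the
#' across-library mean log-abundance (M) is regressed on the average
#' abundance (A) with loess, using prior counts for stability at low counts.
#' The fitted values, mean-centred across libraries for each bin pair and
#' converted to natural log, become the offset adjustments. After applying
#' the offsets the refitted M-vs-A trend is approximately zero for every
#' library pair.
#'
#' @param cm A filtered [bin_pair_counts()] object with >= 2 libraries.
#' @param span Loess span in (0, 1].
#' @param prior Prior count (default 2).
#' @return An `"OffsetMatrix"`.
#' @export
loess_offsets <- function(cm, span = 0.3, prior = 2) {
    stopifnot(inherits(cm, "BinPairCounts"))
    if (ncol(cm$counts) < 2) stop("loess normalization needs >= 2 libraries")
    if (span <= 0 || span > 1) stop("span must be in (0, 1]")
    A <- average_abundance(cm, prior = prior)
    l <- adjusted_log_cpm(cm, prior = prior)
    ref <- rowMeans(l)
    fitted <- vapply(seq_len(ncol(l)), function(i) {
        limma::loessFit(l[, i] - ref, A, span = span)$fitted
    }, numeric(nrow(l)))
    fitted <- matrix(fitted, nrow = nrow(l))
    offset_matrix(fitted * log(2), cm$totals)
}

#' Scaling offsets (trimmed mean of M values)
#'
#' A single scale factor per library, computed as a doubly-trimmed mean of M
#' values (trimmed by M and by A) against the across-library mean, then
#' anchored so the factors multiply to 1. Used when a trended difference may
#' be biologically meaningful and only simple composition/depth scaling
#' should be removed.
#'
#' @param cm A [bin_pair_counts()] object with >= 2 libraries.
#' @param logratio_trim Two-sided trim fraction on M (default 0.3).
#' @param abundance_trim Two-sided trim fraction on A (default 0.05).
#' @return An `"OffsetMatrix"`; the per-library factors are in
#'   `attr(, "factors")`.
#' @export
scaling_offsets <- function(cm, logratio_trim = 0.3, abundance_trim = 0.05) {
    stopifnot(inherits(cm, "BinPairCounts"))
    y <- cm$counts
    if (ncol(y) < 2) stop("scaling normalization needs >= 2 libraries")
    pos <- rowSums(y == 0) == 0       # positive in every library, as in TMM
    if (!any(pos)) stop("no bin pair with positive counts in all libraries")
    cpm <- sweep(y[pos, , drop = FALSE], 2, cm$totals, "/")
    lcpm <- log2(cpm)
    ref <- rowMeans(lcpm)
    A <- average_abundance(cm)[pos]
    a_keep <- A >= stats::quantile(A, abundance_trim) &
              A <= stats::quantile(A, 1 - abundance_trim)
    logf <- vapply(seq_len(ncol(y)), function(i) {
        M <- lcpm[, i] - ref
        lo <- stats::quantile(M[a_keep], logratio_trim)
        hi <- stats::quantile(M[a_keep], 1 - logratio_trim)
        sel <- a_keep & M >= lo & M <= hi
        if (!any(sel)) stop("all bin pairs trimmed; relax the trim fractions")
        mean(M[sel])
    }, numeric(1))
    logf <- logf - mean(logf)        # geometric-mean anchor
    adjust <- matrix(rep(logf * log(2), each = nrow(y)), nrow(y))
    out <- offset_matrix(adjust, cm$totals)
    attr(out, "factors") <- 2^logf
    out
}

#' CNV-driven bias offsets
#'
#' Copy-number differences between conditions change marginal coverage and,
#' through it, interaction counts. For each library (against the first
#' library as reference) the per-bin marginal log2 fold change `v_b` is
#' computed with a prior; each bin pair then carries the ordered covariate
#' pair `(v_anchor1, v_anchor2)` and its own library-size-adjusted log2 fold
#' change as response. A local-regression surface of the response on the two
#' covariates is fitted and its fitted value (in natural log) becomes the
#' offset adjustment, so that residual fold changes show no systematic
#' dependence on the marginal changes.
#'
#' @param cm A [bin_pair_counts()] object.
#' @param span Loess span for the surface.
#' @param min_pairs Minimum number of bin pairs needed to identify the
#'   surface (default 200).
#' @param covariates `"pair"` fits on the ordered covariate pair (default);
#'   `"sum"` fits on their sum, a fallback for sparse data.
#' @return An `"OffsetMatrix"`.
#' @export
cnv_offsets <- function(cm, span = 0.1, min_pairs = 200,
                        covariates = c("pair", "sum")) {
    stopifnot(inherits(cm, "BinPairCounts"))
    covariates <- match.arg(covariates)
    y <- cm$counts
    if (ncol(y) < 2) stop("CNV normalization needs >= 2 libraries")
    if (nrow(y) < min_pairs) {
        stop(sprintf("CNV surface needs >= %d bin pairs", min_pairs))
    }
    marg <- marginal_counts(cm)
    mtot <- colSums(marg)
    lmarg <- log2(sweep(marg + 0.5, 2, mtot + 1, "/"))
    lcpm <- log2(sweep(sweep(y, 2, 0.5, "+"), 2, cm$totals + 1, "/"))
    adjust <- matrix(0, nrow(y), ncol(y))
    for (i in seq(2, ncol(y))) {
        v <- lmarg[, i] - lmarg[, 1]
        r <- lcpm[, i] - lcpm[, 1]
        v1 <- v[cm$anchor1]; v2 <- v[cm$anchor2]
        lo <- pmin(v1, v2); hi <- pmax(v1, v2)   # symmetric in the anchors
        fit <- if (covariates == "pair") {
            stats::loess(r ~ lo + hi, span = span, degree = 1)
        } else {
            stats::loess(r ~ I(lo + hi), span = span, degree = 1)
        }
        adjust[, i] <- stats::fitted(fit) * log(2)
    }
    offset_matrix(adjust, cm$totals)
}

#' Iterative correction (matrix balancing)
#'
#' Alternating row/column rescaling of a symmetric contact matrix, factoring
#' the interaction intensities into per-bin biases and "true" contact
#' probabilities with equal coverage per retained bin. Provided as a
#' diagnostic and as an alternative normalization; it is not chained into
#' GLM offsets by default.
#'
#' @param mat Square, symmetric, non-negative contact matrix.
#' @param max_iter Maximum iterations (default 50).
#' @param tol Convergence tolerance on the coefficient of variation of the
#'   nonzero row sums (default 1e-6).
#' @param exclusion_fraction Fraction in `[0, 1)` of lowest-coverage bins to
#'   drop before balancing.
#' @return List with `bias` (per-bin multiplicative bias; `NA` for excluded
#'   bins), `matrix` (corrected matrix), `iterations`, and `cv` (final
#'   coefficient of variation).
#' @export
iterative_correction <- function(mat, max_iter = 50, tol = 1e-6,
                                 exclusion_fraction = 0) {
    mat <- as.matrix(mat)
    if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
    if (any(mat < 0)) stop("contact matrix must be non-negative")
    if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat)))) {
        stop("contact matrix must be symmetric")
    }
    if (all(mat == 0)) stop("all-zero contact matrix cannot be balanced")
    if (exclusion_fraction < 0 || exclusion_fraction >= 1) {
        stop("exclusion_fraction must be in [0, 1)")
    }
    n <- nrow(mat)
    cov0 <- rowSums(mat)
    n_excl <- floor(exclusion_fraction * n)
    excluded <- rep(FALSE, n)
    if (n_excl > 0) {
        excluded[order(cov0)[seq_len(n_excl)]] <- TRUE
    }
    W <- mat
    W[excluded, ] <- 0
    W[, excluded] <- 0
    bias <- rep(1, n)
    cv <- Inf
    iter <- 0L
    while (iter < max_iter) {
        s <- rowSums(W)
        active <- !excluded & s > 0
        if (!any(active)) stop("no active bins left to balance")
        cv <- stats::sd(s[active]) / mean(s[active])
        if (is.na(cv)) cv <- 0
        if (cv < tol) break
        delta <- rep(1, n)
        delta[active] <- s[active] / mean(s[active])
        W <- W / outer(delta, delta)
        bias <- bias * delta
        iter <- iter + 1L
    }
    bias[excluded] <- NA_real_
    list(bias = bias, matrix = W, iterations = iter, cv = cv)
}

#' Dense contact matrix for one chromosome
#'
#' Builds the symmetric bin-by-bin contact matrix of a chromosome from the
#' sparse bin-pair counts (summed across the selected libraries), e.g. as
#' input to [iterative_correction()].
#'
#' @param cm A [bin_pair_counts()] object.
#' @param chrom Chromosome name.
#' @param libs Library columns to sum (default all).
#' @return A symmetric numeric matrix.
#' @export
contact_matrix <- function(cm, chrom, libs = seq_len(ncol(cm$counts))) {
    stopifnot(inherits(cm, "BinPairCounts"))
    b <- cm$binmap$bins
    sel_bins <- b$bin[b$chrom == chrom]
    if (length(sel_bins) == 0) stop(sprintf("chromosome '%s' not in BinMap", chrom))
    sel <- cm$anchor1 %in% sel_bins & cm$anchor2 %in% sel_bins
    i <- match(cm$anchor1[sel], sel_bins)
    j <- match(cm$anchor2[sel], sel_bins)
    v <- rowSums(cm$counts[sel, libs, drop = FALSE])
    M <- matrix(0, length(sel_bins), length(sel_bins))
    M[cbind(i, j)] <- v
    M[cbind(j, i)] <- v
    M
}
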