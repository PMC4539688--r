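#' Design matrix for a grouped Hi-C experiment
#'
#' Builds an intercept + treatment-coded design from a group factor and
#' optional blocking factor, so that the second coefficient (or the last
#' group coefficient) is a log fold change between conditions.
#'
#' @param group Factor (or coercible) of experimental conditions, one per
#'   library.
#' @param block Optional blocking factor (paired designs).
#' @return A full-column-rank design matrix.
#' @export
hic_design <- function(group, block = NULL) {
    group <- as.factor(group)
    X <- if (is.null(block)) {
        stats::model.matrix(~group)
    } else {
        stats::model.matrix(~as.factor(block) + group)
    }
    if (qr(X)$rank < ncol(X)) stop("design matrix is not of full column rank")
    colnames(X) <- sub("^group", "", colnames(X))
    X
}

# ---- internal vectorized NB GLM machinery -------------------------------

# Row-wise NB deviance; y, mu are B x n matrices, phi a length-B vector
# (phi = 0 gives Poisson deviance). Uses log1p for stability at small phi.
nb_deviance <- function(y, mu, phi) {
    ylogy <- y * log(ifelse(y > 0, y / mu, 1))
    phim <- phi
    pois <- phim == 0
    out <- matrix(0, nrow(y), ncol(y))
    if (any(pois)) {
        yy <- y[pois, , drop = FALSE]; mm <- mu[pois, , drop = FALSE]
        out[pois, ] <- 2 * (ylogy[pois, , drop = FALSE] - (yy - mm))
    }
    if (any(!pois)) {
        sel <- !pois
        yy <- y[sel, , drop = FALSE]; mm <- mu[sel, , drop = FALSE]
        pp <- phi[sel]
        lr <- log1p(pp * (yy - mm) / (1 + pp * mm))
        out[sel, ] <- 2 * (ylogy[sel, , drop = FALSE] - (yy + 1 / pp) * lr)
    }
    rowSums(out)
}

# Row-wise NB log-likelihood via dnbinom (accurate at extreme size values).
nb_loglik <- function(y, mu, phi) {
    B <- nrow(y)
    out <- matrix(0, B, ncol(y))
    pois <- phi == 0
    if (any(pois)) {
        out[pois, ] <- stats::dpois(y[pois, , drop = FALSE],
                                    mu[pois, , drop = FALSE], log = TRUE)
    }
    if (any(!pois)) {
        sel <- which(!pois)
        out[sel, ] <- stats::dnbinom(y[sel, , drop = FALSE],
                                     size = 1 / phi[sel],
                                     mu = mu[sel, , drop = FALSE], log = TRUE)
    }
    rowSums(out)
}

# Batch solve of per-row p x p symmetric systems. A is B x (p*p)
# (row-major flattening), b is B x p. Closed forms for p = 1, 2; solve()
# loop otherwise.
solve_batch <- function(A, b, p) {
    if (p == 1L) {
        return(matrix(b[, 1] / A[, 1], ncol = 1))
    }
    if (p == 2L) {
        a11 <- A[, 1]; a12 <- A[, 2]; a22 <- A[, 4]
        det <- a11 * a22 - a12^2
        x1 <- (a22 * b[, 1] - a12 * b[, 2]) / det
        x2 <- (a11 * b[, 2] - a12 * b[, 1]) / det
        return(cbind(x1, x2, deparse.level = 0))
    }
    out <- matrix(NA_real_, nrow(A), p)
    for (r in seq_len(nrow(A))) {
        M <- matrix(A[r, ], p, p)
        out[r, ] <- tryCatch(solve(M, b[r, ]), error = function(e) rep(0, p))
    }
    out
}

# Fisher information X' W X per row, flattened B x (p*p), W = mu/(1+phi*mu).
fisher_info <- function(mu, phi, X) {
    W <- mu / (1 + phi * mu)
    p <- ncol(X)
    idx <- expand.grid(j = seq_len(p), k = seq_len(p))
    Xcross <- X[, idx$j, drop = FALSE] * X[, idx$k, drop = FALSE]
    W %*% Xcross
}

# log-determinant of each row's p x p information matrix.
info_logdet <- function(info_flat, p) {
    if (p == 1L) return(log(pmax(info_flat[, 1], 1e-300)))
    if (p == 2L) {
        det <- info_flat[, 1] * info_flat[, 4] - info_flat[, 2]^2
        return(log(pmax(det, 1e-300)))
    }
    apply(info_flat, 1, function(a) {
        d <- det(matrix(a, p, p))
        log(max(d, 1e-300))
    })
}

#' Fit negative-binomial GLMs across bin pairs
#'
#' Fits `E(y_bi) = mu_bi` with `log(mu_bi) = sum_j x_ij beta_bj + o_bi` by
#' maximizing the NB likelihood for every bin pair simultaneously, using
#' vectorized Fisher scoring with Levenberg-style damping. With an
#' intercept-only design and equal offsets the solution is the (offset
#' adjusted) log mean count, for any dispersion. All-zero bin pairs are
#' returned as `NA` (they should be filtered out beforehand).
#'
#' @param cm A [bin_pair_counts()] object, or a bare count matrix.
#' @param design Design matrix (libraries x coefficients), e.g. from
#'   [hic_design()].
#' @param offsets An `"OffsetMatrix"`, a matrix, or `NULL` (library-size
#'   offsets).
#' @param dispersion NB dispersion phi: scalar or per-bin-pair vector
#'   (default 0 = Poisson).
#' @param tol Relative deviance-change convergence tolerance (default 1e-8).
#' @param max_iter Maximum scoring iterations (default 100). Non-converged
#'   fits are flagged and the last iterate returned.
#' @return A list of class `"GLMFit"`: `coefficients` (bin pairs x
#'   coefficients, natural log), `fitted` (means), `deviance`,
#'   `df_residual`, `converged`, plus the inputs.
#' @export
fit_nb_glm <- function(cm, design, offsets = NULL, dispersion = 0,
                       tol = 1e-8, max_iter = 100) {
    y <- if (inherits(cm, "BinPairCounts")) cm$counts else as.matrix(cm)
    X <- as.matrix(design)
    n <- ncol(y); p <- ncol(X); B <- nrow(y)
    if (nrow(X) != n) stop("design rows must match the number of libraries")
    if (is.null(offsets)) {
        offsets <- if (inherits(cm, "BinPairCounts")) libsize_offsets(cm) else
            matrix(0, B, n)
    }
    off <- matrix(as.numeric(offsets), B, n)
    phi <- rep_len(as.numeric(dispersion), B)
    storage.mode(y) <- "double"

    allzero <- rowSums(y) == 0
    active0 <- which(!allzero)
    beta <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(X)))
    dev <- rep(NA_real_, B)
    converged <- rep(NA, B)
    mu_out <- matrix(NA_real_, B, n)
    if (length(active0)) {
        ya <- y[active0, , drop = FALSE]
        offa <- off[active0, , drop = FALSE]
        phia <- phi[active0]
        fit <- nb_glm_engine(ya, X, offa, phia, tol, max_iter)
        beta[active0, ] <- fit$beta
        dev[active0] <- fit$dev
        converged[active0] <- fit$converged
        mu_out[active0, ] <- fit$mu
    }
    structure(
        list(coefficients = beta, fitted = mu_out, deviance = dev,
             df_residual = n - p, converged = converged,
             design = X, offsets = off, dispersion = phi,
             counts = y),
        class = "GLMFit"
    )
}

# Core scoring loop on active rows only.
nb_glm_engine <- function(y, X, off, phi, tol, max_iter) {
    B <- nrow(y); n <- ncol(y); p <- ncol(X)
    # initialize from a weighted least-squares fit to log counts
    mu0 <- (y + rowMeans(y)) / 2
    mu0 <- pmax(mu0, 1e-4)
    z0 <- log(mu0) - off
    w0 <- mu0 / (1 + phi * mu0)
    info0 <- fisher_info_weighted(w0, X)
    diag_idx0 <- (seq_len(p) - 1) * p + seq_len(p)
    info0[, diag_idx0] <- info0[, diag_idx0, drop = FALSE] + 1e-8
    rhs0 <- (w0 * z0) %*% X
    beta <- solve_batch(info0, rhs0, p)

    eta <- off + tcrossprod(beta, X)
    eta <- pmin(eta, 30)
    mu <- exp(eta)
    dev <- nb_deviance(y, mu, phi)
    lambda <- rep(1e-6, B)
    done <- rep(FALSE, B)
    converged <- rep(FALSE, B)
    for (it in seq_len(max_iter)) {
        act <- which(!done)
        if (!length(act)) break
        ya <- y[act, , drop = FALSE]; mua <- mu[act, , drop = FALSE]
        offa <- off[act, , drop = FALSE]; phia <- phi[act]
        W <- mua / (1 + phia * mua)
        U <- ((ya - mua) / (1 + phia * mua)) %*% X
        info <- fisher_info_weighted(W, X)
        diag_idx <- (seq_len(p) - 1) * p + seq_len(p)
        lam <- lambda[act]
        dev_a <- dev[act]
        beta_a <- beta[act, , drop = FALSE]
        accepted <- rep(FALSE, length(act))
        new_beta <- beta_a; new_dev <- dev_a; new_mu <- mua
        for (inner in 1:15) {
            todo <- which(!accepted)
            if (!length(todo)) break
            info_d <- info[todo, , drop = FALSE]
            ridge <- lam[todo] * pmax(apply(
                info_d[, diag_idx, drop = FALSE], 1, max), 1e-10)
            info_d[, diag_idx] <- info_d[, diag_idx, drop = FALSE] + ridge
            delta <- solve_batch(info_d, U[todo, , drop = FALSE], p)
            cand <- beta_a[todo, , drop = FALSE] + delta
            eta_c <- offa[todo, , drop = FALSE] + tcrossprod(cand, X)
            eta_c <- pmin(eta_c, 30)
            mu_c <- exp(eta_c)
            dev_c <- nb_deviance(ya[todo, , drop = FALSE], mu_c, phia[todo])
            ok <- is.finite(dev_c) & dev_c <= dev_a[todo] + 1e-10
            acc <- todo[ok]
            if (length(acc)) {
                new_beta[acc, ] <- cand[ok, , drop = FALSE]
                new_dev[acc] <- dev_c[ok]
                new_mu[acc, ] <- mu_c[ok, , drop = FALSE]
                accepted[acc] <- TRUE
                lam[acc] <- pmax(lam[acc] / 10, 1e-10)
            }
            lam[todo[!ok]] <- lam[todo[!ok]] * 10
        }
        improve <- dev_a - new_dev
        conv_now <- accepted & improve < tol * (abs(new_dev) + 0.1)
        stuck_now <- !accepted                 # step rejected 15x: stuck
        beta[act, ] <- new_beta
        dev[act] <- new_dev
        mu[act, ] <- new_mu
        lambda[act] <- lam
        converged[act[conv_now]] <- TRUE
        done[act[conv_now | stuck_now]] <- TRUE
    }
    list(beta = beta, dev = dev, mu = mu, converged = converged)
}

fisher_info_weighted <- function(W, X) {
    p <- ncol(X)
    idx <- expand.grid(j = seq_len(p), k = seq_len(p))
    Xcross <- X[, idx$j, drop = FALSE] * X[, idx$k, drop = FALSE]
    W %*% Xcross
}

#' @export
print.GLMFit <- function(x, ...) {
    cat(sprintf("GLMFit: %d bin pair(s), %d coefficient(s), residual df %d\n",
                nrow(x$coefficients), ncol(x$coefficients), x$df_residual))
    cat(sprintf("Converged: %d / %d\n", sum(x$converged, na.rm = TRUE),
                sum(!is.na(x$converged))))
    invisible(x)
}

# Cox-Reid adjusted profile log-likelihood per bin pair at a given phi.
cox_reid_apl <- function(y, X, off, phi_scalar) {
    B <- nrow(y)
    phi <- rep(phi_scalar, B)
    fit <- nb_glm_engine(y, X, off, phi, tol = 1e-8, max_iter = 60)
    ll <- nb_loglik(y, fit$mu, phi)
    info <- fisher_info(fit$mu, phi, X)
    ll - 0.5 * info_logdet(info, ncol(X))
}

#' Trended NB dispersion estimation
#'
#' Estimates the biological (negative-binomial) dispersion as a smooth
#' function of average abundance. Bin pairs are grouped into equal-count
#' abundance bins; within each, the Cox-Reid adjusted profile likelihood is
#' summed over member bin pairs on a log-spaced dispersion grid and
#' maximized (with quadratic interpolation between grid points). A loess
#' curve through the per-bin estimates gives the trend, evaluated at each
#' bin pair's abundance with clamped extrapolation. The square root of the
#' trended dispersion is the biological coefficient of variation (BCV).
#'
#' @param cm A filtered [bin_pair_counts()] object (or count matrix).
#' @param design Design matrix.
#' @param offsets Offsets as in [fit_nb_glm()].
#' @param abundance Optional precomputed abundances.
#' @param grid_range Dispersion search range (default `c(1e-6, 2)`).
#' @param grid_length Number of grid points (default 21).
#' @param n_abundance_bins Number of abundance bins; default scales with the
#'   number of bin pairs.
#' @param span Loess span for the trend.
#' @return A list of class `"DispersionFit"`: `dispersion` (per bin pair),
#'   `bcv`, `bin_abundance`, `bin_dispersion`, and `trend_fun(abundance)`.
#' @export
estimate_dispersion_trend <- function(cm, design, offsets = NULL,
                                      abundance = NULL,
                                      grid_range = c(1e-6, 2),
                                      grid_length = 21,
                                      n_abundance_bins = NULL,
                                      span = 0.5) {
    y <- if (inherits(cm, "BinPairCounts")) cm$counts else as.matrix(cm)
    X <- as.matrix(design)
    if (ncol(y) - ncol(X) < 1) stop("no residual df: dispersion needs replication")
    if (is.null(abundance)) {
        abundance <- if (inherits(cm, "BinPairCounts")) average_abundance(cm)
                     else average_abundance(y, totals = pmax(colSums(y), 1))
    }
    if (is.null(offsets)) {
        offsets <- if (inherits(cm, "BinPairCounts")) libsize_offsets(cm) else
            matrix(0, nrow(y), ncol(y))
    }
    off <- matrix(as.numeric(offsets), nrow(y), ncol(y))
    use <- rowSums(y) > 0
    yy <- y[use, , drop = FALSE]
    oo <- off[use, , drop = FALSE]
    ab <- abundance[use]
    B <- nrow(yy)
    if (B < 2) stop("too few usable bin pairs for dispersion estimation")

    grid <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                    length.out = grid_length))
    apl <- vapply(grid, function(g) cox_reid_apl(yy, X, oo, g), numeric(B))
    apl <- matrix(apl, nrow = B)

    if (is.null(n_abundance_bins)) {
        n_abundance_bins <- max(2L, min(20L, floor(B / 200)))
    }
    groups <- cut(rank(ab, ties.method = "first"),
                  breaks = n_abundance_bins, labels = FALSE)
    glevels <- sort(unique(groups))
    bin_ab <- vapply(glevels, function(g) mean(ab[groups == g]), numeric(1))
    bin_phi <- exp(vapply(glevels, function(g) {
        tot <- colSums(apl[groups == g, , drop = FALSE])
        maximize_on_grid(log(grid), tot)
    }, numeric(1)))

    lphi <- log(bin_phi)
    fit <- stats::lowess(bin_ab, lphi, f = max(span, 3 / length(bin_ab)))
    trend_fun <- function(a) {
        exp(stats::approx(fit$x, fit$y, xout = a, rule = 2)$y)
    }
    disp <- rep(NA_real_, length(abundance))
    disp[use] <- trend_fun(ab)
    disp[!use] <- trend_fun(abundance[!use])
    structure(
        list(dispersion = disp, bcv = sqrt(disp),
             bin_abundance = as.numeric(bin_ab), bin_dispersion = bin_phi,
             trend_fun = trend_fun),
        class = "DispersionFit"
    )
}

# Argmax of a tabulated function with quadratic interpolation around the
# best grid point; returns the x location.
maximize_on_grid <- function(x, fx) {
    i <- which.max(fx)
    if (i == 1 || i == length(x)) return(x[i])
    x0 <- x[(i - 1):(i + 1)]; f0 <- fx[(i - 1):(i + 1)]
    denom <- f0[1] - 2 * f0[2] + f0[3]
    if (denom >= 0) return(x[i])
    h <- x0[2] - x0[1]
    x[i] + h * (f0[1] - f0[3]) / (2 * denom)
}

#' @export
print.DispersionFit <- function(x, ...) {
    cat(sprintf("DispersionFit: trended NB dispersion over %d abundance bin(s)\n",
                length(x$bin_abundance)))
    cat(sprintf("BCV range: %.3f - %.3f\n", min(x$bcv, na.rm = TRUE),
                max(x$bcv, na.rm = TRUE)))
    invisible(x)
}

#' Quasi-likelihood dispersions with empirical-Bayes moderation
#'
#' The quasi-NB model allows each bin pair its own variance scaling
#' `sigma2_b` around the NB variance function:
#' `var(y_bi) = sigma2_b * (mu_bi + phi_b * mu_bi^2)`. The raw estimate is
#' the GLM deviance (computed at the trended phi) divided by the residual
#' degrees of freedom. Raw estimates are unstable with few replicates, so an
#' empirical-Bayes step estimates a prior df from the spread of the raw
#' values around their abundance trend (matching moments of a scaled F
#' distribution on the log scale) and squeezes each raw value towards the
#' trend with weight `df / (df + prior df)`. Robust mode winsorizes
#' outliers before the moment estimation so that a few aberrant bin pairs do
#' not inflate the prior spread.
#'
#' @param glmfit A [fit_nb_glm()] result (fitted at the trended dispersion).
#' @param abundance Per-bin-pair average abundance.
#' @param robust Winsorize before moment estimation (default TRUE).
#' @param span Loess span for the abundance trend of the raw values.
#' @param winsor_tail Quantile tails winsorized in robust mode.
#' @return A list of class `"QLFit"`: `s2_raw`, `s2_trend`, `s2_post`,
#'   `df_prior`, `df_residual`.
#' @export
ql_dispersions <- function(glmfit, abundance, robust = TRUE, span = 0.5,
                           winsor_tail = 0.05) {
    stopifnot(inherits(glmfit, "GLMFit"))
    df <- glmfit$df_residual
    if (df < 1) stop("no residual df: QL dispersion needs replication")
    s2_raw <- glmfit$deviance / df
    ok <- !is.na(s2_raw)
    pos <- which(ok & s2_raw > 0)

    z <- log(s2_raw[pos])
    a <- abundance[pos]
    fit <- if (length(unique(a)) > 2 && length(z) >= 10) {
        limma::loessFit(z, a, span = span)$fitted
    } else {
        rep(mean(z), length(z))
    }
    # abundance trend: shape from the log-scale loess, location anchored so
    # that the median of raw/trend matches the median of chi2_df / df --
    # a robust first-moment calibration that does not lean on the exact
    # sampling distribution of the deviance
    shape <- exp(fit)
    anchor <- stats::median(s2_raw[pos] / shape) /
        (stats::qchisq(0.5, df) / df)
    trend_all <- rep(NA_real_, length(s2_raw))
    trend_all[pos] <- shape * anchor
    rest <- ok & s2_raw <= 0
    if (any(rest)) {
        # zero-deviance rows: carry the nearest trend value
        trend_all[rest] <- anchor * exp(stats::approx(
            a, fit, xout = abundance[rest], rule = 2, ties = mean)$y)
    }

    # prior df by moment matching of the log residual spread against the
    # null log(chi2_df / df) reference; heavy tails make the plain variance
    # unstable, so both the residuals and the reference are winsorized at
    # the same tail fraction and the attenuation is corrected via the
    # reference (a deterministic quantile grid stands in for the null)
    r <- z - fit
    ref <- log(stats::qchisq(stats::ppoints(8191), df) / df)
    if (robust && length(r) > 10) {
        q <- stats::quantile(r, c(winsor_tail, 1 - winsor_tail))
        r_w <- pmin(pmax(r, q[1]), q[2])
        qr <- stats::quantile(ref, c(winsor_tail, 1 - winsor_tail))
        ref_w <- pmin(pmax(ref, qr[1]), qr[2])
        kappa <- stats::var(ref_w) / stats::var(ref)
        var_e <- stats::var(r_w) / kappa
    } else {
        var_e <- stats::var(r)
    }
    excess <- var_e - stats::var(ref)
    degenerate <- is.na(var_e) || var_e < 1e-10
    df_prior <- if (degenerate || is.na(excess) || excess <= 0) Inf else
        2 * trigamma_inverse(excess)

    w <- if (is.infinite(df_prior)) 0 else df / (df + df_prior)
    s2_post <- w * s2_raw + (1 - w) * trend_all
    if (degenerate) s2_post <- s2_raw   # no spread at all: raw is exact
    structure(
        list(s2_raw = s2_raw, s2_trend = trend_all, s2_post = s2_post,
             df_prior = df_prior, df_residual = df),
        class = "QLFit"
    )
}

# Newton inversion of the trigamma function (solves trigamma(y) = x).
trigamma_inverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (-dif / y < 1e-8) break
    }
    y
}

#' @export
print.QLFit <- function(x, ...) {
    cat(sprintf("QLFit: residual df %d, prior df %s\n", x$df_residual,
                format(x$df_prior)))
    invisible(x)
}

#' Quasi-likelihood F-test for a contrast
#'
#' Tests `contrast' beta = 0` per bin pair with an F statistic: the deviance
#' drop between the null and full fits (both at the trended NB dispersion)
#' divided by the contrast df, over the squeezed QL dispersion. The null
#' distribution is F with `(contrast df, residual df + prior df)` degrees of
#' freedom, so the empirical-Bayes information sharing is reflected in the
#' denominator df.
#'
#' @param glmfit Full-model [fit_nb_glm()] result.
#' @param qlfit [ql_dispersions()] result.
#' @param contrast Numeric contrast vector (length = number of
#'   coefficients), or a single coefficient index/name to drop.
#' @return A data.frame of class `"TestResult"` with `logFC` (log2, for 1-df
#'   contrasts), `F`, `PValue`, `FDR`.
#' @export
ql_f_test <- function(glmfit, qlfit, contrast) {
    stopifnot(inherits(glmfit, "GLMFit"), inherits(qlfit, "QLFit"))
    X <- glmfit$design
    p <- ncol(X)
    if (length(contrast) == 1 && (is.character(contrast) ||
                                  contrast == round(contrast))) {
        ci <- if (is.character(contrast)) match(contrast, colnames(X)) else
            as.integer(contrast)
        if (is.na(ci) || ci < 1 || ci > p) stop("unknown coefficient")
        cvec <- rep(0, p); cvec[ci] <- 1
    } else {
        cvec <- as.numeric(contrast)
        if (length(cvec) != p) stop("contrast length must match coefficients")
    }
    if (all(cvec == 0)) stop("contrast must be nonzero")
    # null design spans the subspace where the contrast vanishes
    Q <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)
    N <- Q[, -1, drop = FALSE]
    Xnull <- X %*% N
    if (qr(Xnull)$rank < ncol(Xnull)) stop("contrast outside the design space")

    null_fit <- fit_nb_glm(glmfit$counts, Xnull, glmfit$offsets,
                           glmfit$dispersion)
    drop <- pmax(null_fit$deviance - glmfit$deviance, 0)
    df1 <- 1
    Fstat <- (drop / df1) / qlfit$s2_post
    df2 <- qlfit$df_residual + qlfit$df_prior
    pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    logFC <- as.numeric(glmfit$coefficients %*% cvec) / log(2)
    out <- data.frame(logFC = logFC, F = Fstat, PValue = pval,
                      FDR = bh_adjust(pval))
    class(out) <- c("TestResult", "data.frame")
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a p-value vector; `NA` values
#' are propagated.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NA allowed).
#' @return Adjusted values, monotone in the sorted order and capped at 1.
#' @export
bh_adjust <- function(pvalues) {
    stats::p.adjust(pvalues, method = "BH")
}

#' One-stop differential interaction test
#'
#' Runs the full statistical stage: trended NB dispersion, GLM fit, QL
#' dispersion squeeze, and the QL F-test for the requested contrast.
#'
#' @param cm A filtered [bin_pair_counts()] object.
#' @param design Design matrix, e.g. [hic_design()].
#' @param offsets An `"OffsetMatrix"` (default: library sizes only).
#' @param contrast Contrast vector or coefficient (default: last column).
#' @param robust Robust EB moderation (default TRUE).
#' @return A data.frame with bin-pair coordinates and `logFC`, `F`,
#'   `PValue`, `FDR`; the `"GLMFit"`, `"DispersionFit"` and `"QLFit"` are
#'   attached as attributes.
#' @export
test_interactions <- function(cm, design, offsets = NULL,
                              contrast = ncol(design), robust = TRUE) {
    stopifnot(inherits(cm, "BinPairCounts"))
    if (is.null(offsets)) offsets <- libsize_offsets(cm)
    ab <- average_abundance(cm)
    dispfit <- estimate_dispersion_trend(cm, design, offsets, abundance = ab)
    glmfit <- fit_nb_glm(cm, design, offsets, dispersion = dispfit$dispersion)
    qlfit <- ql_dispersions(glmfit, ab, robust = robust)
    res <- ql_f_test(glmfit, qlfit, contrast)
    out <- cbind(pairs_table(cm)[, 1:6], res)
    attr(out, "glmfit") <- glmfit
    attr(out, "dispersion") <- dispfit
    attr(out, "qlfit") <- qlfit
    class(out) <- c("TestResult", "data.frame")
    out
}
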