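two_group_design <- function(reps = 2) hic_design(rep(c("a", "b"), each = reps))

test_that("intercept-only NB fits solve the score equation exactly", {
    X <- matrix(1, 2, 1)
    # saturated mean: counts (6,6) -> beta = ln 6
    f1 <- fit_nb_glm(matrix(c(6, 6), 1, 2), X, offsets = matrix(0, 1, 2),
                     dispersion = 0.3)
    expect_equal(as.numeric(f1$coefficients), log(6), tolerance = 1e-7)
    # counts (2,4): the NB score equation is solved by the mean for any phi
    for (phi in c(0, 0.05, 0.5, 2)) {
        f <- fit_nb_glm(matrix(c(2, 4), 1, 2), X, offsets = matrix(0, 1, 2),
                        dispersion = phi)
        expect_equal(as.numeric(f$coefficients), log(3), tolerance = 1e-7)
    }
    # all-zero bin pairs are skipped with NA
    f0 <- fit_nb_glm(matrix(0, 1, 2), X, offsets = matrix(0, 1, 2))
    expect_true(is.na(f0$coefficients[1, 1]))
    expect_true(is.na(f0$deviance))
})

test_that("phi = 0 reproduces Poisson GLM estimates from an independent fitter", {
    set.seed(14)
    B <- 40; n <- 6
    X <- cbind(1, rep(c(0, 1), each = 3), rnorm(n))
    off <- matrix(rnorm(B * n, 8, 0.2), B, n)
    mu <- exp(off - 4 + rnorm(B))
    y <- matrix(rpois(B * n, mu), B, n)
    fit <- fit_nb_glm(y, X, off, dispersion = 0)
    for (b in seq_len(B)) {
        if (sum(y[b, ]) == 0) next
        ref <- glm(y[b, ] ~ 0 + X, family = poisson(), offset = off[b, ])
        expect_equal(unname(fit$coefficients[b, ]), unname(coef(ref)),
                     tolerance = 1e-5)
        expect_equal(fit$deviance[b], deviance(ref), tolerance = 1e-6)
    }
})

test_that("NB fits agree with the edgeR reference implementation", {
    set.seed(15)
    B <- 200; n <- 4
    X <- two_group_design()
    off <- matrix(log(runif(n, 0.8e6, 1.2e6)), B, n, byrow = TRUE)
    mu <- exp(off + log(runif(B, 1e-5, 5e-4)))
    y <- matrix(rnbinom(B * n, mu = mu, size = 10), B, n)
    phi <- runif(B, 0.01, 0.3)
    fit <- fit_nb_glm(y, X, off, dispersion = phi)
    ref <- edgeR::glmFit(y, X, dispersion = phi, offset = off, prior.count = 0)
    keep <- rowSums(y) > 0
    expect_lt(max(abs(fit$coefficients[keep, ] - ref$coefficients[keep, ])),
              1e-4)
    expect_lt(max(abs(fit$deviance[keep] - ref$deviance[keep])), 1e-4)
})

test_that("group-absorbable offset constants shift logFC but not the F statistic", {
    set.seed(16)
    B <- 300; n <- 4
    X <- two_group_design()
    off <- matrix(log(1e6), B, n)
    mu <- exp(log(runif(B, 1e-5, 3e-4)) + log(1e6))
    y <- matrix(rnbinom(B * n, mu = mu, size = 1 / 0.05), B, n)
    ab <- average_abundance(y, totals = rep(1e6, n))
    run <- function(off) {
        g <- fit_nb_glm(y, X, off, dispersion = 0.05)
        q <- ql_dispersions(g, ab, robust = FALSE)
        ql_f_test(g, q, 2)
    }
    r0 <- run(off)
    # a constant shared by all libraries is absorbed by the intercept and
    # changes nothing at all
    r_all <- run(off + 0.7)
    expect_equal(r_all$F, r0$F, tolerance = 1e-6)
    expect_equal(r_all$logFC, r0$logFC, tolerance = 1e-6)
    # a constant on one group is absorbed by the group coefficient in the
    # full model: same full-model deviance, logFC shifted by -c/log(2)
    cshift <- 0.7
    off2 <- off
    off2[, 3:4] <- off2[, 3:4] + cshift
    g_a <- fit_nb_glm(y, X, off, dispersion = 0.05)
    g_b <- fit_nb_glm(y, X, off2, dispersion = 0.05)
    expect_equal(g_b$deviance, g_a$deviance, tolerance = 1e-6)
    expect_equal(g_b$coefficients[, 2],
                 g_a$coefficients[, 2] - cshift, tolerance = 1e-6)
    expect_equal(g_b$fitted, g_a$fitted, tolerance = 1e-5)
    # and a constant on one library within a group changes fitted means by e^c
    g0 <- fit_nb_glm(y, X, off, dispersion = 0.05)
    off3 <- off; off3[, 1] <- off3[, 1] + 0.3
    g1 <- fit_nb_glm(y, X, off3, dispersion = 0.05)
    rel <- g1$fitted[, 1] / g0$fitted[, 1]
    expect_gt(median(rel, na.rm = TRUE), 1)   # pulled up by the offset
})

test_that("dispersion trend recovers constant truth and the Poisson limit", {
    set.seed(17)
    B <- 4000; n <- 4
    X <- two_group_design()
    off <- matrix(log(1e6), B, n)
    mu <- exp(runif(B, log(8), log(512)))
    y_nb <- matrix(rnbinom(B * n, mu = mu, size = 1 / 0.05), B, n)
    d_nb <- estimate_dispersion_trend(y_nb, X, off,
                                      abundance = log2(mu))
    mid <- abs(log2(mu) - median(log2(mu))) < 1
    expect_gt(mean(d_nb$dispersion[mid]), 0.035)
    expect_lt(mean(d_nb$dispersion[mid]), 0.065)
    y_po <- matrix(rpois(B * n, mu), B, n)
    d_po <- estimate_dispersion_trend(y_po, X, off, abundance = log2(mu))
    expect_lt(max(d_po$dispersion), 0.01)
    expect_equal(d_po$bcv, sqrt(d_po$dispersion))
    # no replication: error
    expect_error(estimate_dispersion_trend(y_nb[, 1:2], diag(2), off[, 1:2]),
                 "residual df|replication")
})

test_that("a decreasing dispersion-abundance relationship is recovered", {
    set.seed(18)
    B <- 6000; n <- 4
    X <- two_group_design()
    off <- matrix(log(1e6), B, n)
    ab <- runif(B, log2(8), log2(512))
    mu <- 2^ab
    phi_true <- 0.12 - 0.015 * (ab - min(ab))    # decreasing with abundance
    y <- matrix(rnbinom(B * n, mu = mu, size = 1 / phi_true), B, n)
    d <- estimate_dispersion_trend(y, X, off, abundance = ab)
    lo <- mean(d$dispersion[ab < quantile(ab, 0.2)])
    hi <- mean(d$dispersion[ab > quantile(ab, 0.8)])
    expect_gt(lo, hi)
    expect_equal(lo, mean(phi_true[ab < quantile(ab, 0.2)]), tolerance = 0.35)
})

test_that("QL squeeze lands between raw and trend with a calibrated centre", {
    set.seed(19)
    B <- 4000; n <- 4
    X <- two_group_design()
    off <- matrix(log(1e6), B, n)
    mu <- exp(runif(B, log(32), log(512)))
    y <- matrix(rnbinom(B * n, mu = mu, size = 1 / 0.05), B, n)
    ab <- log2(mu)
    g <- fit_nb_glm(y, X, off, dispersion = 0.05)
    q <- ql_dispersions(g, ab)
    between <- (q$s2_post >= pmin(q$s2_raw, q$s2_trend) - 1e-10) &
               (q$s2_post <= pmax(q$s2_raw, q$s2_trend) + 1e-10)
    expect_true(all(between, na.rm = TRUE))
    expect_gt(q$df_prior, 0)
    expect_equal(mean(q$s2_post, na.rm = TRUE), 1, tolerance = 0.15)
    # identical raw values: infinite prior df, squeezed equals raw
    g2 <- g
    g2$deviance <- rep(2.4, B)
    q2 <- ql_dispersions(g2, ab, robust = FALSE)
    expect_equal(q2$df_prior, Inf)
    expect_equal(q2$s2_post, q2$s2_raw, tolerance = 1e-10)
})

test_that("the QL F-test is calibrated under the null and degenerate cases", {
    set.seed(20)
    B <- 4000; n <- 4
    X <- two_group_design()
    off <- matrix(log(1e6), B, n)
    mu <- exp(runif(B, log(16), log(512)))
    y <- matrix(rnbinom(B * n, mu = mu, size = 1 / 0.05), B, n)
    ab <- average_abundance(y, totals = rep(1e6, n))
    d <- estimate_dispersion_trend(y, X, off, abundance = ab)
    g <- fit_nb_glm(y, X, off, dispersion = d$dispersion)
    q <- ql_dispersions(g, ab)
    res <- ql_f_test(g, q, 2)
    expect_true(all(res$PValue >= 0 & res$PValue <= 1, na.rm = TRUE))
    ks <- suppressWarnings(ks.test(res$PValue, "punif"))
    expect_gt(ks$p.value, 0.001)
    expect_lt(abs(mean(res$PValue < 0.05, na.rm = TRUE) - 0.05), 0.02)
    # identical counts across libraries: logFC 0, p near 1
    yc <- matrix(77, 1, 4)
    gc <- fit_nb_glm(yc, X, off[1, , drop = FALSE], dispersion = 0.05)
    qc <- list(s2_raw = 1, s2_trend = 1, s2_post = 1, df_prior = 3,
               df_residual = 2)
    class(qc) <- "QLFit"
    resc <- ql_f_test(gc, qc, 2)
    expect_equal(resc$logFC, 0, tolerance = 1e-8)
    expect_gt(resc$PValue, 0.99)
    expect_error(ql_f_test(g, q, rep(0, 2)), "nonzero")
    expect_error(ql_f_test(g, q, 5), "unknown")
})

test_that("large-count F-test p-values approach the normal z-test", {
    set.seed(22)
    B <- 400; n <- 4
    X <- two_group_design()
    off <- matrix(log(1e6), B, n)
    mu <- rep(5e4, B)
    y <- matrix(rpois(B * n, mu), B, n)
    g <- fit_nb_glm(y, X, off, dispersion = 0)
    q <- list(s2_raw = rep(1, B), s2_trend = rep(1, B), s2_post = rep(1, B),
              df_prior = Inf, df_residual = 2)
    class(q) <- "QLFit"
    res <- ql_f_test(g, q, 2)
    # z-test on log ratio of group sums
    s1 <- y[, 1] + y[, 2]; s2 <- y[, 3] + y[, 4]
    z <- (log(s2) - log(s1)) / sqrt(1 / s1 + 1 / s2)
    pz <- 2 * pnorm(-abs(z))
    comparable <- pz > 1e-4
    expect_lt(median(abs(res$PValue[comparable] - pz[comparable]) /
                         pz[comparable]), 0.1)
})

test_that("BH adjustment matches a hand-coded step-up on random vectors", {
    expect_equal(bh_adjust(0.02), 0.02)
    expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
    step_up <- function(p) {          # independent reference implementation
        n <- length(p)
        o <- order(p)
        adj <- numeric(n)
        run_min <- 1
        for (i in n:1) {
            run_min <- min(run_min, n * p[o[i]] / i)
            adj[o[i]] <- run_min
        }
        pmin(adj, 1)
    }
    set.seed(23)
    for (i in 1:25) {
        p <- runif(sample(1:50, 1))^sample(1:3, 1)
        expect_equal(bh_adjust(p), step_up(p))
    }
})

test_that("test_interactions produces a coherent end-to-end result table", {
    sim <- simulate_counts(n_pairs = 1500, dispersion = 0.05, seed = 24,
                           mean_range = c(32, 512))
    res <- test_interactions(sim$counts, hic_design(sim$group))
    expect_equal(nrow(res), 1500)
    expect_true(all(c("chrom1", "start1", "logFC", "F", "PValue", "FDR") %in%
                    names(res)))
    expect_true(all(res$FDR >= res$PValue - 1e-12, na.rm = TRUE))
    # spiked DIs carry larger |logFC| on average
    expect_gt(mean(abs(res$logFC[sim$truth$is_di])),
              mean(abs(res$logFC[!sim$truth$is_di])))
})
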