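coords_df <- function(s1, s2, w = 10) {
    data.frame(chrom1 = "chrA", start1 = s1, end1 = s1 + w - 1,
               chrom2 = "chrA", start2 = s2, end2 = s2 + w - 1)
}

test_that("adjacent bin pairs cluster with single linkage and transitivity", {
    # shared anchor bin, adjacent in the other: one cluster
    cd <- coords_df(c(1, 1), c(11, 21))
    expect_equal(cluster_bin_pairs(cd, max_gap = 0), c(1L, 1L))
    # diagonal chain of three links into one component
    chain <- coords_df(c(1, 11, 21), c(1, 11, 21))
    expect_equal(cluster_bin_pairs(chain, max_gap = 0), rep(1L, 3))
    # too far apart: separate clusters
    apart <- coords_df(c(1, 100), c(1, 200))
    expect_equal(cluster_bin_pairs(apart, max_gap = 5), c(1L, 2L))
    # chromosomes must match on both anchors
    mixed <- coords_df(c(1, 1), c(1, 1))
    mixed$chrom2 <- c("chrA", "chrB")
    expect_equal(cluster_bin_pairs(mixed, max_gap = 0), c(1L, 2L))
    expect_error(cluster_bin_pairs(cd, max_gap = -1), "max_gap")
})

test_that("clustering matches brute-force graph components on random sets", {
    brute_components <- function(cd, max_gap) {
        n <- nrow(cd)
        gap <- function(s1, e1, s2, e2) max(0, max(s2 - e1, s1 - e2) - 1)
        adj <- matrix(FALSE, n, n)
        for (i in seq_len(n)) for (j in seq_len(n)) {
            adj[i, j] <- cd$chrom1[i] == cd$chrom1[j] &&
                cd$chrom2[i] == cd$chrom2[j] &&
                gap(cd$start1[i], cd$end1[i], cd$start1[j], cd$end1[j]) <= max_gap &&
                gap(cd$start2[i], cd$end2[i], cd$start2[j], cd$end2[j]) <= max_gap
        }
        comp <- seq_len(n)
        repeat {
            changed <- FALSE
            for (i in seq_len(n)) for (j in seq_len(n)) {
                if (adj[i, j] && comp[j] != comp[i]) {
                    old <- comp[j]
                    comp[comp == old] <- comp[i]
                    changed <- TRUE
                }
            }
            if (!changed) break
        }
        match(comp, unique(comp))
    }
    set.seed(61)
    for (trial in 1:10) {
        n <- sample(5:30, 1)
        cd <- data.frame(
            chrom1 = sample(c("chrA", "chrB"), n, TRUE),
            start1 = sample(seq(1, 200, by = 10), n, TRUE),
            chrom2 = "chrC", start2 = sample(seq(1, 200, by = 10), n, TRUE))
        cd$end1 <- cd$start1 + 9; cd$end2 <- cd$start2 + 9
        max_gap <- sample(c(0, 5, 15), 1)
        got <- cluster_bin_pairs(cd, max_gap)
        want <- brute_components(cd, max_gap)
        # same partition (ids may be permuted)
        expect_equal(outer(got, got, "=="), outer(want, want, "=="))
    }
})

test_that("clustering is order-invariant and monotone in the gap", {
    set.seed(62)
    n <- 40
    cd <- coords_df(sample(seq(1, 300, 10), n, TRUE),
                    sample(seq(1, 300, 10), n, TRUE))
    id <- cluster_bin_pairs(cd, max_gap = 10)
    perm <- sample(n)
    id_p <- cluster_bin_pairs(cd[perm, ], max_gap = 10)
    expect_equal(outer(id_p, id_p, "=="), outer(id[perm], id[perm], "=="))
    n_small <- max(cluster_bin_pairs(cd, max_gap = 0))
    n_large <- max(cluster_bin_pairs(cd, max_gap = 50))
    expect_lte(n_large, n_small)
})

test_that("cluster reports carry bounding boxes, Simes p and BH across clusters", {
    res <- data.frame(
        chrom1 = "chrA", start1 = c(1, 11, 101), end1 = c(10, 20, 110),
        chrom2 = "chrA", start2 = c(1, 11, 101), end2 = c(10, 20, 110),
        logFC = c(2, 1, -1), F = c(9, 4, 2),
        PValue = c(0.001, 0.01, 0.2), FDR = c(0.003, 0.015, 0.2))
    out <- cluster_results(res, max_gap = 0)
    expect_equal(nrow(out$clusters), 2)
    c1 <- out$clusters[1, ]
    expect_equal(c(c1$start1, c1$end1), c(1, 20))        # bounding box
    expect_equal(c1$PValue, simes_combine(c(0.001, 0.01)))
    expect_equal(c1$logFC, 2)                            # smallest-p member
    expect_equal(out$clusters$FDR, bh_adjust(out$clusters$PValue))
    empty <- cluster_results(res[res$FDR < 1e-6, ], max_gap = 0)
    expect_equal(nrow(empty$clusters), 0)
})

test_that("small bin pairs nest into the parents containing their midpoints", {
    parent_bm <- synthetic_binmap(c(chrA = 2), width = 1e6)   # bins 1, 2
    small <- data.frame(
        chrom1 = "chrA", start1 = c(1, 980001), end1 = c(20000, 1000000),
        chrom2 = "chrA", start2 = c(20001, 1000001), end2 = c(40000, 1020000))
    nest <- nest_bin_pairs(small, parent_bm)
    expect_equal(nest$parent1, c(1, 1))
    expect_equal(nest$parent2, c(1, 2))
    # identical bin sizes: every pair is its own parent
    same <- nest_bin_pairs(small, synthetic_binmap(c(chrA = 51), width = 20000))
    expect_equal(nrow(unique(same)), 2)
    # midpoint outside the parent map errors
    far <- small; far$start2 <- far$start2 + 9e6; far$end2 <- far$end2 + 9e6
    expect_error(nest_bin_pairs(far, parent_bm), "outside")
})

test_that("Simes combination matches its definition and bounds", {
    expect_equal(simes_combine(0.2), 0.2)
    expect_equal(simes_combine(c(0.01, 0.04)), 0.02)
    expect_equal(simes_combine(rep(0.3, 7)), 0.3)
    expect_error(simes_combine(numeric(0)), "empty")
    set.seed(63)
    for (i in 1:50) {
        p <- runif(sample(1:20, 1))^2
        got <- simes_combine(p)
        ps <- sort(p)
        expect_equal(got, min(1, min(length(p) * ps / seq_along(ps))))
        expect_gte(got, min(p))                    # never below the minimum
        expect_lte(got, min(1, length(p) * min(p)))  # never above Bonferroni
    }
})

test_that("multi-resolution consolidation pools children with their parent", {
    parent_bm <- synthetic_binmap(c(chrA = 2), width = 1e6)
    small <- data.frame(
        chrom1 = "chrA", start1 = c(1, 100001, 1000001), end1 = c(1e5, 2e5, 11e5),
        chrom2 = "chrA", start2 = c(1, 100001, 1000001), end2 = c(1e5, 2e5, 11e5),
        PValue = c(0.01, 0.04, 0.5))
    parent <- data.frame(
        chrom1 = "chrA", start1 = c(1, 1000001), end1 = c(1e6, 2e6),
        chrom2 = "chrA", start2 = c(1, 1000001), end2 = c(1e6, 2e6),
        PValue = c(0.02, 0.9))
    out <- consolidate_resolutions(small, parent_bm, parent)
    expect_equal(nrow(out), 2)
    expect_equal(out$n_pooled, c(3, 2))
    expect_equal(out$PValue[1], simes_combine(c(0.01, 0.04, 0.02)))
    expect_equal(out$PValue[2], simes_combine(c(0.5, 0.9)))
    expect_equal(out$FDR, bh_adjust(out$PValue))
})

test_that("plaid rasters place pairs in library-size-scaled pixels", {
    reg1 <- list(chrom = "chrA", start = 1, end = 1000)
    reg2 <- list(chrom = "chrB", start = 1, end = 1000)
    none <- make_pairs(character(0), integer(0), character(0), integer(0))
    r0 <- plot_plaid(none, reg1, reg2, pixel = 100, total = 10, plot = FALSE)
    expect_true(all(r0 == 0))
    one <- make_pairs("chrA", 250, "chrB", 850)
    r1 <- plot_plaid(one, reg1, reg2, pixel = 100, total = 10, plot = FALSE)
    expect_equal(sum(r1 > 0), 1)
    expect_equal(r1[3, 9], 1 / 10)      # box (200,300) x (800,900)
    r2 <- plot_plaid(one, reg1, reg2, pixel = 100, total = 20, plot = FALSE)
    expect_equal(r2[3, 9], r1[3, 9] / 2)  # doubling library size halves intensity
    # drawing path works on a null device
    png_file <- tempfile(fileext = ".png")
    grDevices::png(png_file)
    plot_plaid(one, reg1, reg2, pixel = 100, total = 10)
    grDevices::dev.off()
    expect_true(file.exists(png_file))
})
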