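#' Cluster adjacent bin pairs in the interaction space
#'
#' Builds single-linkage components in which two bin pairs are linked when
#' both anchor-interval gaps are at most `max_gap` (Chebyshev adjacency in
#' the 2-D interaction space, anchors compared on matching chromosomes).
#' Reduces redundancy when a differential signal spreads over several
#' neighbouring bin pairs. Cluster ids are deterministic: clusters are
#' numbered by their first member in input order.
#'
#' @param coords data.frame with `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` (1-based inclusive, as produced by [pairs_table()]).
#' @param max_gap Maximum gap in bp between anchor intervals (>= 0);
#'   touching or overlapping intervals always link.
#' @return Integer cluster id per bin pair.
#' @export
cluster_bin_pairs <- function(coords, max_gap = 0) {
    if (max_gap < 0) stop("max_gap must be non-negative")
    n <- nrow(coords)
    if (n == 0) return(integer(0))
    r1 <- IRanges::IRanges(coords$start1, coords$end1)
    r2 <- IRanges::IRanges(coords$start2, coords$end2)
    h1 <- IRanges::findOverlaps(r1, maxgap = max_gap, drop.self = FALSE,
                                drop.redundant = FALSE)
    h2 <- IRanges::findOverlaps(r2, maxgap = max_gap, drop.self = FALSE,
                                drop.redundant = FALSE)
    key <- function(h) {
        as.numeric(S4Vectors::queryHits(h)) * (n + 1) + S4Vectors::subjectHits(h)
    }
    common <- intersect(key(h1), key(h2))
    qi <- as.integer(common %/% (n + 1))
    si <- as.integer(common %% (n + 1))
    same <- coords$chrom1[qi] == coords$chrom1[si] &
            coords$chrom2[qi] == coords$chrom2[si]
    qi <- qi[same]; si <- si[same]

    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (k in seq_along(qi)) {
        a <- find(qi[k]); b <- find(si[k])
        if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find, integer(1))
    match(root, unique(root))
}

#' Summarize clusters of tested bin pairs
#'
#' One row per cluster: the bounding box of its members in the interaction
#' space, the Simes-combined p-value, its BH-adjusted FDR across clusters,
#' and the log fold change of the member with the smallest p-value.
#'
#' @param results A `"TestResult"` data.frame with coordinates (from
#'   [test_interactions()]).
#' @param max_gap Passed to [cluster_bin_pairs()].
#' @param significant_only Cluster only bin pairs at `fdr_threshold` first
#'   (default FALSE: cluster all supplied bin pairs).
#' @param fdr_threshold FDR cutoff used when `significant_only = TRUE`.
#' @return A list with `clusters` (one row per cluster) and `members`
#'   (per-bin-pair table with its cluster id).
#' @export
cluster_results <- function(results, max_gap = 0, significant_only = FALSE,
                            fdr_threshold = 0.05) {
    res <- as.data.frame(results)
    if (significant_only) res <- res[!is.na(res$FDR) & res$FDR <= fdr_threshold, ]
    if (nrow(res) == 0) {
        return(list(clusters = data.frame(), members = res))
    }
    id <- cluster_bin_pairs(res, max_gap = max_gap)
    res$cluster <- id
    cl <- lapply(split(seq_len(nrow(res)), id), function(ii) {
        sub <- res[ii, ]
        best <- ii[which.min(sub$PValue)]
        data.frame(
            chrom1 = sub$chrom1[1], start1 = min(sub$start1), end1 = max(sub$end1),
            chrom2 = sub$chrom2[1], start2 = min(sub$start2), end2 = max(sub$end2),
            n_members = nrow(sub),
            PValue = simes_combine(sub$PValue),
            logFC = res$logFC[best]
        )
    })
    clusters <- do.call(rbind, cl)
    clusters <- cbind(cluster = as.integer(names(cl)), clusters)
    clusters <- clusters[order(clusters$cluster), , drop = FALSE]
    clusters$FDR <- bh_adjust(clusters$PValue)
    rownames(clusters) <- NULL
    list(clusters = clusters, members = res)
}

#' Nest small bin pairs within larger parent bin pairs
#'
#' Assigns each bin pair of a fine-resolution analysis to the parent bin
#' pair (coarse resolution) whose anchor bins contain its anchor midpoints;
#' every small pair gets exactly one parent.
#'
#' @param small_coords data.frame of fine bin-pair coordinates (1-based, as
#'   from [pairs_table()]).
#' @param parent_binmap The coarse [build_bins()] object.
#' @return data.frame with parent global bin indices `parent1 <= parent2`.
#' @export
nest_bin_pairs <- function(small_coords, parent_binmap) {
    stopifnot(inherits(parent_binmap, "BinMap"))
    mid1 <- floor((small_coords$start1 - 1 + small_coords$end1) / 2)
    mid2 <- floor((small_coords$start2 - 1 + small_coords$end2) / 2)
    p1 <- pos_to_bin(parent_binmap, small_coords$chrom1, mid1)
    p2 <- pos_to_bin(parent_binmap, small_coords$chrom2, mid2)
    data.frame(parent1 = pmin(p1, p2), parent2 = pmax(p1, p2))
}

#' Combine p-values across resolutions
#'
#' Pools, for each parent bin pair, its own p-value (when the parent
#' resolution was tested) together with the p-values of all nested child bin
#' pairs, and combines each pool with Simes' method; the combined values are
#' then BH-adjusted across parents.
#'
#' @param small_results Fine-resolution `"TestResult"` with coordinates.
#' @param parent_binmap Coarse [build_bins()] object.
#' @param parent_results Optional coarse-resolution `"TestResult"`.
#' @return data.frame, one row per parent bin pair: coordinates, number of
#'   pooled p-values, combined `PValue`, `FDR`.
#' @export
consolidate_resolutions <- function(small_results, parent_binmap,
                                    parent_results = NULL) {
    nest <- nest_bin_pairs(as.data.frame(small_results), parent_binmap)
    key <- paste(nest$parent1, nest$parent2)
    pools <- split(small_results$PValue, key)
    if (!is.null(parent_results)) {
        pn <- nest_bin_pairs(as.data.frame(parent_results), parent_binmap)
        pkey <- paste(pn$parent1, pn$parent2)
        for (k in unique(pkey)) {
            pools[[k]] <- c(pools[[k]], parent_results$PValue[pkey == k])
        }
    }
    ids <- do.call(rbind, strsplit(names(pools), " "))
    b <- parent_binmap$bins
    a1 <- as.integer(ids[, 1]); a2 <- as.integer(ids[, 2])
    out <- data.frame(
        chrom1 = b$chrom[a1], start1 = b$start[a1] + 1L, end1 = b$end[a1],
        chrom2 = b$chrom[a2], start2 = b$start[a2] + 1L, end2 = b$end[a2],
        n_pooled = lengths(pools),
        PValue = vapply(pools, simes_combine, numeric(1))
    )
    out$FDR <- bh_adjust(out$PValue)
    ord <- order(a1, a2)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Simes' combined p-value
#'
#' `min_i ( n * p_(i) / i )` over the ascending order statistics: a combined
#' p-value for the global null of a set of tests, valid under positive
#' dependence and never smaller than the smallest member nor larger than the
#' Bonferroni combination.
#'
#' @param pvalues Non-empty numeric vector of p-values (NA dropped).
#' @return The combined p-value.
#' @export
simes_combine <- function(pvalues) {
    pvalues <- pvalues[!is.na(pvalues)]
    n <- length(pvalues)
    if (n == 0) stop("cannot combine an empty p-value set")
    p <- sort(pvalues)
    min(1, min(n * p / seq_len(n)))
}

#' Plaid plot of read-pair density
#'
#' Renders a rectangle of the interaction space as a heat map: read pairs
#' are rasterized into square boxes of `pixel` bp and the colour of each
#' pixel is linear in its count divided by the library size, so intensities
#' are comparable across libraries of different depth.
#'
#' @param pairs An `"hic_pairs"` data.frame (processed read pairs of one
#'   library).
#' @param region1,region2 Lists `list(chrom, start, end)` (1-based) for the
#'   two axes.
#' @param pixel Pixel side length in bp.
#' @param total Library size used for the intensity scale (default: number
#'   of pairs supplied).
#' @param max_intensity Count-per-library-size value mapped to full colour;
#'   defaults to the maximum pixel intensity.
#' @param col High-end colour.
#' @param plot Draw the image (set FALSE to only compute the raster).
#' @return Invisibly, the numeric intensity raster (rows = region1 boxes,
#'   columns = region2 boxes).
#' @export
plot_plaid <- function(pairs, region1, region2, pixel = 1e5, total = NULL,
                       max_intensity = NULL, col = "firebrick", plot = TRUE) {
    stopifnot(inherits(pairs, "hic_pairs"))
    if (is.null(total)) total <- max(nrow(pairs), 1)
    br1 <- seq(region1$start - 1, region1$end + pixel, by = pixel)
    br2 <- seq(region2$start - 1, region2$end + pixel, by = pixel)
    n1 <- length(br1) - 1L; n2 <- length(br2) - 1L
    raster <- matrix(0, n1, n2)
    sel_fwd <- pairs$chrom1 == region1$chrom & pairs$chrom2 == region2$chrom
    sel_rev <- pairs$chrom1 == region2$chrom & pairs$chrom2 == region1$chrom
    add_pairs <- function(pos_a, pos_b) {
        i <- findInterval(pos_a, br1, rightmost.closed = FALSE)
        j <- findInterval(pos_b, br2, rightmost.closed = FALSE)
        ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
        for (k in which(ok)) raster[i[k], j[k]] <<- raster[i[k], j[k]] + 1
    }
    if (any(sel_fwd)) add_pairs(pairs$pos1[sel_fwd], pairs$pos2[sel_fwd])
    same_region <- identical(region1, region2)
    if (any(sel_rev) && !same_region) {
        add_pairs(pairs$pos2[sel_rev], pairs$pos1[sel_rev])
    } else if (same_region) {
        # mirror within one region so the plot is symmetric
        i <- findInterval(pairs$pos2[sel_fwd], br1)
        j <- findInterval(pairs$pos1[sel_fwd], br2)
        ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2 & i != j
        for (k in which(ok)) raster[i[k], j[k]] <- raster[i[k], j[k]] + 1
    }
    raster <- raster / total
    if (plot) {
        if (is.null(max_intensity)) max_intensity <- max(raster, 1e-12)
        pal <- grDevices::colorRampPalette(c("white", col))(100)
        graphics::image(
            x = (br1[-1] + br1[-length(br1)]) / 2,
            y = (br2[-1] + br2[-length(br2)]) / 2,
            z = pmin(raster / max_intensity, 1),
            zlim = c(0, 1), col = pal, useRaster = TRUE,
            xlab = sprintf("%s (bp)", region1$chrom),
            ylab = sprintf("%s (bp)", region2$chrom))
    }
    invisible(raster)
}
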