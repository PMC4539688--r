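#' Direct filter against the non-specific ligation rate
#'
#' Chromosome territories make genuine inter-chromosomal contacts rare, so
#' the median abundance of all inter-chromosomal bin pairs estimates the
#' non-specific ligation rate. The median is taken over the full
#' inter-chromosomal universe: unmaterialized bin pairs enter as zero-count
#' abundances, counted analytically from the universe size rather than being
#' materialized. A bin pair is kept when its abundance exceeds the median by
#' more than `log2(fold)`.
#'
#' @param cm A [bin_pair_counts()] object.
#' @param fold Fold change over the non-specific rate (>= 1; default 5, the
#'   setting used for real-data analyses).
#' @param prior Prior count for [average_abundance()].
#' @return A list of class `"FilterDecision"` with `keep` (logical per bin
#'   pair), `threshold`, and `strategy`.
#' @export
direct_filter <- function(cm, fold = 5, prior = 2) {
    stopifnot(inherits(cm, "BinPairCounts"))
    if (fold < 1) stop("fold must be >= 1")
    ab <- average_abundance(cm, prior = prior)
    inter <- is_inter_chromosomal(cm)
    n_inter_univ <- universe_size(cm$binmap, "inter")
    if (n_inter_univ == 0) stop("direct filter needs inter-chromosomal bin pairs")
    med <- median_with_zeros(ab[inter], n_inter_univ, zero_abundance(cm, prior))
    threshold <- med + log2(fold)
    structure(list(keep = ab > threshold, threshold = threshold,
                   strategy = "direct", abundance = ab),
              class = "FilterDecision")
}

# Median of `obs` padded with (n_total - length(obs)) copies of `zero_value`,
# without materializing them.
median_with_zeros <- function(obs, n_total, zero_value) {
    n_obs <- length(obs)
    n_zero <- n_total - n_obs
    if (n_zero < 0) stop("universe smaller than the observed set")
    if (n_zero == 0) return(stats::median(obs))
    # ranks of the middle order statistic(s) in the padded vector
    k <- if (n_total %% 2 == 1) (n_total + 1) / 2 else c(n_total / 2, n_total / 2 + 1)
    sorted <- sort(obs)
    n_below <- sum(sorted < zero_value)   # observed values sorting below zeros
    val_at <- function(kk) {
        if (kk <= n_below) sorted[kk]
        else if (kk <= n_below + n_zero) zero_value
        else sorted[kk - n_zero]
    }
    mean(vapply(k, val_at, numeric(1)))
}

#' @export
print.FilterDecision <- function(x, ...) {
    cat(sprintf("FilterDecision (%s): keeping %d / %d bin pair(s)\n",
                x$strategy, sum(x$keep), length(x$keep)))
    if (!is.null(x$threshold)) {
        cat(sprintf("Threshold: %s\n", paste(format(x$threshold), collapse = ", ")))
    }
    invisible(x)
}

#' Distance-trend filter for intra-chromosomal bin pairs
#'
#' Most intra-chromosomal contacts reflect the compaction of the linear
#' genome: abundance decays smoothly with genomic distance. A loess trend of
#' abundance against log10 distance is fitted over intra-chromosomal bin
#' pairs, and an intra pair is kept only when its abundance exceeds the
#' fitted value at its distance. Inter-chromosomal pairs are compared against
#' the direct-filter threshold instead.
#'
#' @param cm A [bin_pair_counts()] object with at least 10 intra-chromosomal
#'   bin pairs.
#' @param fold Fold passed to [direct_filter()] for the inter-chromosomal
#'   side.
#' @param span Loess span.
#' @param prior Prior count for [average_abundance()].
#' @return A `"FilterDecision"` with the per-pair fitted threshold.
#' @export
trend_filter <- function(cm, fold = 1, span = 0.3, prior = 2) {
    stopifnot(inherits(cm, "BinPairCounts"))
    ab <- average_abundance(cm, prior = prior)
    inter <- is_inter_chromosomal(cm)
    d <- pair_distance(cm)
    intra <- !inter
    if (sum(intra) < 10) stop("trend filter needs at least 10 intra-chromosomal bin pairs")
    ld <- log10(d[intra] + 1)
    fitted_intra <- if (length(unique(ld)) < 2) {
        warning("degenerate distances; falling back to the mean abundance")
        rep(mean(ab[intra]), sum(intra))
    } else {
        fit <- limma::loessFit(ab[intra], ld, span = span)
        fit$fitted
    }
    threshold <- rep(NA_real_, length(ab))
    threshold[intra] <- fitted_intra
    keep <- logical(length(ab))
    keep[intra] <- ab[intra] > fitted_intra
    if (any(inter)) {
        dfd <- direct_filter(cm, fold = max(fold, 1), prior = prior)
        threshold[inter] <- dfd$threshold
        keep[inter] <- ab[inter] > dfd$threshold
    }
    structure(list(keep = keep, threshold = threshold, strategy = "trend",
                   abundance = ab),
              class = "FilterDecision")
}

#' Peak filter: local enrichment in the 2-D interaction space
#'
#' Selects sharp, punctate interactions ("peaks"): for each bin pair the
#' counts in the square rings of its Chebyshev neighbourhood (radii 1 to
#' `radius`, excluding the pixel itself) are summarized as abundances, and
#' the enrichment score is the pixel abundance minus the largest ring
#' abundance. Neighbourhoods are truncated at the edges of the space and at
#' the diagonal (only canonical pixels are used).
#'
#' @param cm A [bin_pair_counts()] object.
#' @param radius Neighbourhood radius in bins (>= 1).
#' @param threshold Log2 enrichment needed to keep a bin pair (default 0.5).
#' @param prior Prior count used in the abundance transform.
#' @return A `"FilterDecision"` with an `enrichment` score per bin pair.
#' @export
peak_filter <- function(cm, radius = 2, threshold = 0.5, prior = 2) {
    stopifnot(inherits(cm, "BinPairCounts"))
    radius <- as.integer(radius)
    if (radius < 1L) stop("radius must be >= 1")
    per_chrom <- table(cm$binmap$bins$chrom)
    if (radius >= max(per_chrom)) {
        stop("radius larger than the largest chromosome bin count")
    }
    total <- rowSums(cm$counts)
    nb <- n_bins(cm$binmap)
    key <- as.numeric(cm$anchor1 - 1) * nb + cm$anchor2
    lookup <- function(a1, a2) {
        k <- as.numeric(a1 - 1) * nb + a2
        v <- total[match(k, key)]
        ifelse(is.na(v), 0, v)
    }
    mean_total <- sum(cm$totals) / length(cm$totals)
    pixel_ab <- log2((total + prior) / mean_total * 1e6)
    chrom_of <- cm$binmap$bins$chrom
    enrichment <- numeric(length(total))
    for (b in seq_along(total)) {
        a1 <- cm$anchor1[b]; a2 <- cm$anchor2[b]
        ring_ab <- ring_abundances(a1, a2, radius, nb, chrom_of, lookup,
                                   prior, mean_total)
        enrichment[b] <- pixel_ab[b] - max(ring_ab)
    }
    structure(list(keep = enrichment > threshold, threshold = threshold,
                   strategy = "peak", enrichment = enrichment),
              class = "FilterDecision")
}

# Abundance of each square ring (radius 1..radius) around a pixel, truncated
# at chromosome edges and at the diagonal of the canonical space.
ring_abundances <- function(a1, a2, radius, nb, chrom_of, lookup,
                            prior, mean_total) {
    vapply(seq_len(radius), function(r) {
        box <- expand.grid(i = (a1 - r):(a1 + r), j = (a2 - r):(a2 + r))
        ring <- box[pmax(abs(box$i - a1), abs(box$j - a2)) == r, ]
        ring <- ring[ring$i >= 1 & ring$j >= 1 & ring$i <= nb & ring$j <= nb, ]
        # stay on the pixel's chromosome pair and in the canonical triangle
        ring <- ring[ring$i <= ring$j, ]
        ring <- ring[chrom_of[ring$i] == chrom_of[a1] &
                     chrom_of[ring$j] == chrom_of[a2], ]
        if (nrow(ring) == 0L) return(-Inf)
        avg <- mean(lookup(ring$i, ring$j))
        log2((avg + prior) / mean_total * 1e6)
    }, numeric(1))
}

#' Apply a filter decision to a count matrix
#' @param cm A [bin_pair_counts()] object.
#' @param decision A `"FilterDecision"`.
#' @return The filtered `"BinPairCounts"`.
#' @export
apply_filter <- function(cm, decision) {
    stopifnot(inherits(decision, "FilterDecision"))
    subset_pairs(cm, decision$keep)
}
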