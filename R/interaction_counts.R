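#' Bin-pair count matrix
#'
#' The central container of the pipeline: integer read-pair counts for each
#' canonical bin pair (upper triangle of the interaction space) in each
#' library. Only observed bin pairs are materialized; all others are implicit
#' zeros, since the interaction space is quadratic in the number of bins.
#'
#' @param anchor1,anchor2 Global bin indices (see [build_bins()]), with
#'   `anchor1 <= anchor2` (canonical upper-triangle ordering).
#' @param counts Integer matrix, bin pairs in rows, libraries in columns.
#' @param binmap The [build_bins()] object the indices refer to.
#' @param totals Library sizes: total retained read pairs per library.
#'   Defaults to the column sums over materialized bin pairs.
#' @return An object of class `"BinPairCounts"`.
#' @export
bin_pair_counts <- function(anchor1, anchor2, counts, binmap, totals = NULL) {
    stopifnot(inherits(binmap, "BinMap"))
    counts <- as.matrix(counts)
    anchor1 <- as.integer(anchor1)
    anchor2 <- as.integer(anchor2)
    if (length(anchor1) != nrow(counts) || length(anchor2) != nrow(counts)) {
        stop("anchors and count rows must align")
    }
    if (any(anchor1 > anchor2)) stop("anchors must satisfy anchor1 <= anchor2")
    nb <- n_bins(binmap)
    if (length(anchor1) && (min(anchor1) < 1L || max(anchor2) > nb)) {
        stop("anchor indices outside the BinMap")
    }
    if (any(counts < 0)) stop("counts must be non-negative")
    if (is.null(totals)) totals <- colSums(counts)
    if (any(totals < colSums(counts) - 1e-8)) {
        stop("library sizes cannot be smaller than the counted totals")
    }
    if (is.null(colnames(counts))) {
        colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
    }
    structure(
        list(anchor1 = anchor1, anchor2 = anchor2, counts = counts,
             totals = as.numeric(totals), binmap = binmap),
        class = "BinPairCounts"
    )
}

#' @export
print.BinPairCounts <- function(x, ...) {
    cat(sprintf("BinPairCounts: %d bin pair(s) x %d library(ies), %d bins\n",
                nrow(x$counts), ncol(x$counts), n_bins(x$binmap)))
    cat(sprintf("Library sizes: %s\n", paste(format(x$totals), collapse = ", ")))
    invisible(x)
}

#' @export
dim.BinPairCounts <- function(x) dim(x$counts)

#' Keep a subset of bin pairs
#' @param cm A [bin_pair_counts()] object.
#' @param idx Logical or integer row index.
#' @return A `"BinPairCounts"` with the selected bin pairs.
#' @export
subset_pairs <- function(cm, idx) {
    stopifnot(inherits(cm, "BinPairCounts"))
    bin_pair_counts(cm$anchor1[idx], cm$anchor2[idx],
                    cm$counts[idx, , drop = FALSE], cm$binmap, cm$totals)
}

#' Chromosomes of each anchor
#' @param cm A [bin_pair_counts()] object.
#' @return data.frame with `chrom1`, `chrom2`.
#' @export
anchor_chroms <- function(cm) {
    ch <- cm$binmap$bins$chrom
    data.frame(chrom1 = ch[cm$anchor1], chrom2 = ch[cm$anchor2],
               stringsAsFactors = FALSE)
}

#' Inter-chromosomal indicator per bin pair
#' @param cm A [bin_pair_counts()] object.
#' @return Logical vector.
#' @export
is_inter_chromosomal <- function(cm) {
    ch <- cm$binmap$bins$chrom
    ch[cm$anchor1] != ch[cm$anchor2]
}

#' Genomic distance between bin midpoints
#'
#' @param cm A [bin_pair_counts()] object.
#' @return Numeric vector of midpoint distances in bp; `NA` for
#'   inter-chromosomal bin pairs.
#' @export
pair_distance <- function(cm) {
    b <- cm$binmap$bins
    mid <- (b$start + b$end) / 2
    d <- abs(mid[cm$anchor2] - mid[cm$anchor1])
    d[is_inter_chromosomal(cm)] <- NA_real_
    d
}

#' Count read pairs into bin pairs
#'
#' Each read pair increments exactly one canonical bin pair: the pair of bins
#' containing the two 5' positions (half-open bins, so a read exactly on a
#' boundary belongs to the bin starting there). Bin pairs never observed in
#' any library are left implicit.
#'
#' @param pair_stores A named list of `"hic_pairs"` data.frames (one per
#'   library), or a single `"hic_pairs"` object.
#' @param binmap A [build_bins()] object sharing the chromosome namespace.
#' @param totals Optional library sizes; defaults to the number of counted
#'   pairs per library.
#' @return A [bin_pair_counts()] object.
#' @export
count_pairs <- function(pair_stores, binmap, totals = NULL) {
    if (inherits(pair_stores, "hic_pairs")) pair_stores <- list(lib1 = pair_stores)
    if (is.null(names(pair_stores))) {
        names(pair_stores) <- paste0("lib", seq_along(pair_stores))
    }
    nb <- n_bins(binmap)
    keys_per_lib <- lapply(pair_stores, function(pr) {
        pr <- pr[!pr$unmapped, , drop = FALSE]
        if (nrow(pr) == 0L) return(integer(0))
        b1 <- pos_to_bin(binmap, pr$chrom1, pr$pos1)
        b2 <- pos_to_bin(binmap, pr$chrom2, pr$pos2)
        lo <- pmin(b1, b2)
        hi <- pmax(b1, b2)
        as.numeric(lo - 1) * nb + hi      # canonical key, order-invariant
    })
    all_keys <- sort(unique(unlist(keys_per_lib)))
    counts <- matrix(0L, nrow = length(all_keys), ncol = length(pair_stores),
                     dimnames = list(NULL, names(pair_stores)))
    for (i in seq_along(keys_per_lib)) {
        counts[, i] <- tabulate(match(keys_per_lib[[i]], all_keys),
                                nbins = length(all_keys))
    }
    a1 <- as.integer((all_keys - 1) %/% nb + 1)
    a2 <- as.integer((all_keys - 1) %% nb + 1)
    if (is.null(totals)) totals <- vapply(keys_per_lib, length, integer(1))
    bin_pair_counts(a1, a2, counts, binmap, totals)
}

pos_to_bin <- function(binmap, chrom, pos0) {
    out <- integer(length(chrom))
    for (chr in unique(chrom)) {
        sel <- chrom == chr
        out[sel] <- bin_of(binmap, chr, pos0[sel])
    }
    out
}

#' Marginal read counts per bin
#'
#' Counts every read individually (libraries treated as single-end): an
#' off-diagonal bin pair contributes its count to each anchor bin once, a
#' diagonal bin pair contributes twice to its bin. Marginal counts proxy
#' genomic coverage and hence copy number.
#'
#' @param cm A [bin_pair_counts()] object.
#' @return Integer matrix, bins (all bins of the BinMap) x libraries.
#' @export
marginal_counts <- function(cm) {
    stopifnot(inherits(cm, "BinPairCounts"))
    nb <- n_bins(cm$binmap)
    nl <- ncol(cm$counts)
    out <- matrix(0L, nrow = nb, ncol = nl,
                  dimnames = list(NULL, colnames(cm$counts)))
    for (i in seq_len(nl)) {
        y <- cm$counts[, i]
        m <- rowsum_by(y, cm$anchor1, nb) + rowsum_by(y, cm$anchor2, nb)
        out[, i] <- as.integer(m)
    }
    out
}

rowsum_by <- function(x, f, nbins) {
    out <- numeric(nbins)
    agg <- rowsum(x, f)
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
}

#' Average abundance of each bin pair (log2 CPM)
#'
#' The filter statistic: the average log2 count-per-million across libraries,
#' with a prior count scaled per library in proportion to library size (and
#' added twice to the library size in the denominator, so that the statistic
#' is finite and scale-invariant at zero counts).
#'
#' @param cm A [bin_pair_counts()] object (or an integer count matrix, with
#'   `totals` supplied).
#' @param prior Pseudo-count (default 2); must be non-negative.
#' @param totals Library sizes when `cm` is a bare matrix.
#' @return Numeric vector of abundances, one per bin pair.
#' @export
average_abundance <- function(cm, prior = 2, totals = NULL) {
    if (inherits(cm, "BinPairCounts")) {
        y <- cm$counts
        totals <- cm$totals
    } else {
        y <- as.matrix(cm)
        if (is.null(totals)) stop("totals required for a bare count matrix")
    }
    if (prior < 0) stop("prior count must be non-negative")
    if (any(totals <= 0)) stop("library sizes must be positive")
    prior_i <- prior * totals / mean(totals)
    numer <- rowMeans(sweep(y, 2, prior_i, "+"))
    denom <- mean(totals + 2 * prior_i)
    log2(numer / denom * 1e6)
}

#' Abundance of implicit (unobserved) bin pairs
#'
#' The abundance that [average_abundance()] would assign to an all-zero bin
#' pair; used when the full interaction-space universe enters a statistic.
#'
#' @inheritParams average_abundance
#' @return A single abundance value.
#' @export
zero_abundance <- function(cm, prior = 2) {
    stopifnot(inherits(cm, "BinPairCounts"))
    totals <- cm$totals
    prior_i <- prior * totals / mean(totals)
    log2(mean(prior_i) / mean(totals + 2 * prior_i) * 1e6)
}

#' Drop bin pairs anchored on given chromosomes
#'
#' Typically used to discard chromosome Y, avoiding spurious differential
#' calls driven by sex differences between samples.
#'
#' @param cm A [bin_pair_counts()] object.
#' @param chroms Chromosome names to exclude.
#' @return A `"BinPairCounts"` without bin pairs touching those chromosomes.
#' @export
exclude_chromosomes <- function(cm, chroms) {
    stopifnot(inherits(cm, "BinPairCounts"))
    known <- unique(cm$binmap$bins$chrom)
    unknown <- setdiff(chroms, known)
    if (length(unknown)) {
        warning(sprintf("unknown chromosome(s) ignored: %s",
                        paste(unknown, collapse = ", ")))
    }
    ac <- anchor_chroms(cm)
    keep <- !(ac$chrom1 %in% chroms | ac$chrom2 %in% chroms)
    subset_pairs(cm, keep)
}

#' Total number of bin pairs in the interaction-space universe
#'
#' Counts all canonical bin pairs (including the diagonal), or only the
#' inter-chromosomal ones.
#'
#' @param binmap A [build_bins()] object.
#' @param what `"all"` or `"inter"`.
#' @return Number of bin pairs.
#' @export
universe_size <- function(binmap, what = c("all", "inter")) {
    what <- match.arg(what)
    nb_per_chrom <- table(factor(binmap$bins$chrom,
                                 levels = names(binmap$boundaries)))
    nb <- sum(nb_per_chrom)
    total <- nb * (nb + 1) / 2
    intra <- sum(nb_per_chrom * (nb_per_chrom + 1) / 2)
    switch(what, all = total, inter = total - intra)
}

#' Bin-pair table with genomic coordinates
#'
#' @param cm A [bin_pair_counts()] object.
#' @param extra Optional data.frame of per-bin-pair columns to append.
#' @param zero_based Use 0-based half-open coordinates (BEDPE style) instead
#'   of the default 1-based inclusive report coordinates.
#' @return A data.frame with coordinates and one count column per library.
#' @export
pairs_table <- function(cm, extra = NULL, zero_based = FALSE) {
    stopifnot(inherits(cm, "BinPairCounts"))
    b <- cm$binmap$bins
    off <- if (zero_based) 0L else 1L
    out <- data.frame(
        chrom1 = b$chrom[cm$anchor1],
        start1 = b$start[cm$anchor1] + off, end1 = b$end[cm$anchor1],
        chrom2 = b$chrom[cm$anchor2],
        start2 = b$start[cm$anchor2] + off, end2 = b$end[cm$anchor2],
        stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(cm$counts))
    if (!is.null(extra)) out <- cbind(out, extra)
    out
}

#' Write a bin-pair count table as TSV
#' @param cm A [bin_pair_counts()] object.
#' @param path Output path.
#' @param extra Optional per-bin-pair columns (e.g. filter decisions).
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path, extra = NULL) {
    utils::write.table(pairs_table(cm, extra), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write bin pairs as BEDPE
#' @param cm A [bin_pair_counts()] object.
#' @param path Output path.
#' @param scores Optional numeric score per bin pair (defaults to summed
#'   counts).
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(cm, path, scores = NULL) {
    tab <- pairs_table(cm, zero_based = TRUE)
    if (is.null(scores)) scores <- rowSums(cm$counts)
    bedpe <- data.frame(tab$chrom1, tab$start1, tab$end1,
                        tab$chrom2, tab$start2, tab$end2,
                        name = paste0("bp", seq_len(nrow(tab))),
                        score = scores)
    utils::write.table(bedpe, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
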