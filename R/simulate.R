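#' Synthetic bin map
#'
#' A BinMap built directly from bin counts and a fixed width, without a
#' genome or digest, used to give simulated counts a realistic interaction
#' space (intra- and inter-chromosomal structure) for filters and
#' normalization.
#'
#' @param bins_per_chrom Named integer vector: bins per chromosome.
#' @param width Bin width in bp.
#' @return A `"BinMap"` object.
#' @export
synthetic_binmap <- function(bins_per_chrom = c(chrA = 75, chrB = 75),
                             width = 1e5) {
    if (is.null(names(bins_per_chrom))) {
        names(bins_per_chrom) <- paste0("chr", seq_along(bins_per_chrom))
    }
    boundaries <- lapply(bins_per_chrom, function(nb) as.integer(width * (0:nb)))
    seqlengths <- vapply(boundaries, max, numeric(1))
    bins <- do.call(rbind, lapply(names(boundaries), function(chr) {
        b <- boundaries[[chr]]
        data.frame(chrom = chr, start = b[-length(b)], end = b[-1])
    }))
    bins$bin <- seq_len(nrow(bins))
    structure(list(boundaries = boundaries, width = width,
                   seqlengths = seqlengths, bins = bins),
              class = "BinMap")
}

#' Simulate overdispersed bin-pair counts with spiked differential
#' interactions
#'
#' Emulates a multi-group Hi-C bin-pair count matrix: baseline expected
#' counts are drawn log-uniformly and mapped onto randomly chosen canonical
#' bin pairs of a synthetic interaction space; a fraction of bin pairs are
#' true differential interactions whose mean is multiplied by `fold` in one
#' group (direction alternating); counts are drawn from a negative binomial
#' with dispersion `dispersion` independently per replicate. The same seed
#' always reproduces the same matrix.
#'
#' @param n_pairs Number of materialized bin pairs (default 10000).
#' @param n_groups Number of biological conditions (default 2).
#' @param n_replicates Replicates per group (default 2; must be >= 2 for
#'   dispersion estimation downstream).
#' @param lib_size Nominal library scale; baseline means are drawn for a
#'   1e6-pair library and scaled by `lib_size / 1e6` (default 1e6).
#' @param dispersion NB dispersion phi between replicates (>= 0; 0 gives
#'   Poisson counts).
#' @param di_fraction Fraction of bin pairs spiked as true DIs (default 0.1).
#' @param fold Fold change applied to spiked bin pairs (default 4).
#' @param mean_range Log-uniform range of baseline expected counts
#'   (default c(8, 512)).
#' @param binmap Interaction space (default [synthetic_binmap()]).
#' @param seed Optional RNG seed for full reproducibility.
#' @return A list with `counts` (a [bin_pair_counts()]), `truth` (data.frame
#'   with `is_di`, `true_logfc` in log2, `mean_base`), and `params`.
#' @export
simulate_counts <- function(n_pairs = 10000, n_groups = 2, n_replicates = 2,
                            lib_size = 1e6, dispersion = 0.05,
                            di_fraction = 0.1, fold = 4,
                            mean_range = c(8, 512),
                            binmap = synthetic_binmap(), seed = NULL) {
    if (n_replicates < 2) stop("need >= 2 replicates per group")
    if (dispersion < 0 || di_fraction < 0 || di_fraction > 1 || fold < 1) {
        stop("invalid simulation parameters")
    }
    if (!is.null(seed)) set.seed(seed)
    nb <- n_bins(binmap)
    n_univ <- nb * (nb + 1) / 2
    if (n_pairs > n_univ) stop("more bin pairs requested than the space holds")
    # sample canonical keys without replacement
    keys <- sample.int(n_univ, n_pairs)
    # invert triangular indexing: key -> (a1, a2), a1 <= a2 (row-major upper)
    a1 <- findInterval(keys - 1, cumsum(nb:1), rightmost.closed = FALSE) + 1L
    offset_in_row <- keys - 1 - c(0, cumsum(nb:1))[a1]
    a2 <- a1 + as.integer(offset_in_row)
    ord <- order(a1, a2)
    a1 <- a1[ord]; a2 <- a2[ord]

    mean_base <- exp(stats::runif(n_pairs, log(mean_range[1]),
                                  log(mean_range[2]))) * lib_size / 1e6
    is_di <- rep(FALSE, n_pairs)
    is_di[sample.int(n_pairs, round(di_fraction * n_pairs))] <- TRUE
    direction <- ifelse(stats::rbinom(n_pairs, 1, 0.5) == 1, 1, -1)
    true_logfc <- ifelse(is_di, direction * log2(fold), 0)

    group <- factor(rep(paste0("g", seq_len(n_groups)), each = n_replicates))
    n_libs <- n_groups * n_replicates
    # fold applied to the last group, centred so average abundance is stable
    mean_mat <- matrix(mean_base, n_pairs, n_libs)
    in_last <- group == levels(group)[n_groups]
    mean_mat[, in_last] <- mean_mat[, in_last] * 2^(true_logfc / 2)
    mean_mat[, !in_last] <- mean_mat[, !in_last] * 2^(-true_logfc / 2)
    counts <- matrix(0L, n_pairs, n_libs)
    for (i in seq_len(n_libs)) {
        counts[, i] <- if (dispersion == 0) {
            stats::rpois(n_pairs, mean_mat[, i])
        } else {
            stats::rnbinom(n_pairs, mu = mean_mat[, i], size = 1 / dispersion)
        }
    }
    colnames(counts) <- paste0(group, "_r", rep(seq_len(n_replicates), n_groups))
    cm <- bin_pair_counts(a1, a2, counts, binmap)
    truth <- data.frame(is_di = is_di, true_logfc = true_logfc,
                        mean_base = mean_base)
    list(counts = cm, truth = truth, group = group,
         params = list(n_pairs = n_pairs, n_groups = n_groups,
                       n_replicates = n_replicates, lib_size = lib_size,
                       dispersion = dispersion, di_fraction = di_fraction,
                       fold = fold, mean_range = mean_range, seed = seed))
}

#' Exact two-sided binomial comparator
#'
#' The test used by simpler two-library tools: for each bin pair, an exact
#' two-sided binomial test of `y1` successes in `y1 + y2` trials with
#' success probability `N1 / (N1 + N2)`. It accounts only for sequencing
#' (sampling) variability, not biological replication.
#'
#' @param y1,y2 Count vectors of the two libraries.
#' @param n1,n2 Library sizes.
#' @return Vector of p-values; bin pairs with zero total count get p = 1.
#' @export
binomial_comparator <- function(y1, y2, n1, n2) {
    pr <- n1 / (n1 + n2)
    tot <- y1 + y2
    vapply(seq_along(y1), function(i) {
        n <- tot[i]
        if (n == 0) return(1)
        d <- stats::dbinom(0:n, n, pr)
        sum(d[d <= d[y1[i] + 1] * (1 + 1e-7)])
    }, numeric(1))
}

#' Binomial detection with pooled replicates
#'
#' Pools replicates within each of two groups (summing counts and library
#' sizes) and applies [binomial_comparator()] with BH correction.
#'
#' @param cm A [bin_pair_counts()] object.
#' @param group Two-level factor over libraries.
#' @param nominal_fdr Detection threshold on the BH-adjusted values.
#' @return List with `pvalue`, `fdr`, `detected`.
#' @export
binomial_pooled_detect <- function(cm, group, nominal_fdr = 0.05) {
    group <- as.factor(group)
    if (nlevels(group) != 2) stop("binomial comparator needs exactly two groups")
    g1 <- group == levels(group)[1]
    y1 <- rowSums(cm$counts[, g1, drop = FALSE])
    y2 <- rowSums(cm$counts[, !g1, drop = FALSE])
    p <- binomial_comparator(y1, y2, sum(cm$totals[g1]), sum(cm$totals[!g1]))
    fdr <- bh_adjust(p)
    list(pvalue = p, fdr = fdr, detected = fdr <= nominal_fdr)
}

#' Binomial detection intersected over replicate pairings
#'
#' The ad hoc workaround for replicate variability in binomial testing: run
#' the two-library test for every between-group pairing of libraries and
#' keep only bin pairs detected in all of them.
#'
#' @inheritParams binomial_pooled_detect
#' @return List with `detected` (intersection) and `per_pairing` (matrix of
#'   detection flags).
#' @export
binomial_intersection_detect <- function(cm, group, nominal_fdr = 0.05) {
    group <- as.factor(group)
    if (nlevels(group) != 2) stop("binomial comparator needs exactly two groups")
    i1 <- which(group == levels(group)[1])
    i2 <- which(group == levels(group)[2])
    combos <- expand.grid(a = i1, b = i2)
    det <- vapply(seq_len(nrow(combos)), function(k) {
        a <- combos$a[k]; b <- combos$b[k]
        p <- binomial_comparator(cm$counts[, a], cm$counts[, b],
                                 cm$totals[a], cm$totals[b])
        bh_adjust(p) <= nominal_fdr
    }, logical(nrow(cm$counts)))
    det <- matrix(det, nrow = nrow(cm$counts))
    list(detected = rowSums(det) == ncol(det), per_pairing = det)
}

#' Observed FDR and true-positive count of a detection set
#'
#' @param detected Logical detection flags per bin pair.
#' @param is_di True DI flags, aligned with `detected`.
#' @return List with `observed_fdr` (false detections over `max(1,
#'   detections)`), `true_positives`, `detections`.
#' @export
evaluate_detection <- function(detected, is_di) {
    if (length(detected) != length(is_di)) {
        stop("detection flags and truth are misaligned")
    }
    detected <- detected & !is.na(detected)
    n_det <- sum(detected)
    fp <- sum(detected & !is_di)
    list(observed_fdr = fp / max(1, n_det),
         true_positives = sum(detected & is_di),
         detections = n_det)
}

#' Random genome for simulations
#'
#' Uniform-random A/C/G/T chromosomes; restriction sites of any enzyme occur
#' at their background frequency (about one per 4^site-length bp).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param seed Optional RNG seed.
#' @return Named character vector of sequences.
#' @export
random_genome <- function(chrom_lengths = c(chrA = 50000, chrB = 50000),
                          seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    vapply(chrom_lengths, function(n) {
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
}

#' Simulate chimeric Hi-C reads across ligation junctions
#'
#' Each simulated ligation product joins the filled-in ends of two
#' restriction fragments: the left side of the product runs up to
#' `site start + p + L` on one chromosome and the right side starts at
#' `site start + p` on another (p = cut offset, L = overhang), so the
#' junction carries the exact ligation signature. A read of fixed length is
#' sampled across the junction at a random offset; the truth table records
#' the genomic origin of the read's 5' base and of the 3'-side locus.
#'
#' @param genome Named character vector / DNAStringSet / FASTA path.
#' @param enz An [enzyme()] object; must cut the genome at least twice.
#' @param n_reads Number of reads.
#' @param read_length Read length in nt (default 75).
#' @param seed Optional RNG seed.
#' @return List with `reads` (character vector) and `truth` (data.frame:
#'   `chrom5`, `pos5` 0-based position of the read's 5' base, `offset`
#'   bases taken from the 5'-side fragment, `has_signature`).
#' @export
simulate_chimeric_reads <- function(genome, enz, n_reads, read_length = 75,
                                    seed = NULL) {
    seqs <- load_genome(genome)
    if (!is.null(seed)) set.seed(seed)
    sig <- ligation_signature(enz)
    p <- enz$cut_offset
    L <- enz$overhang
    len_rec <- nchar(enz$recognition)
    sites <- lapply(seq_along(seqs), function(i) {
        BiocGenerics::start(Biostrings::matchPattern(enz$recognition, seqs[[i]],
                                                     fixed = TRUE)) - 1L
    })
    names(sites) <- names(seqs)
    chars <- stats::setNames(
        lapply(seq_along(seqs), function(i) as.character(seqs[[i]])),
        names(seqs))
    # need enough flanking sequence on both sides of each junction
    usable <- lapply(names(sites), function(chr) {
        s <- sites[[chr]]
        s[s >= read_length & s + len_rec + read_length <= nchar(chars[[chr]])]
    })
    names(usable) <- names(sites)
    pool <- do.call(rbind, lapply(names(usable), function(chr) {
        if (length(usable[[chr]]) == 0) return(NULL)
        data.frame(chrom = chr, site = usable[[chr]])
    }))
    if (is.null(pool) || nrow(pool) < 2) {
        stop("enzyme recognition site absent (or too close to the ends) in the genome")
    }
    left_i <- sample.int(nrow(pool), n_reads, replace = TRUE)
    right_i <- sample.int(nrow(pool), n_reads, replace = TRUE)
    offset <- sample.int(read_length + 1L, n_reads, replace = TRUE) - 1L

    reads <- character(n_reads)
    chrom5 <- character(n_reads)
    pos5 <- integer(n_reads)
    for (k in seq_len(n_reads)) {
        lc <- pool$chrom[left_i[k]]; ls <- pool$site[left_i[k]]
        rc <- pool$chrom[right_i[k]]; rs <- pool$site[right_i[k]]
        left_end0 <- ls + p + L                      # half-open end on left chrom
        right_start0 <- rs + p
        off <- offset[k]
        left_part <- if (off > 0) {
            substr(chars[[lc]], left_end0 - off + 1L, left_end0)
        } else ""
        right_part <- if (off < read_length) {
            substr(chars[[rc]], right_start0 + 1L, right_start0 + (read_length - off))
        } else ""
        reads[k] <- paste0(left_part, right_part)
        if (off > 0) {
            chrom5[k] <- lc
            pos5[k] <- left_end0 - off
        } else {
            chrom5[k] <- rc
            pos5[k] <- right_start0
        }
    }
    half <- nchar(sig) %/% 2L
    has_sig <- offset >= half & (read_length - offset) >= half
    list(reads = reads,
         truth = data.frame(chrom5 = chrom5, pos5 = pos5, offset = offset,
                            has_signature = has_sig,
                            stringsAsFactors = FALSE))
}

#' Write simulated reads as FASTA
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- paste0("read", seq_along(reads))
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Benchmark differential-interaction detection on spiked simulations
#'
#' Runs the full detection study: for each iteration, simulates overdispersed
#' counts with spiked DIs, applies the package pipeline (direct filter at
#' five-fold over the non-specific rate, loess offsets, quasi-NB GLM with the
#' QL F-test) and the two binomial comparators (replicates pooled per group;
#' detections intersected over all between-group pairings), and scores each
#' detection set against the simulation truth.
#'
#' @param n_iterations Number of simulation iterations (default 5).
#' @param nominal_fdr Detection threshold on BH-adjusted values (default
#'   0.05).
#' @param seed Base seed; iteration i uses `seed * 1000 + i`.
#' @param filter_fold Fold for the direct filter (default 5).
#' @param ... Passed to [simulate_counts()] (e.g. `dispersion`, `n_pairs`).
#' @return A list with `iterations` (data.frame: method, iteration,
#'   observed_fdr, true_positives, detections, tested) and `summary`
#'   (per-method means and standard errors).
#' @export
benchmark_detection <- function(n_iterations = 5, nominal_fdr = 0.05,
                                seed = 1, filter_fold = 5, ...) {
    rows <- list()
    for (it in seq_len(n_iterations)) {
        sim <- simulate_counts(seed = seed * 1000 + it, ...)
        cm <- sim$counts
        keep <- direct_filter(cm, fold = filter_fold)$keep
        kept <- subset_pairs(cm, keep)
        truth <- sim$truth$is_di[keep]
        design <- hic_design(sim$group)
        offsets <- loess_offsets(kept)
        res <- test_interactions(kept, design, offsets)
        det_ql <- !is.na(res$FDR) & res$FDR <= nominal_fdr
        det_bin <- binomial_pooled_detect(kept, sim$group, nominal_fdr)$detected
        det_int <- binomial_intersection_detect(kept, sim$group,
                                                nominal_fdr)$detected
        for (m in c("ql", "binomial", "intersection")) {
            det <- switch(m, ql = det_ql, binomial = det_bin,
                          intersection = det_int)
            ev <- evaluate_detection(det, truth)
            rows[[length(rows) + 1]] <- data.frame(
                method = m, iteration = it, observed_fdr = ev$observed_fdr,
                true_positives = ev$true_positives,
                detections = ev$detections, tested = length(truth))
        }
    }
    iterations <- do.call(rbind, rows)
    summary <- do.call(rbind, lapply(split(iterations, iterations$method),
        function(d) {
            data.frame(method = d$method[1],
                       mean_fdr = mean(d$observed_fdr),
                       se_fdr = stats::sd(d$observed_fdr) /
                           sqrt(nrow(d)),
                       mean_tp = mean(d$true_positives),
                       se_tp = stats::sd(d$true_positives) / sqrt(nrow(d)))
        }))
    rownames(summary) <- NULL
    list(iterations = iterations, summary = summary)
}

#' Null-calibration study of the QL pipeline
#'
#' Simulates zero-effect data, runs the filter + loess + QL pipeline, and
#' returns the tested p-values (for uniformity checks) along with the
#' fraction significant at a nominal level.
#'
#' @param nominal Significance level for the rejection-rate summary.
#' @param seed Seed passed to [simulate_counts()].
#' @param filter_fold Fold for the direct filter.
#' @param ... Passed to [simulate_counts()]; `di_fraction` is forced to 0.
#' @return List with `pvalue`, `n_tested`, `rejection_rate`.
#' @export
null_calibration <- function(nominal = 0.05, seed = 1, filter_fold = 5, ...) {
    args <- list(...)
    args$di_fraction <- 0
    args$seed <- seed
    sim <- do.call(simulate_counts, args)
    cm <- sim$counts
    kept <- apply_filter(cm, direct_filter(cm, fold = filter_fold))
    res <- test_interactions(kept, hic_design(sim$group), loess_offsets(kept))
    p <- res$PValue[!is.na(res$PValue)]
    list(pvalue = p, n_tested = length(p),
         rejection_rate = mean(p < nominal))
}
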