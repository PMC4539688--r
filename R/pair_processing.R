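#' Split a read sequence at the ligation signature
#'
#' A chimeric Hi-C read spans a proximity-ligation junction: its 5' and 3'
#' segments come from different genomic loci. The junction carries the known
#' ligation signature, so the read can be split at the signature centre before
#' alignment. If the signature is absent the whole read is returned as the 5'
#' segment; if it occurs more than once the 5'-most occurrence is used.
#'
#' @param read_sequence Read sequence (character).
#' @param signature Ligation signature (character, even length by
#'   construction; see [ligation_signature()]).
#' @return Character vector: `c(five_prime)` or
#'   `c(five_prime, three_prime)`. An empty read gives `character(0)` with a
#'   warning.
#' @export
split_read_at_signature <- function(read_sequence, signature) {
    read_sequence <- as.character(read_sequence)
    if (nchar(read_sequence) == 0L) {
        warning("empty read sequence; nothing to split")
        return(character(0))
    }
    hit <- regexpr(signature, read_sequence, fixed = TRUE)
    if (hit < 0L) {
        return(read_sequence)
    }
    centre <- as.integer(hit) - 1L + nchar(signature) %/% 2L   # 0-based split point
    c(substr(read_sequence, 1L, centre),
      substr(read_sequence, centre + 1L, nchar(read_sequence)))
}

#' Load Hi-C read pairs from a name-sorted SAM/BAM file
#'
#' Reads a name-sorted alignment file and assembles one pair record per
#' template, taking the primary alignment of each read as its 5' segment
#' (after pre-splitting, the 5' segment is aligned as the primary record; 3'
#' segments appear as secondary/supplementary records and are ignored, since
#' the mate already provides that locus). Templates whose 5' segment is
#' unmapped on either side are kept with an `unmapped` sentinel so that QC
#' statistics can account for them.
#'
#' @param file Path to a name-sorted SAM or BAM file.
#' @param fragmap Optional [fragment_map()]; when supplied, fragment indices
#'   and inferred sequencing-fragment sizes are annotated.
#' @return A data.frame of class `"hic_pairs"`, one row per template, with
#'   columns `qname`, `chrom1`, `pos1` (0-based 5' position), `strand1`,
#'   `mapq1`, `dup1`, the same for anchor 2, `unmapped`, and (with `fragmap`)
#'   `frag1`, `frag2`, `size`, `orientation`, `gap`. Anchors are in canonical
#'   order (chromosome order, then position).
#' @export
load_hic_pairs <- function(file, fragmap = NULL) {
    bam <- file
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                                indexDestination = FALSE)
    }
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar")
    )
    rec <- Rsamtools::scanBam(bam, param = param)[[1]]
    n <- length(rec$qname)
    if (n == 0L) {
        return(empty_hic_pairs(fragmap))
    }
    flag <- rec$flag
    primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
    # name-sortedness check: each qname must occupy one contiguous block
    runs <- rle(rec$qname)
    if (anyDuplicated(runs$values)) {
        dup <- runs$values[duplicated(runs$values)][1]
        at <- which(runs$values == dup)
        stop(sprintf(
            "input is not name-sorted: template '%s' reappears after '%s'",
            dup, runs$values[at[2] - 1L]))
    }

    keep <- primary
    qname <- rec$qname[keep]
    flag <- flag[keep]
    chrom <- as.character(rec$rname)[keep]
    pos1based <- rec$pos[keep]
    mapq <- rec$mapq[keep]
    cigar <- rec$cigar[keep]
    unmapped <- bitwAnd(flag, 4L) != 0L
    reverse <- bitwAnd(flag, 16L) != 0L
    dup <- bitwAnd(flag, 1024L) != 0L
    first_in_pair <- bitwAnd(flag, 64L) != 0L

    # 5'-most genomic position of the aligned segment: leftmost base for
    # forward reads, rightmost aligned base for reverse reads
    pos5 <- rep(NA_integer_, length(flag))
    ok <- !unmapped & !is.na(cigar)
    width <- rep(NA_integer_, length(flag))
    width[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
    pos5[ok & !reverse] <- pos1based[ok & !reverse] - 1L
    pos5[ok & reverse] <- pos1based[ok & reverse] - 1L + width[ok & reverse] - 1L

    tmpl <- unique(qname)
    i1 <- match(tmpl, qname[first_in_pair])
    i2 <- match(tmpl, qname[!first_in_pair])
    idx1 <- which(first_in_pair)[i1]
    idx2 <- which(!first_in_pair)[i2]
    missing_side <- is.na(idx1) | is.na(idx2)

    grab <- function(v, idx) ifelse(is.na(idx), NA, v[idx])
    pr <- data.frame(
        qname = tmpl,
        chrom1 = grab(chrom, idx1), pos1 = as.integer(grab(pos5, idx1)),
        strand1 = ifelse(grab(reverse, idx1), "-", "+"),
        mapq1 = as.integer(grab(mapq, idx1)), dup1 = grab(dup, idx1) %in% TRUE,
        chrom2 = grab(chrom, idx2), pos2 = as.integer(grab(pos5, idx2)),
        strand2 = ifelse(grab(reverse, idx2), "-", "+"),
        mapq2 = as.integer(grab(mapq, idx2)), dup2 = grab(dup, idx2) %in% TRUE,
        stringsAsFactors = FALSE
    )
    pr$unmapped <- missing_side |
        grab(unmapped, idx1) %in% c(TRUE, NA) |
        grab(unmapped, idx2) %in% c(TRUE, NA) |
        is.na(pr$pos1) | is.na(pr$pos2)
    chrom_order <- if (!is.null(fragmap)) names(fragmap$seqlengths) else
        sort(unique(c(pr$chrom1, pr$chrom2)))
    pr <- canonicalize_pairs(pr, chrom_order)
    if (!is.null(fragmap)) {
        pr <- annotate_pairs(pr, fragmap)
    }
    class(pr) <- c("hic_pairs", "data.frame")
    pr
}

empty_hic_pairs <- function(fragmap = NULL) {
    pr <- data.frame(
        qname = character(0),
        chrom1 = character(0), pos1 = integer(0), strand1 = character(0),
        mapq1 = integer(0), dup1 = logical(0),
        chrom2 = character(0), pos2 = integer(0), strand2 = character(0),
        mapq2 = integer(0), dup2 = logical(0),
        unmapped = logical(0), stringsAsFactors = FALSE
    )
    if (!is.null(fragmap)) {
        pr$frag1 <- integer(0); pr$frag2 <- integer(0)
        pr$size <- numeric(0); pr$orientation <- character(0)
        pr$gap <- numeric(0)
    }
    class(pr) <- c("hic_pairs", "data.frame")
    pr
}

# Swap anchors so that (chrom1, pos1) <= (chrom2, pos2) in chromosome order.
canonicalize_pairs <- function(pr, chrom_order) {
    c1 <- match(pr$chrom1, chrom_order)
    c2 <- match(pr$chrom2, chrom_order)
    swap <- !pr$unmapped & (c2 < c1 | (c1 == c2 & pr$pos2 < pr$pos1))
    swap[is.na(swap)] <- FALSE
    if (any(swap)) {
        for (f in c("chrom", "pos", "strand", "mapq", "dup")) {
            a <- paste0(f, "1"); b <- paste0(f, "2")
            tmp <- pr[[a]][swap]
            pr[[a]][swap] <- pr[[b]][swap]
            pr[[b]][swap] <- tmp
        }
    }
    pr
}

# Adds fragment indices, orientation, gap and inferred fragment size.
annotate_pairs <- function(pr, fragmap) {
    n <- nrow(pr)
    pr$frag1 <- rep(NA_integer_, n); pr$frag2 <- rep(NA_integer_, n)
    pr$size <- rep(NA_real_, n); pr$orientation <- rep(NA_character_, n)
    pr$gap <- rep(NA_real_, n)
    ok <- !pr$unmapped
    if (any(ok)) {
        pr$frag1[ok] <- frag_index(fragmap, pr$chrom1[ok], pr$pos1[ok])
        pr$frag2[ok] <- frag_index(fragmap, pr$chrom2[ok], pr$pos2[ok])
        d1 <- cut_distance(fragmap, pr$chrom1[ok], pr$pos1[ok], pr$strand1[ok])
        d2 <- cut_distance(fragmap, pr$chrom2[ok], pr$pos2[ok], pr$strand2[ok])
        pr$size[ok] <- d1 + d2
        inter <- pr$chrom1[ok] != pr$chrom2[ok]
        s1 <- pr$strand1[ok]; s2 <- pr$strand2[ok]
        orient <- ifelse(inter, "inter",
                  ifelse(s1 == s2, "same-strand",
                  ifelse(s1 == "+", "inward", "outward")))
        pr$orientation[ok] <- orient
        pr$gap[ok] <- ifelse(inter, NA_real_, pr$pos2[ok] - pr$pos1[ok])
        if (any(!is.na(pr$gap) & pr$gap < 0)) {
            stop("internal error: negative gap after canonical ordering")
        }
    }
    pr
}

# 1-based fragment index within the chromosome for 0-based positions.
frag_index <- function(fragmap, chrom, pos0) {
    out <- integer(length(chrom))
    for (chr in unique(chrom)) {
        sel <- chrom == chr
        cuts <- fragmap$cuts[[chr]]
        if (is.null(cuts) && !chr %in% names(fragmap$seqlengths)) {
            stop(sprintf("chromosome '%s' not in FragmentMap", chr))
        }
        out[sel] <- findInterval(pos0[sel], c(0, cuts), rightmost.closed = FALSE)
    }
    out
}

# Distance from a read's 5' position to the nearest cut site in the read
# direction; falls back to the chromosome end when no cut lies that way.
cut_distance <- function(fragmap, chrom, pos0, strand) {
    out <- numeric(length(chrom))
    for (chr in unique(chrom)) {
        sel <- which(chrom == chr)
        cuts <- fragmap$cuts[[chr]]
        len <- fragmap$seqlengths[[chr]]
        fwd <- sel[strand[sel] == "+"]
        rev <- sel[strand[sel] == "-"]
        if (length(fwd)) {
            # first cut at or after the 5' position
            k <- findInterval(pos0[fwd] - 0.5, cuts) + 1L
            nxt <- ifelse(k <= length(cuts), cuts[pmin(k, length(cuts))], len)
            out[fwd] <- nxt - pos0[fwd]
        }
        if (length(rev)) {
            k <- findInterval(pos0[rev], cuts)   # last cut <= pos
            prv <- ifelse(k >= 1L, cuts[pmax(k, 1L)], 0)
            out[rev] <- pos0[rev] - prv
        }
    }
    out
}

#' Classify and filter Hi-C read pairs
#'
#' Applies the standard Hi-C QC cascade, in a fixed order so that removal
#' statistics are reproducible: (1) unmapped 5' segment or MAPQ below
#' `min_mapq` on either anchor; (2) duplicate flag; (3) inferred
#' sequencing-fragment size strictly above `max_frag` (non-specific
#' cleavage); (4) intra-chromosomal inward-facing pairs closer than
#' `min_inward` (dangling ends); (5) intra-chromosomal outward-facing pairs
#' closer than `min_outward` (self-circles). Inter-chromosomal and
#' same-strand pairs are exempt from the orientation filters. Gaps are
#' 5'-to-5' distances after canonical ordering.
#'
#' @param pairs An `"hic_pairs"` data.frame from [load_hic_pairs()] with
#'   fragment annotation.
#' @param min_mapq Minimum MAPQ (default 10).
#' @param max_frag Maximum inferred fragment size in bp (default 600).
#' @param min_inward Minimum gap for inward-facing pairs in bp (default 1000).
#' @param min_outward Minimum gap for outward-facing pairs in bp (default
#'   25000).
#' @return A list with `pairs` (retained rows) and `stats`, a named integer
#'   vector of class `"PairFilterStats"` whose removal causes partition the
#'   removed pairs (`retained + removed == input`).
#' @export
classify_and_filter <- function(pairs, min_mapq = 10, max_frag = 600,
                                min_inward = 1000, min_outward = 25000) {
    stopifnot(inherits(pairs, "hic_pairs"))
    if (any(c(min_mapq, max_frag, min_inward, min_outward) < 0)) {
        stop("thresholds must be non-negative")
    }
    if (!"size" %in% names(pairs)) {
        stop("pairs must carry fragment annotation (load with a FragmentMap)")
    }
    n <- nrow(pairs)
    cause <- rep("retained", n)
    low_q <- pairs$unmapped |
        is.na(pairs$mapq1) | is.na(pairs$mapq2) |
        pairs$mapq1 < min_mapq | pairs$mapq2 < min_mapq
    cause[low_q] <- "unmapped_or_low_mapq"
    free <- cause == "retained"
    is_dup <- free & (pairs$dup1 | pairs$dup2)
    cause[is_dup] <- "duplicate"
    free <- cause == "retained"
    oversized <- free & pairs$size > max_frag
    cause[oversized] <- "oversized_fragment"
    free <- cause == "retained"
    dangling <- free & pairs$orientation %in% "inward" & pairs$gap < min_inward
    cause[dangling] <- "dangling_end"
    free <- cause == "retained"
    selfcirc <- free & pairs$orientation %in% "outward" & pairs$gap < min_outward
    cause[selfcirc] <- "self_circle"

    causes <- c("unmapped_or_low_mapq", "duplicate", "oversized_fragment",
                "dangling_end", "self_circle")
    stats <- c(input = n, retained = sum(cause == "retained"),
               vapply(causes, function(cc) sum(cause == cc), integer(1)))
    class(stats) <- "PairFilterStats"
    kept <- pairs[cause == "retained", , drop = FALSE]
    class(kept) <- c("hic_pairs", "data.frame")
    list(pairs = kept, stats = stats)
}

#' @export
print.PairFilterStats <- function(x, ...) {
    cat("Hi-C pair filter statistics:\n")
    for (nm in names(x)) cat(sprintf("  %-22s %d\n", nm, x[[nm]]))
    invisible(x)
}

#' Save a pair store
#'
#' Persists processed pairs as a TSV table (one row per pair, grouped by
#' chromosome pair) plus a JSON QC report next to it.
#'
#' @param pairs An `"hic_pairs"` data.frame.
#' @param path Output TSV path.
#' @param stats Optional `"PairFilterStats"` written as `<path>.qc.json`.
#' @return `path`, invisibly.
#' @export
save_pair_store <- function(pairs, path, stats = NULL) {
    stopifnot(inherits(pairs, "hic_pairs"))
    ord <- order(pairs$chrom1, pairs$chrom2, pairs$pos1, pairs$pos2)
    utils::write.table(pairs[ord, , drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(stats)) {
        jsonlite::write_json(as.list(unclass(stats)), paste0(path, ".qc.json"),
                             auto_unbox = TRUE)
    }
    invisible(path)
}

#' Load a pair store
#' @param path TSV path written by [save_pair_store()].
#' @return An `"hic_pairs"` data.frame.
#' @export
load_pair_store <- function(path) {
    pr <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    class(pr) <- c("hic_pairs", "data.frame")
    pr
}

#' Pool pair stores (technical replicates)
#'
#' Technical replicates of one library are pooled by concatenating their
#' pair stores before counting.
#'
#' @param ... `"hic_pairs"` data.frames.
#' @return A single pooled `"hic_pairs"` data.frame.
#' @export
pool_pairs <- function(...) {
    parts <- list(...)
    stopifnot(all(vapply(parts, inherits, logical(1), "hic_pairs")))
    out <- do.call(rbind, lapply(parts, as.data.frame))
    class(out) <- c("hic_pairs", "data.frame")
    out
}
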