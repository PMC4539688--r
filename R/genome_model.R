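#' Restriction enzyme definition
#'
#' Describes a palindromic restriction enzyme by its recognition sequence and
#' the position of the top-strand cut. Hi-C protocols rely on enzymes that
#' leave a 5' overhang (or a blunt end) which is filled in before proximity
#' ligation, so only those are supported.
#'
#' @param recognition Uppercase recognition sequence (A/C/G/T). Must equal its
#'   own reverse complement.
#' @param cut_offset Integer offset `p` in nucleotides from the 5' end of the
#'   recognition site to the top-strand cut. The overhang length is
#'   `nchar(recognition) - 2 * cut_offset` and must be non-negative.
#'
#' @return An object of class `"Enzyme"` with elements `recognition`,
#'   `cut_offset` and `overhang`.
#' @examples
#' hindiii <- enzyme("AAGCTT", 1)
#' ligation_signature(hindiii)
#' @export
enzyme <- function(recognition, cut_offset) {
    recognition <- toupper(as.character(recognition))
    if (!grepl("^[ACGT]+$", recognition)) {
        stop("recognition sequence must be a non-empty string over A/C/G/T")
    }
    cut_offset <- as.integer(cut_offset)
    len <- nchar(recognition)
    if (is.na(cut_offset) || cut_offset < 0L || cut_offset > len) {
        stop("cut_offset must lie in [0, nchar(recognition)]")
    }
    overhang <- len - 2L * cut_offset
    if (overhang < 0L) {
        stop("unsupported enzyme: 3'-overhang cutters (negative overhang) are not handled")
    }
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition)))
    if (rc != recognition) {
        stop("recognition sequence must be palindromic (equal to its reverse complement)")
    }
    structure(
        list(recognition = recognition, cut_offset = cut_offset, overhang = overhang),
        class = "Enzyme"
    )
}

#' Parse an enzyme from a "SEQ:offset" string
#'
#' Convenience parser for configuration input, e.g. `"AAGCTT:1"` for HindIII.
#'
#' @param spec String of the form `"SEQ:offset"`.
#' @return An [enzyme()] object.
#' @export
parse_enzyme <- function(spec) {
    parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("enzyme spec must look like 'AAGCTT:1'")
    enzyme(parts[1], as.integer(parts[2]))
}

#' @export
print.Enzyme <- function(x, ...) {
    cat(sprintf("Enzyme: %s (cut at %d, %d nt 5' overhang)\n",
                x$recognition, x$cut_offset, x$overhang))
    cat(sprintf("Ligation signature: %s\n", ligation_signature(x)))
    invisible(x)
}

#' Ligation signature of an enzyme
#'
#' The sequence created at a Hi-C proximity-ligation junction. Both fragment
#' ends are filled in to blunt ends and ligated, so the junction carries the
#' 5' part of the site through the overhang, followed by the sequence from the
#' cut onwards: `recognition[1..p+L]` followed by `recognition[(p+1)..]`,
#' where `p` is the cut offset and `L` the overhang length. For HindIII
#' (AAGCTT, p = 1) this gives AAGCTAGCTT.
#'
#' @param enz An [enzyme()] object.
#' @return A character string of length `nchar(recognition) + overhang`;
#'   palindromic for palindromic sites.
#' @export
ligation_signature <- function(enz) {
    stopifnot(inherits(enz, "Enzyme"))
    p <- enz$cut_offset
    L <- enz$overhang
    rec <- enz$recognition
    paste0(substr(rec, 1L, p + L), substr(rec, p + 1L, nchar(rec)))
}

#' Digest a chromosome sequence in silico
#'
#' Finds every exact occurrence of the recognition sequence and records one
#' cut per occurrence at the centre of the site (the blunt-end position after
#' fill-in). Occurrences containing N are skipped; overlapping occurrences are
#' all counted.
#'
#' @param chrom_sequence A character string or [Biostrings::DNAString] over
#'   A/C/G/T/N.
#' @param enz An [enzyme()] object.
#' @return Integer vector of 0-based cut positions, strictly increasing.
#' @export
digest <- function(chrom_sequence, enz) {
    stopifnot(inherits(enz, "Enzyme"))
    subject <- if (inherits(chrom_sequence, "DNAString")) {
        chrom_sequence
    } else {
        Biostrings::DNAString(as.character(chrom_sequence))
    }
    # fixed matching: N in the subject never matches an A/C/G/T pattern,
    # which skips N-containing occurrences for free
    hits <- Biostrings::matchPattern(enz$recognition, subject, fixed = TRUE)
    starts0 <- BiocGenerics::start(hits) - 1L
    centre <- nchar(enz$recognition) %/% 2L
    sort(unique(starts0 + centre))
}

#' Restriction-fragment map of a genome
#'
#' Digests every chromosome of a genome and stores the cut positions and
#' chromosome lengths. Fragments are the half-open intervals between
#' consecutive cuts (plus the chromosome ends) and tile each chromosome
#' exactly.
#'
#' @param genome A named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param enz An [enzyme()] object.
#' @return An object of class `"FragmentMap"`: list with `cuts` (named list of
#'   0-based cut positions per chromosome), `seqlengths` (named integer
#'   vector) and `enzyme`.
#' @export
fragment_map <- function(genome, enz) {
    seqs <- load_genome(genome)
    cuts <- lapply(seq_along(seqs), function(i) {
        cc <- digest(seqs[[i]], enz)
        # boundary-touching cuts would create empty fragments; fold them into
        # the chromosome ends
        cc[cc > 0L & cc < length(seqs[[i]])]
    })
    names(cuts) <- names(seqs)
    structure(
        list(cuts = cuts,
             seqlengths = stats::setNames(lengths(seqs), names(seqs)),
             enzyme = enz),
        class = "FragmentMap"
    )
}

# Accepts FASTA path, named character vector or DNAStringSet.
load_genome <- function(genome) {
    if (inherits(genome, "DNAStringSet")) {
        seqs <- genome
    } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
        seqs <- Biostrings::readDNAStringSet(genome)
        names(seqs) <- sub("\\s.*$", "", names(seqs))
    } else if (is.character(genome)) {
        if (is.null(names(genome))) stop("genome sequences must be named by chromosome")
        seqs <- Biostrings::DNAStringSet(genome)
    } else {
        stop("unsupported genome input")
    }
    if (anyDuplicated(names(seqs))) stop("duplicate chromosome names in genome")
    seqs
}

#' @export
print.FragmentMap <- function(x, ...) {
    cat(sprintf("FragmentMap: %d chromosome(s), %d cut site(s) (%s)\n",
                length(x$seqlengths), sum(lengths(x$cuts)), x$enzyme$recognition))
    invisible(x)
}

#' Restriction fragments of a FragmentMap
#'
#' @param fragmap A [fragment_map()] object.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and `frag` (1-based fragment index within the chromosome).
#' @export
fragments <- function(fragmap) {
    stopifnot(inherits(fragmap, "FragmentMap"))
    out <- lapply(names(fragmap$seqlengths), function(chr) {
        bounds <- c(0L, fragmap$cuts[[chr]], fragmap$seqlengths[[chr]])
        data.frame(chrom = chr,
                   start = bounds[-length(bounds)],
                   end = bounds[-1],
                   frag = seq_len(length(bounds) - 1L))
    })
    do.call(rbind, out)
}

#' Genomic bins with boundaries rounded to restriction sites
#'
#' Partitions each chromosome into contiguous bins of a nominal width, with
#' every interior boundary moved to the nearest restriction cut site. This
#' reflects the spatial resolution limit of Hi-C: ligation always happens at
#' fragment ends, so bin edges between cut sites carry no information.
#' Equidistant cuts round to the larger coordinate; boundaries that collide
#' after rounding are deduplicated (the empty bin is dropped). A chromosome
#' without cut sites becomes a single bin.
#'
#' @param fragmap A [fragment_map()] object.
#' @param width Nominal bin width in bp (>= 1).
#' @return An object of class `"BinMap"`: `boundaries` (named list of 0-based
#'   boundary vectors including 0 and the chromosome length), `width`,
#'   `seqlengths`, and a `bins` data.frame (`chrom`, `start`, `end` 0-based
#'   half-open, `bin` global 1-based index).
#' @export
build_bins <- function(fragmap, width) {
    stopifnot(inherits(fragmap, "FragmentMap"))
    width <- as.numeric(width)
    if (is.na(width) || width < 1) stop("bin width must be >= 1 bp")
    boundaries <- lapply(names(fragmap$seqlengths), function(chr) {
        len <- fragmap$seqlengths[[chr]]
        cuts <- fragmap$cuts[[chr]]
        nominal <- if (width >= len) numeric(0) else
            seq(width, len - 1, by = width)
        nominal <- nominal[nominal < len]
        if (length(cuts) == 0L || length(nominal) == 0L) {
            return(c(0L, len))
        }
        rounded <- vapply(nominal, function(b) {
            d <- abs(cuts - b)
            cand <- cuts[d == min(d)]
            max(cand)          # tie broken towards the larger coordinate
        }, numeric(1))
        sort(unique(c(0L, rounded, len)))
    })
    names(boundaries) <- names(fragmap$seqlengths)
    bins <- do.call(rbind, lapply(names(boundaries), function(chr) {
        b <- boundaries[[chr]]
        data.frame(chrom = chr, start = b[-length(b)], end = b[-1])
    }))
    bins$bin <- seq_len(nrow(bins))
    structure(
        list(boundaries = boundaries, width = width,
             seqlengths = fragmap$seqlengths, bins = bins),
        class = "BinMap"
    )
}

#' @export
print.BinMap <- function(x, ...) {
    cat(sprintf("BinMap: %d bin(s) over %d chromosome(s), nominal width %g bp\n",
                nrow(x$bins), length(x$boundaries), x$width))
    invisible(x)
}

#' Number of bins in a BinMap
#' @param binmap A [build_bins()] object.
#' @return Integer bin count.
#' @export
n_bins <- function(binmap) {
    stopifnot(inherits(binmap, "BinMap"))
    nrow(binmap$bins)
}

# Global bin index of 0-based positions on a chromosome (half-open bins).
# Positions must lie in [0, seqlength).
bin_of <- function(binmap, chrom, pos0) {
    b <- binmap$boundaries[[chrom]]
    if (is.null(b)) stop(sprintf("chromosome '%s' not in BinMap", chrom))
    len <- binmap$seqlengths[[chrom]]
    bad <- pos0 < 0 | pos0 >= len
    if (any(bad)) {
        stop(sprintf("position %d outside chromosome '%s' (length %d)",
                     pos0[which(bad)[1]], chrom, len))
    }
    local_idx <- findInterval(pos0, b, rightmost.closed = FALSE)
    offset <- match(chrom, names(binmap$boundaries))
    first_global <- binmap$bins$bin[match(chrom, binmap$bins$chrom)]
    first_global + local_idx - 1L
}

#' Bins as a GRanges object
#'
#' User-facing coordinates are 1-based inclusive, as throughout Bioconductor.
#'
#' @param binmap A [build_bins()] object.
#' @return A [GenomicRanges::GRanges] with one range per bin and a `bin`
#'   metadata column.
#' @export
bins_to_granges <- function(binmap) {
    stopifnot(inherits(binmap, "BinMap"))
    b <- binmap$bins
    gr <- GenomicRanges::GRanges(
        seqnames = b$chrom,
        ranges = IRanges::IRanges(start = b$start + 1L, end = b$end),
        bin = b$bin
    )
    GenomeInfoDb::seqlengths(gr) <- binmap$seqlengths[GenomeInfoDb::seqlevels(gr)]
    gr
}

#' Export bins as a BED file
#'
#' @param binmap A [build_bins()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_bins_bed <- function(binmap, path) {
    gr <- bins_to_granges(binmap)
    names(gr) <- paste0("bin", gr$bin)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
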