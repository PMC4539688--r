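# Deterministic fixtures built in code at test time.

# Sequence of `len` bp with HindIII sites planted so that cuts fall exactly
# at `cut_positions` (site start = cut - 3). The ACGT-repeat filler cannot
# form an accidental AAGCTT.
planted_chrom <- function(len, cut_positions) {
    filler <- strrep("ACGT", ceiling(len / 4))
    s <- substr(filler, 1, len)
    for (cut in cut_positions) {
        substr(s, cut - 2, cut + 3) <- "AAGCTT"   # 1-based site start = cut - 2
    }
    s
}

# Random sequence with HindIII sites planted at the given cut positions;
# unique enough for exact-match mapping, unlike the periodic filler above.
planted_random_chrom <- function(len, cut_positions, seed) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    for (cut in cut_positions) {
        substr(s, cut - 2, cut + 3) <- "AAGCTT"
    }
    s
}

# Two-chromosome genome with known cut sites:
#   chrA (100 kb): cuts 1000, 10000, 30000, 60000
#   chrB (50 kb):  cuts 5000, 20000
test_genome <- function() {
    c(chrA = planted_chrom(100000, c(1000, 10000, 30000, 60000)),
      chrB = planted_chrom(50000, c(5000, 20000)))
}

test_fragmap <- function() fragment_map(test_genome(), enzyme("AAGCTT", 1))

# Hand-built name-sorted SAM of 12 templates exercising every removal cause.
# 0-based 5' positions chosen against the test_genome() cut sites:
#   t1  retained      intra inward, gap 20400, size 200+200
#   t2  retained      inter-chromosomal, size 150+100
#   t3  low MAPQ      (anchor2 MAPQ 5)
#   t4  unmapped      (anchor2 unmapped)
#   t5  duplicate     (t1 with duplicate flag)
#   t6  oversized     size 5000+100 > 600
#   t7  dangling end  inward, gap 500 < 1000, size 100+400
#   t8  self-circle   outward, gap 19800 < 25000, size 100+100
#   t9  retained      outward, gap 49800 >= 25000
#   t10 retained      same-strand (exempt from orientation filters)
#   t11 low MAPQ      (also duplicate-flagged: MAPQ removal takes precedence)
#   t12 unmapped      (3' segment mapped only as supplementary)
# Expected: input 12, retained 4, unmapped_or_low_mapq 4, duplicate 1,
# oversized_fragment 1, dangling_end 1, self_circle 1.
write_test_sam <- function(path = tempfile(fileext = ".sam")) {
    rec <- function(qname, flag, rname, pos, mapq, cigar = "50M") {
        paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, "*", "*",
              sep = "\t")
    }
    # forward read with 5' at X0 -> pos X0+1; reverse read (50M) -> pos X0-48
    lines <- c(
        "@HD\tVN:1.6\tSO:queryname",
        "@SQ\tSN:chrA\tLN:100000",
        "@SQ\tSN:chrB\tLN:50000",
        rec("t1", 65, "chrA", 9801, 30), rec("t1", 145, "chrA", 30152, 30),
        rec("t2", 65, "chrA", 9851, 30), rec("t2", 129, "chrB", 4901, 30),
        rec("t3", 65, "chrA", 9801, 30), rec("t3", 145, "chrA", 30152, 5),
        rec("t4", 73, "chrA", 9801, 30), rec("t4", 133, "*", 0, 0, "*"),
        rec("t5", 1089, "chrA", 9801, 30), rec("t5", 145, "chrA", 30152, 30),
        rec("t6", 65, "chrA", 5001, 30), rec("t6", 145, "chrA", 30052, 30),
        rec("t7", 65, "chrA", 9901, 30), rec("t7", 145, "chrA", 10352, 30),
        rec("t8", 81, "chrA", 10052, 30), rec("t8", 129, "chrA", 29901, 30),
        rec("t9", 81, "chrA", 10052, 30), rec("t9", 129, "chrA", 59901, 30),
        rec("t10", 65, "chrA", 9801, 30), rec("t10", 129, "chrA", 29901, 30),
        rec("t11", 1089, "chrA", 9801, 30), rec("t11", 145, "chrA", 30152, 5),
        rec("t12", 73, "chrA", 9801, 30), rec("t12", 133, "*", 0, 0, "*"),
        rec("t12", 2177, "chrB", 1001, 30)
    )
    writeLines(lines, path)
    path
}

# Minimal hand-made hic_pairs object (already canonical and annotated).
make_pairs <- function(chrom1, pos1, chrom2, pos2, strand1 = "+",
                       strand2 = "-") {
    n <- length(pos1)
    pr <- data.frame(
        qname = sprintf("p%d", seq_len(n)),
        chrom1 = rep_len(chrom1, n), pos1 = as.integer(pos1),
        strand1 = rep_len(strand1, n), mapq1 = rep(30L, n),
        dup1 = rep(FALSE, n),
        chrom2 = rep_len(chrom2, n), pos2 = as.integer(pos2),
        strand2 = rep_len(strand2, n), mapq2 = rep(30L, n),
        dup2 = rep(FALSE, n),
        unmapped = rep(FALSE, n), stringsAsFactors = FALSE
    )
    class(pr) <- c("hic_pairs", "data.frame")
    pr
}

# Small BinPairCounts built directly from anchors and counts.
make_counts <- function(anchor1, anchor2, counts, binmap = NULL,
                        totals = NULL) {
    if (is.null(binmap)) {
        binmap <- synthetic_binmap(c(chrA = max(anchor2, 4)), width = 1000)
    }
    bin_pair_counts(anchor1, anchor2, counts, binmap, totals)
}
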