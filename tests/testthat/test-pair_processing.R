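hindiii_sig <- "AAGCTAGCTT"

test_that("reads are split at the centre of the ligation signature", {
    # no signature: whole read is the 5' segment
    expect_identical(split_read_at_signature("ACGTACGT", hindiii_sig),
                     "ACGTACGT")
    # signature at 0-based 5..15, centre at 10
    out <- split_read_at_signature("TTTTTAAGCTAGCTTGGGGG", hindiii_sig)
    expect_identical(out, c("TTTTTAAGCT", "AGCTTGGGGG"))
    # two occurrences: split at the 5'-most
    r2 <- paste0("CC", hindiii_sig, "GG", hindiii_sig, "AA")
    out2 <- split_read_at_signature(r2, hindiii_sig)
    expect_identical(out2[1], "CCAAGCT")
    expect_identical(paste0(out2, collapse = ""), r2)
    expect_warning(out3 <- split_read_at_signature("", hindiii_sig), "empty")
    expect_length(out3, 0)
})

test_that("fragment sizes sum per-read distances to the next cut in the read direction", {
    fm <- test_fragmap()
    # + read at 9800 (next cut 10000 -> 200), - read at 30200 (prev cut 30000 -> 200)
    pr <- make_pairs("chrA", 9800, "chrA", 30200)
    ann <- hicdelta:::annotate_pairs(pr, fm)
    expect_equal(ann$size, 400)
    expect_equal(ann$orientation, "inward")
    expect_equal(ann$gap, 20400)
    # read starting exactly at a cut facing it: distance 0
    pr0 <- make_pairs("chrA", 10000, "chrA", 30000, strand1 = "+", strand2 = "-")
    ann0 <- hicdelta:::annotate_pairs(pr0, fm)
    expect_equal(ann0$size, 0)
    # no cut in the read direction: distance to the chromosome end
    pre <- make_pairs("chrA", 70000, "chrA", 80000, strand1 = "+", strand2 = "+")
    anne <- hicdelta:::annotate_pairs(pre, fm)
    expect_equal(anne$size, (100000 - 70000) + (100000 - 80000))
    # inter-chromosomal sizes are computed per chromosome
    pri <- make_pairs("chrA", 9900, "chrB", 4950, strand1 = "+", strand2 = "+")
    anni <- hicdelta:::annotate_pairs(pri, fm)
    expect_equal(anni$size, 100 + 50)
    expect_equal(anni$orientation, "inter")
    expect_true(is.na(anni$gap))
})

test_that("the 12-template SAM fixture yields the hand-enumerated filter statistics", {
    fm <- test_fragmap()
    pr <- load_hic_pairs(write_test_sam(), fm)
    expect_equal(nrow(pr), 12)
    res <- classify_and_filter(pr)
    expect_equal(unclass(res$stats),
                 c(input = 12L, retained = 4L, unmapped_or_low_mapq = 4L,
                   duplicate = 1L, oversized_fragment = 1L,
                   dangling_end = 1L, self_circle = 1L))
    expect_setequal(res$pairs$qname, c("t1", "t2", "t9", "t10"))
})

test_that("filter causes partition the input and filtering is idempotent", {
    fm <- test_fragmap()
    pr <- load_hic_pairs(write_test_sam(), fm)
    res <- classify_and_filter(pr)
    s <- res$stats
    expect_equal(s[["retained"]] + sum(s[c("unmapped_or_low_mapq", "duplicate",
                                           "oversized_fragment", "dangling_end",
                                           "self_circle")]),
                 s[["input"]])
    again <- classify_and_filter(res$pairs)
    expect_equal(again$stats[["retained"]], s[["retained"]])
    expect_equal(sum(again$stats) - again$stats[["input"]] -
                     again$stats[["retained"]], 0)
})

test_that("orientation thresholds are applied at the stated boundaries", {
    fm <- test_fragmap()
    # outward pairs anchored 100 bp from their cuts, at varying gaps
    mk <- function(pos1, pos2) {
        pr <- make_pairs("chrA", pos1, "chrA", pos2,
                         strand1 = "-", strand2 = "+")
        hicdelta:::annotate_pairs(pr, fm)
    }
    # gap 19800, size 100 + 100: strictness at the outward threshold
    pair <- mk(10100, 29900)
    below <- classify_and_filter(pair, min_outward = 19801)
    at <- classify_and_filter(pair, min_outward = 19800)
    expect_equal(below$stats[["self_circle"]], 1L)
    expect_equal(at$stats[["retained"]], 1L)
    # inward strictness likewise (gap 500, size 100 + 400)
    inw <- hicdelta:::annotate_pairs(
        make_pairs("chrA", 9900, "chrA", 10400), test_fragmap())
    expect_equal(classify_and_filter(inw, min_inward = 501)$stats[["dangling_end"]], 1L)
    expect_equal(classify_and_filter(inw, min_inward = 500)$stats[["retained"]], 1L)
    # fragment size exactly at the default cap is retained (strict >)
    atcap <- make_pairs("chrA", 9750, "chrA", 30350)  # 250 + 350 = 600
    atcap <- hicdelta:::annotate_pairs(atcap, fm)
    expect_equal(atcap$size, 600)
    expect_equal(classify_and_filter(atcap)$stats[["retained"]], 1L)
})

test_that("name-sorted loading keeps template order and flags unsorted input", {
    fm <- test_fragmap()
    pr <- load_hic_pairs(write_test_sam(), fm)
    expect_equal(pr$qname, paste0("t", 1:12))
    # anchors are canonical
    ok <- !pr$unmapped
    expect_true(all(pr$chrom1[ok] <= pr$chrom2[ok]))
    same <- ok & pr$chrom1 == pr$chrom2
    expect_true(all(pr$pos1[same] <= pr$pos2[same]))
    # unsorted: t1 reappears after t2
    bad <- tempfile(fileext = ".sam")
    lines <- readLines(write_test_sam())
    body <- lines[-(1:3)]
    writeLines(c(lines[1:3], body[c(1, 3, 2)]), bad)
    expect_error(load_hic_pairs(bad, fm), "not name-sorted")
})

test_that("empty input and pooling behave", {
    fm <- test_fragmap()
    empty <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:queryname", "@SQ\tSN:chrA\tLN:100000"), empty)
    pr <- load_hic_pairs(empty, fm)
    expect_equal(nrow(pr), 0)
    st <- classify_and_filter(hicdelta:::annotate_pairs(pr, fm))$stats
    expect_equal(st[["input"]], 0L)
    a <- make_pairs("chrA", c(100, 200), "chrA", c(5000, 6000))
    b <- make_pairs("chrB", 300, "chrB", 9000)
    pooled <- pool_pairs(a, b)
    expect_equal(nrow(pooled), 3)
    expect_s3_class(pooled, "hic_pairs")
})

test_that("pair stores round-trip through TSV with a QC report", {
    fm <- test_fragmap()
    pr <- load_hic_pairs(write_test_sam(), fm)
    res <- classify_and_filter(pr)
    path <- tempfile(fileext = ".tsv")
    save_pair_store(res$pairs, path, stats = res$stats)
    back <- load_pair_store(path)
    expect_equal(nrow(back), nrow(res$pairs))
    expect_setequal(back$qname, res$pairs$qname)
    qc <- jsonlite::read_json(paste0(path, ".qc.json"))
    expect_equal(qc$retained, 4)
})

test_that("pre-splitting chimeric reads recovers more true 5' loci than naive exact mapping", {
    enz <- enzyme("AAGCTT", 1)
    genome <- c(
        chrA = planted_random_chrom(40000, c(5000, 15000, 25000, 35000), seed = 11),
        chrB = planted_random_chrom(40000, c(8000, 18000, 28000), seed = 13))
    sim <- simulate_chimeric_reads(genome, enz, n_reads = 150,
                                   read_length = 60, seed = 12)
    sig <- ligation_signature(enz)
    subj <- Biostrings::DNAStringSet(genome)

    # exact-match "aligner": unique hit of the query anywhere in the genome
    locate <- function(query) {
        if (nchar(query) < 15) return(NULL)    # too short to be unique
        hits <- lapply(seq_along(subj), function(i) {
            BiocGenerics::start(Biostrings::matchPattern(query, subj[[i]])) - 1L
        })
        tot <- sum(lengths(hits))
        if (tot != 1) return(NULL)
        chr <- which(lengths(hits) == 1)
        list(chrom = names(subj)[chr], pos = hits[[chr]][1])
    }
    correct <- function(query, truth_chrom, truth_pos) {
        loc <- locate(query)
        !is.null(loc) && loc$chrom == truth_chrom && loc$pos == truth_pos
    }
    n_pre <- n_naive <- 0
    for (k in seq_along(sim$reads)) {
        read <- sim$reads[k]
        five <- split_read_at_signature(read, sig)[1]
        if (correct(five, sim$truth$chrom5[k], sim$truth$pos5[k])) {
            n_pre <- n_pre + 1
        }
        if (correct(read, sim$truth$chrom5[k], sim$truth$pos5[k])) {
            n_naive <- n_naive + 1
        }
    }
    expect_gt(n_pre, 0)
    expect_gte(n_pre, n_naive)
})
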