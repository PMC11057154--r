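test_that("spliced 5'UTRs are extracted from GTF + FASTA on both strands", {
    d <- withr::local_tempdir()
    # plus-strand 2-exon gene: UTR blocks [0,4)+[10,14) 0-based half-open,
    # CDS continues in the second exon; minus-strand gene on its own contig
    contigs <- list(
        chr_t = "ACGTNNNNNNTTAGATGAAATGAGGG",
        chr_m = paste0(strrep("G", 20), "CATTTTCATTCTTTTTTTTTT"))
    # chr_m minus gene: UTR exon genomic [20,26) reads CATTTT -> revcomp AAAATG
    # CDS upstream of it in genomic space: [5,20) placeholder with stop/start
    gtfLines <- c(
        gtfLine("chr_t", "exon", 1, 4, "+", "gPlus", "tPlus"),
        gtfLine("chr_t", "exon", 11, 26, "+", "gPlus", "tPlus"),
        gtfLine("chr_t", "CDS", 15, 23, "+", "gPlus", "tPlus"),
        gtfLine("chr_m", "exon", 6, 26, "-", "gMinus", "tMinus"),
        gtfLine("chr_m", "CDS", 6, 20, "-", "gMinus", "tMinus"))
    fx <- writeToyGenome(d, contigs, gtfLines)
    models <- loadTranscripts(fx$gtf, fx$fa)

    mp <- models[["gPlus"]]
    expect_identical(utr5Seq(mp), "ACGTTTAG")
    expect_identical(utr5IntronCount(mp), 1L)
    expect_identical(cdsSeq(mp), "ATGAAATGA")
    expect_true(mp@canonicalStart)
    expect_identical(mrnaLength(mp), 20L)

    mm <- models[["gMinus"]]
    expect_identical(utr5Seq(mm), "AAAATG")
    expect_identical(mm@strand, "-")
})

test_that("transcripts with empty 5'UTRs are excluded and counted", {
    d <- withr::local_tempdir()
    contigs <- list(chr_t = "ATGAAATGAGGGTTT")
    gtfLines <- c(
        gtfLine("chr_t", "exon", 1, 12, "+", "gNoUtr", "tNoUtr"),
        gtfLine("chr_t", "CDS", 1, 9, "+", "gNoUtr", "tNoUtr"))
    fx <- writeToyGenome(d, contigs, gtfLines)
    models <- loadTranscripts(fx$gtf, fx$fa)
    expect_length(models, 0L)
    md <- S4Vectors::metadata(models)
    expect_identical(md$excludedEmptyUTR, 1L)
    expect_identical(md$transcriptsSeen,
                     md$excludedEmptyUTR + md$skippedNoCDS + length(models))
})

test_that("a transcript without CDS is skipped with a warning, bad exon is fatal", {
    d <- withr::local_tempdir()
    contigs <- list(chr_t = "ACGTACGTACGTACGT")
    fx <- writeToyGenome(d, contigs, c(
        gtfLine("chr_t", "exon", 1, 8, "+", "gA", "tA")))
    expect_warning(models <- loadTranscripts(fx$gtf, fx$fa), "no CDS")
    expect_identical(S4Vectors::metadata(models)$skippedNoCDS, 1L)

    fx2 <- writeToyGenome(d, contigs, c(
        gtfLine("chr_t", "exon", 1, 40, "+", "gB", "tB"),
        gtfLine("chr_t", "CDS", 30, 38, "+", "gB", "tB")))
    expect_error(loadTranscripts(fx2$gtf, fx2$fa), "tB")
})

test_that("coordinate mapping matches exon arithmetic and round-trips", {
    m <- toyModel()   # plus strand, UTR blocks [0,4)+[10,14) 0-based
    expect_identical(genomicToTranscript(m, 10L), 4L)
    expect_identical(genomicToTranscript(m, 5L), NA_integer_)
    expect_identical(genomicToTranscript(m, 0L), 0L)

    mm <- TranscriptModel("gM", "tM", "chr_m", "-",
                          IRanges::IRanges(21, 26),
                          utr5Seq = "AAAATG", cdsSeq = "ATGTAA")
    expect_identical(genomicToTranscript(mm, 25L), 0L)
    expect_identical(transcriptToGenomic(mm, 0L), 25L)

    # round trip over every UTR base, both strands, random exon structures
    set.seed(11)
    for (rep in 1:20) {
        nEx <- sample(1:3, 1)
        w <- sample(3:9, nEx, replace = TRUE)
        gaps <- sample(5:20, nEx, replace = TRUE)
        starts <- cumsum(gaps + c(0, w[-nEx]))
        ex <- IRanges::IRanges(starts, width = w)
        std <- sample(c("+", "-"), 1)
        if (std == "-") ex <- rev(ex)
        L <- sum(w)
        m <- TranscriptModel("g", "t", "c", std, ex,
                             utr5Seq = randSeq(L), cdsSeq = "ATGTAA")
        offs <- 0:(L - 1L)
        g <- transcriptToGenomic(m, offs)
        expect_false(anyNA(g))
        expect_identical(genomicToTranscript(m, g), offs)
        # strict monotonicity along transcript order
        expect_true(all(diff(g) != 0L))
        expect_identical(genomicToTranscript(m, max(g) + 1000L), NA_integer_)
    }
})

test_that("splice consistency: exon pieces concatenate to the spliced UTR", {
    set.seed(12)
    for (rep in 1:10) {
        d <- withr::local_tempdir()
        w <- sample(4:10, 2)
        intron <- sample(5:15, 1)
        utrSeq <- randSeq(sum(w))
        g1 <- substr(utrSeq, 1, w[1])
        g2 <- substring(utrSeq, w[1] + 1)
        contig <- paste0(g1, randSeq(intron), g2, "ATGCCCTAA")
        gtfLines <- c(
            gtfLine("c1", "exon", 1, w[1], "+", "g", "t"),
            gtfLine("c1", "exon", w[1] + intron + 1, nchar(contig), "+", "g", "t"),
            gtfLine("c1", "CDS", w[1] + intron + w[2] + 1, nchar(contig), "+",
                    "g", "t"))
        fx <- writeToyGenome(d, list(c1 = contig), gtfLines)
        m <- loadTranscripts(fx$gtf, fx$fa)[[1]]
        expect_identical(utr5Seq(m), utrSeq)
        expect_identical(utr5IntronCount(m), 1L)
    }
})

test_that("gene metadata merges with higher-LOEUF duplicate resolution", {
    d <- withr::local_tempdir()
    lf <- file.path(d, "loeuf.tsv")
    writeLines(c("gene_id\tloeuf",
                 "G1\t0.3", "G1\t0.5",
                 paste0("G", 2:10, "\t", seq(0.6, 2.2, by = 0.2))), lf)
    cg <- file.path(d, "cage.tsv")
    writeLines(c("gene_id\tcage_peaks", "G1\t4", "G2\t1"), cg)
    meta <- loadGeneMeta(lf, cagePath = cg)
    expect_equal(meta$loeuf[meta$gene_id == "G1"], 0.5)
    # 10 genes with distinct retained scores: decile of rank-k gene is k
    expect_identical(meta$loeuf_decile[order(meta$loeuf)], 1:10)
    expect_identical(meta$cage_peaks[meta$gene_id == "G3"], NA_integer_)
    expect_true(is.na(meta$mean_tpm[1]))
})

test_that("unparseable numeric metadata reports the offending line", {
    d <- withr::local_tempdir()
    lf <- file.path(d, "loeuf.tsv")
    writeLines(c("gene_id\tloeuf", "G1\t0.3", "G2\tnot_a_number"), lf)
    expect_error(loadGeneMeta(lf), "line 3")
})

test_that("rank binning is deterministic under ties with near-equal bins", {
    x <- c(0.1, 0.2, 0.2, 0.3, NA, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
    ids <- paste0("g", seq_along(x))
    b1 <- rankBins(x, ids, nBins = 10L)
    b2 <- rankBins(x, ids, nBins = 10L)
    expect_identical(b1, b2)
    expect_true(is.na(b1[5]))
    tab <- table(b1)
    expect_lte(diff(range(tab)), 1L)
    # 20 genes, distinct values: deciles of size 2, quintile groups of 4
    b <- rankBins(seq_len(20), nBins = 10L)
    expect_true(all(table(b) == 2L))
    expect_identical(sum(b <= 2L), 4L)
})

test_that("evidence loading filters to uORFs and tallies start codons", {
    d <- withr::local_tempdir()
    ev <- file.path(d, "ev.tsv")
    writeLines(c("gene_id\tstart\tend\ttype\tstart_codon",
                 "G1\t4\t13\tuORF\tATG",
                 "G1\t20\t35\tuORF\tCTG",
                 "G2\t5\t20\tdORF\tATG"), ev)
    x <- loadEvidenceUORFs(ev)
    expect_identical(nrow(x), 2L)
    expect_identical(attr(x, "nCanonical"), 1L)
    expect_identical(attr(x, "nNonCanonical"), 1L)
    expect_equal(attr(x, "nCanonical") / nrow(x), 0.5)

    bad <- file.path(d, "bad.tsv")
    writeLines(c("gene_id\tstart\tend\ttype\tstart_codon",
                 "G1\t13\t4\tuORF\tATG"), bad)
    expect_error(loadEvidenceUORFs(bad), "end <= start")
})

test_that("score tracks read from bedGraph and TSV agree", {
    d <- withr::local_tempdir()
    bg <- file.path(d, "t.bedGraph")
    writeLines(c("c1\t0\t3\t1.5", "c1\t7\t8\t-2"), bg)
    tr <- readScoreTrack(bg)
    expect_identical(tr@pos, c(0:2, 7L))
    expect_equal(tr@score, c(1.5, 1.5, 1.5, -2))

    tsv <- file.path(d, "t.tsv")
    writeLines(c("contig\tpos\tscore", "c1\t0\t1.5", "c1\t1\t1.5",
                 "c1\t2\t1.5", "c1\t7\t-2"), tsv)
    tr2 <- readScoreTrack(tsv)
    expect_equal(tr2@score, tr@score)
    expect_identical(tr2@pos, tr@pos)
})
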