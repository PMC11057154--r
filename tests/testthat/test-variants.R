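test_that("applying variants edits the 5'UTR with a faithful coordinate map", {
    r <- applyUTRVariant("CCTTGCCC", 2L, "T", "A")
    expect_identical(r$seq, "CCATGCCC")
    expect_identical(r$map, 0:7)

    d <- applyUTRVariant("CCTTGCCC", 3L, "TG", "")
    expect_identical(d$seq, "CCTCCC")
    expect_identical(d$map, c(0L, 1L, 2L, NA, NA, 3L, 4L, 5L))

    ins <- applyUTRVariant("CCTTGCCC", 3L, "", "AA")
    expect_identical(ins$seq, "CCTAATGCCC")
    expect_identical(ins$map, c(0L, 1L, 2L, 5L, 6L, 7L, 8L, 9L))

    expect_error(applyUTRVariant("CCTTGCCC", 2L, "G", "A"), "mismatch")
    expect_error(applyUTRVariant("CCTTGCCC", 6L, "CCC", ""), "spans beyond")
})

test_that("effect classification covers the canonical cases", {
    classify <- function(utr, off, ref, alt, cds = "ATGCCC") {
        ap <- applyUTRVariant(utr, off, ref, alt)
        classifyVariantEffect(scanUpstreamAUGs(utr, cds),
                              scanUpstreamAUGs(ap$seq, cds), ap$map)
    }
    g <- classify("CCTTGCCC", 2L, "T", "A")      # creates an ATG
    expect_identical(g$effects, "uAUG_gained")
    expect_identical(g$resulting_klass,
                     scanUpstreamAUGs("CCATGCCC")$klass)

    l <- classify("CCATGCCC", 2L, "A", "T")      # destroys the ATG
    expect_identical(l$effects, "uAUG_lost")

    s <- classify("ATGAAATAGCC", 6L, "T", "C")   # stop TAG -> CAG
    expect_identical(s$effects, "uSTOP_lost")
    expect_true(s$resulting_klass %in% c("oORF_out_of_frame", "NTE"))

    # out-of-frame oORF stays put; classification is frame arithmetic
    expect_identical(scanUpstreamAUGs("CATGAACCCACC")$klass,
                     "oORF_out_of_frame")

    # body-neutral change: neither start, stop, nor Kozak affected
    n <- classify("ATGAAATAGCC", 4L, "A", "C")
    expect_identical(n$effects, "none")
})

test_that("a uSTOP-gained transition is detected when an oORF gains a stop", {
    utr <- "CCCATGCACCAC"      # ATG offset 3, in-frame codons CAC CAC: oORF
    expect_identical(scanUpstreamAUGs(utr)$klass, "NTE")
    ap <- applyUTRVariant(utr, 6L, "CAC", "TAA")
    cls <- classifyVariantEffect(scanUpstreamAUGs(utr),
                                 scanUpstreamAUGs(ap$seq), ap$map)
    expect_true("uSTOP_gained" %in% cls$effects)
    expect_identical(cls$resulting_klass, "start_stop")
})

test_that("indels that merely shift a uAUG are not reported as lost+gained", {
    utr <- "CCCCATGAAATAGCC"
    ap <- applyUTRVariant(utr, 1L, "", "G")      # insertion upstream
    cls <- classifyVariantEffect(scanUpstreamAUGs(utr),
                                 scanUpstreamAUGs(ap$seq), ap$map)
    expect_identical(cls$effects, "none")
    ap2 <- applyUTRVariant(utr, 0L, "C", "")     # deletion upstream
    cls2 <- classifyVariantEffect(scanUpstreamAUGs(utr),
                                  scanUpstreamAUGs(ap2$seq), ap2$map)
    expect_identical(cls2$effects, "none")
})

test_that("classification agrees with the naive rescan oracle and reverses", {
    set.seed(201)
    nAgree <- 0L
    for (i in 1:300) {
        L <- sample(12:60, 1)
        utr <- randSeq(L)
        kind <- sample(c("snv", "del", "ins"), 1)
        if (kind == "snv") {
            off <- sample(L, 1) - 1L
            ref <- substr(utr, off + 1L, off + 1L)
            alt <- sample(setdiff(NTS, ref), 1)
        } else if (kind == "del") {
            k <- sample(1:3, 1)
            off <- sample(L - k, 1) - 1L
            ref <- substr(utr, off + 1L, off + k)
            alt <- ""
        } else {
            k <- sample(1:3, 1)
            off <- sample(L, 1) - 1L
            ref <- ""
            alt <- randSeq(k)
        }
        ap <- applyUTRVariant(utr, off, ref, alt)
        got <- classifyVariantEffect(scanUpstreamAUGs(utr),
                                     scanUpstreamAUGs(ap$seq), ap$map)
        expect_identical(sort(got$effects),
                         oracleVariantEffects(utr, off, ref, alt))
        nAgree <- nAgree + 1L

        # reversibility: applying the inverse restores the classification
        back <- applyUTRVariant(ap$seq, off, alt, ref)
        expect_identical(back$seq, utr)
        e0 <- scanUpstreamAUGs(utr)
        e2 <- scanUpstreamAUGs(back$seq)
        expect_identical(e0$utr_offset, e2$utr_offset)
        expect_identical(e0$klass, e2$klass)
    }
    expect_identical(nAgree, 300L)
})

test_that("every uAUG_gained effect's created element is findable by rescan", {
    set.seed(202)
    for (i in 1:100) {
        utr <- randSeq(40)
        off <- sample(40, 1) - 1L
        ref <- substr(utr, off + 1L, off + 1L)
        alt <- sample(setdiff(NTS, ref), 1)
        ap <- applyUTRVariant(utr, off, ref, alt)
        altEl <- scanUpstreamAUGs(ap$seq)
        cls <- classifyVariantEffect(scanUpstreamAUGs(utr), altEl, ap$map)
        if ("uAUG_gained" %in% cls$effects) {
            expect_true(length(cls$created) >= 1L)
            expect_true(all(altEl$utr_offset[cls$created] %in%
                            altEl$utr_offset))
            expect_identical(cls$resulting_klass,
                             altEl$klass[cls$created[1]])
        }
    }
})

test_that("saturation enumerates the full small-variant set deterministically", {
    m <- TranscriptModel("g", "t", "c", "+", IRanges::IRanges(1, 12),
                         utr5Seq = "CCTTGCCCAGGT", cdsSeq = "ATGCCCTAA")
    sat <- saturateVariants(m, maxIndel = 3L)
    L <- 12L
    expect_identical(sum(sat$type == "SNV"), 3L * L)
    # deletions at position p have exactly min(3, L - p) lengths
    for (p in c(0L, L - 2L, L - 1L)) {
        expect_identical(sum(sat$type == "del" & sat$utr_offset == p),
                         min(3L, L - p))
    }
    # insertions enumerate all 4^k sequences for k <= 3
    expect_identical(sum(sat$type == "ins" & sat$utr_offset == 0L),
                     4L + 16L + 64L)
    # deterministic order: position, then type, then allele
    sat2 <- saturateVariants(m, maxIndel = 3L)
    expect_identical(sat, sat2)

    # no ATG can arise from any SNV of a C-homopolymer
    mC <- TranscriptModel("g2", "t2", "c", "+", IRanges::IRanges(1, 4),
                          utr5Seq = "CCCC", cdsSeq = "ATGCCCTAA")
    satC <- saturateVariants(mC)
    expect_true(all(satC$effects[satC$type == "SNV"] == "none"))
})

test_that("genomic-space application handles strands and boundary rejection", {
    # plus strand toy gene with UTR [0,8) on its contig
    m <- TranscriptModel("g", "t", "c", "+", IRanges::IRanges(1, 8),
                         utr5Seq = "CCTTGCCC", cdsSeq = "ATGCCCTAA")
    ap <- applyVariant(m, pos = 3L, ref = "T", alt = "A")
    expect_identical(ap$seq, "CCATGCCC")
    expect_error(applyVariant(m, pos = 20L, ref = "A", alt = "C"),
                 "does not fall")

    # minus strand: genomic C at the mapped position is a transcript G
    mm <- TranscriptModel("gm", "tm", "c", "-", IRanges::IRanges(11, 18),
                          utr5Seq = "CCTTGCCC", cdsSeq = "ATGCCCTAA")
    # transcript offset 2 ('T') sits at genomic 0-based 15, genomic base 'A'
    expect_identical(transcriptToGenomic(mm, 2L), 15L)
    ap2 <- applyVariant(mm, pos = 16L, ref = "A", alt = "T")
    expect_identical(ap2$seq, "CCATGCCC")
    expect_error(applyVariant(mm, pos = 16L, ref = "AT", alt = "A"),
                 "minus-strand")
})

test_that("VCF round trip preserves variants and annotation labels", {
    d <- withr::local_tempdir()
    v <- data.frame(gene_id = c("g1", "g2"), contig = c("c1", "c2"),
                    pos = c(5L, 9L), ref = c("T", "G"), alt = c("A", "C"),
                    stringsAsFactors = FALSE)
    p <- file.path(d, "v.vcf")
    writeVariantVCF(v, p)
    back <- readVariants(p)
    expect_identical(back$contig, v$contig)
    expect_identical(back$pos, v$pos)
    expect_identical(back$ref, v$ref)
    expect_identical(back$alt, v$alt)
    expect_identical(back$gene_id, v$gene_id)
})
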