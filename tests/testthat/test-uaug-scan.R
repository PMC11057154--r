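test_that("uAUG classification matches the hand-derived cases", {
    # start-stop: AUG immediately followed by a stop
    e <- scanUpstreamAUGs("ATGTAACC", "ATGCCC")
    expect_identical(e$klass, "start_stop")
    expect_identical(e$length_bp, 6L)
    expect_identical(e$stop_offset, 6L)

    # uORF with one body codon: ATG-AAA-TAG, 1 nt re-initiation gap
    e <- scanUpstreamAUGs("ATGAAATAGC", "ATGCCC")
    expect_identical(e$klass, "uORF")
    expect_identical(e$stop_offset, 9L)
    expect_identical(e$length_bp, 9L)
    expect_identical(e$distance_to_cds, 1L)

    # frame arithmetic decides oORF subclass
    expect_identical(scanUpstreamAUGs("CATGAAAC")$klass, "oORF_out_of_frame")
    expect_identical(scanUpstreamAUGs("CCATGAAC")$klass, "NTE")

    # several uAUGs in frame to one stop are all emitted; the one abutting
    # the stop is a start-stop, never counted as a uORF
    e <- scanUpstreamAUGs("ATGATGATGTAAC", "ATGCCC")
    expect_identical(e$klass, c("uORF", "uORF", "start_stop"))
    expect_true(all(e$stop_offset == 12L))
    expect_identical(e$length_bp, c(12L, 9L, 6L))
})

test_that("codons containing N never act as stops and empty UTRs scan empty", {
    e <- scanUpstreamAUGs("ATGTNACCCTAAC")     # TNA is not a stop
    expect_identical(e$klass, "uORF")
    expect_identical(e$stop_offset, 12L)
    expect_identical(nrow(scanUpstreamAUGs("")), 0L)
    expect_identical(nrow(scanUpstreamAUGs("CCCCCC")), 0L)
})

test_that("classification agrees with the brute-force oracle on random UTRs", {
    set.seed(101)
    for (i in 1:400) {
        utr <- randSeq(sample(3:60, 1))
        got <- scanUpstreamAUGs(utr)
        want <- oracleScan(utr)
        expect_identical(got$utr_offset, want$utr_offset)
        expect_identical(got$klass, want$klass)
        expect_identical(got$length_bp, want$length_bp)
    }
})

test_that("element classes partition ATG occurrences on long random UTRs", {
    set.seed(102)
    for (i in 1:300) {
        utr <- randSeq(300)
        e <- scanUpstreamAUGs(utr)
        nATG <- length(gregexpr("ATG", utr, fixed = TRUE)[[1]])
        if (gregexpr("ATG", utr, fixed = TRUE)[[1]][1] == -1L) nATG <- 0L
        expect_identical(nrow(e), nATG)
        expect_true(all(e$klass %in%
            c("uORF", "oORF_out_of_frame", "NTE", "start_stop")))
        # start-stop iff length 6; uORF lengths are multiples of 3, >= 6
        orf <- e$klass %in% c("uORF", "start_stop")
        expect_true(all(e$length_bp[orf] %% 3L == 0L))
        expect_true(all(e$length_bp[orf] >= 6L))
        expect_identical(e$klass == "start_stop",
                         !is.na(e$length_bp) & e$length_bp == 6L)
    }
})

test_that("appending 3' sequence after stops and prepending shift as expected", {
    set.seed(103)
    for (i in 1:50) {
        utr <- randSeq(60)
        e0 <- scanUpstreamAUGs(utr)
        orf <- e0[e0$klass %in% c("uORF", "start_stop"), , drop = FALSE]
        if (!nrow(orf)) next
        # appending beyond all stops never reclassifies existing uORFs
        ext <- paste0(utr, strrep("CCC", 4))
        e1 <- scanUpstreamAUGs(ext)
        for (r in seq_len(nrow(orf))) {
            j <- which(e1$utr_offset == orf$utr_offset[r])
            expect_identical(e1$klass[j], orf$klass[r])
            expect_identical(e1$length_bp[j], orf$length_bp[r])
        }
        # prepending shifts every offset by the prepended length
        pre <- paste0("CC", utr)
        e2 <- scanUpstreamAUGs(pre)
        expect_identical(e2$utr_offset, e0$utr_offset + 2L)
    }
})

test_that("Kozak strength follows the -3/+4 rule with missing -3 non-matching", {
    expect_identical(kozakStrength("AAAATGG", 3L), "strong")
    expect_identical(kozakStrength("TTTATGG", 3L), "moderate")
    expect_identical(kozakStrength("AAAATGC", 3L), "moderate")
    expect_identical(kozakStrength("TTTATGC", 3L), "weak")
    # offset < 3: -3 unavailable counts as non-matching
    expect_identical(kozakStrength("CATGC", 1L), "weak")
    expect_identical(kozakStrength("CATGG", 1L), "moderate")
    # +4 drawn from the CDS at the UTR/CDS junction
    expect_identical(kozakStrength("AAAATG", 3L, cdsSeq = "GGG"), "strong")
    # vectorised
    expect_identical(kozakStrength("AAAATGGCATGC", c(3L, 8L)),
                     c("strong", "moderate"))
})

test_that("TE lookup excludes too-close contexts separately from unmatched", {
    te <- c("AAAAAAATGGA" = 120)
    # context assembled as 6 upstream + ATG + 2 downstream
    full <- "CAAAAAAATGGAC"
    r <- lookupTE(full, "ATGCCC", 7L, te)
    expect_equal(r$te, 120)
    expect_identical(r$status, "ok")
    r2 <- lookupTE("CCATGAAAAA", "ATGCCC", 2L, te)
    expect_identical(r2$status, "too_close")
    r3 <- lookupTE("TTTTTTTATGCCCCC", "ATGCCC", 7L, te)
    expect_identical(r3$status, "unmatched")
    # downstream bases may come from the CDS
    r4 <- lookupTE("AAAAAAATG", "GACCC", 6L, te)
    expect_equal(r4$te, 120)
})

test_that("codon optimality is the optimal fraction over sense codons", {
    tab <- c(AAA = 1L, CCC = 0L)
    expect_equal(codonOptimality(strrep("AAA", 4), c(AAA = 1L)), 1.0)
    expect_equal(codonOptimality("AAACCCAAATAA", tab), 2 / 3)
    expect_true(is.na(codonOptimality("ATGTAA",
                                      c(ATG = 1L))))   # start-stop: no body
    expect_error(codonOptimality("AAAA", tab), "divisible")
})

test_that("evidence matching is by strict coordinate equality and idempotent", {
    e <- scanUpstreamAUGs("CCCCATGAAATAGCC", "ATGCCC")  # uORF [4,13)
    ev <- data.frame(gene_id = "g", start = c(4L, 20L), end = c(13L, 35L),
                     type = "uORF", start_codon = c("ATG", "CTG"),
                     canonical = c(TRUE, FALSE))
    m1 <- matchEvidence(e, ev)
    expect_true(m1$evidence_matched[1])
    expect_equal(attr(m1, "matchedFraction"), 1.0)
    expect_identical(attr(m1, "nNonCanonical"), 1L)
    # off-by-three stop never matches under strict equality
    ev2 <- data.frame(gene_id = "g", start = 4L, end = 10L,
                      type = "uORF", start_codon = "ATG", canonical = TRUE)
    m2 <- matchEvidence(e, ev2)
    expect_false(any(m2$evidence_matched))
    expect_true(any(matchEvidence(e, ev2, by = "start")$evidence_matched))
    # idempotent
    m3 <- matchEvidence(m1, ev)
    expect_identical(m3$evidence_matched, m1$evidence_matched)
})

test_that("the per-gene feature vector obeys its contracts", {
    m <- TranscriptModel("g1", "t1", "c", "+", IRanges::IRanges(1, 10),
                         utr5Seq = "ATGAAATAGC", cdsSeq = "ATGCCCTAA",
                         mrnaLength = 40L)
    f <- buildFeatures(m)
    expect_identical(f$n_uaug, 1L)
    expect_equal(f$uaug_per_bp, 0.1)
    expect_identical(f$closest_stop_distance, 1L)
    expect_equal(f$utr_mrna_fraction, 0.25)
    expect_identical(f$n_uaug, f$n_uorf + f$n_oorf + f$n_start_stop)

    m0 <- TranscriptModel("g2", "t2", "c", "+", IRanges::IRanges(1, 8),
                          utr5Seq = "CCCCCCCC", cdsSeq = "ATGTAA",
                          mrnaLength = 50L)
    f0 <- buildFeatures(m0)
    expect_false(f0$has_uorf)
    expect_true(is.na(f0$closest_stop_distance))
    expect_true(is.na(f0$mean_uorf_length_bp))
    expect_true(is.na(f0$mfe))
    expect_true(is.na(f0$n_riboseq_uorf))

    m3 <- TranscriptModel("g3", "t3", "c", "+", IRanges::IRanges(1, 50),
                          utr5Seq = randSeq(50), cdsSeq = "ATGTAA",
                          mrnaLength = 200L)
    f3 <- buildFeatures(m3)
    expect_equal(f3$utr_mrna_fraction, 0.25)
    expect_true(f3$gc_fraction >= 0 && f3$gc_fraction <= 1)
    expect_true(f3$uaug_per_bp <= 1 / 3 + 1e-9)
})
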