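# Independent oracles used to cross-check the implementation. These are
# deliberately naive (character-by-character loops, exhaustive enumeration)
# and share no code with the package internals.

NTS <- c("A", "C", "G", "T")

randSeq <- function(L, alphabet = NTS) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# brute-force uAUG classification: walk every frame codon by codon
oracleScan <- function(utr) {
    L <- nchar(utr)
    out <- list()
    for (i in seq_len(max(0L, L - 2L))) {
        if (substr(utr, i, i + 2L) != "ATG") next
        klass <- NULL; stopEnd <- NA_integer_
        j <- i + 3L
        while (j + 2L <= L) {
            cod <- substr(utr, j, j + 2L)
            if (cod %in% c("TAA", "TAG", "TGA")) {
                klass <- if (j == i + 3L) "start_stop" else "uORF"
                stopEnd <- j + 2L
                break
            }
            j <- j + 3L
        }
        if (is.null(klass))
            klass <- if ((L - (i - 1L)) %% 3L == 0L) "NTE"
                     else "oORF_out_of_frame"
        out[[length(out) + 1L]] <- data.frame(
            utr_offset = i - 1L, klass = klass,
            stop_offset = stopEnd,           # 0-based one past stop
            length_bp = if (is.na(stopEnd)) NA_integer_
                        else stopEnd - i + 1L,
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(utr_offset = integer(0), klass = character(0),
                          stop_offset = integer(0), length_bp = integer(0)))
    do.call(rbind, out)
}

# the multiset of consecutive pairs of a sequence
dinucMultiset <- function(seq) {
    ch <- strsplit(seq, "")[[1L]]
    sort(paste0(ch[-length(ch)], ch[-1L]))
}

# exhaustive DFS enumeration of all distinct strings sharing a sequence's
# dinucleotide multiset and first character (= all its Eulerian trails)
oracleShuffleSet <- function(seq) {
    ch <- strsplit(seq, "")[[1L]]
    L <- length(ch)
    if (L < 2L) return(seq)
    edges <- paste0(ch[-L], ch[-1L])
    found <- new.env()
    recurse <- function(prefix, remaining) {
        if (!length(remaining)) {
            assign(paste(prefix, collapse = ""), TRUE, envir = found)
            return(invisible())
        }
        cur <- prefix[length(prefix)]
        nxt <- unique(substr(remaining[startsWith(remaining, cur)], 2L, 2L))
        for (b in nxt) {
            e <- paste0(cur, b)
            idx <- match(e, remaining)
            recurse(c(prefix, b), remaining[-idx])
        }
    }
    recurse(ch[1L], edges)
    sort(ls(found))
}

# exact two-sided rank-sum permutation p-value by exhaustive enumeration
exactRankSumP <- function(a, b) {
    n1 <- length(a); n <- n1 + length(b)
    r <- rank(c(a, b))
    w <- sum(r[seq_len(n1)])
    ws <- apply(utils::combn(n, n1), 2L, function(ix) sum(r[ix]))
    min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# naive variant-effect oracle: rebuild the altered sequence by plain string
# surgery, rescan both sides with the brute-force scanner, map reference
# starts by simple arithmetic, and diff the start sets
oracleVariantEffects <- function(utr, offset, ref, alt) {
    L <- nchar(utr)
    r <- nchar(ref); a <- nchar(alt)
    altSeq <- paste0(substr(utr, 1L, offset), alt,
                     substring(utr, offset + r + 1L))
    mapOff <- function(o) {
        if (r == a) return(o)       # in-place substitution keeps coordinates
        if (o < offset) return(o)
        common <- 0L
        while (common < min(r, a) &&
               substr(ref, common + 1L, common + 1L) ==
               substr(alt, common + 1L, common + 1L)) common <- common + 1L
        if (o < offset + common) return(o)
        if (o < offset + r) return(NA_integer_)
        o + (a - r)
    }
    re <- oracleScan(utr)
    ae <- oracleScan(altSeq)
    reMapped <- vapply(re$utr_offset, mapOff, integer(1))
    survives <- !is.na(reMapped) & reMapped %in% ae$utr_offset
    eff <- character(0)
    if (any(!(ae$utr_offset %in% reMapped[survives]))) eff <- c(eff, "uAUG_gained")
    if (any(!survives)) eff <- c(eff, "uAUG_lost")
    orfish <- c("uORF", "start_stop")
    kz <- function(s, off) {
        m3 <- if (off >= 3L) substr(s, off - 2L, off - 2L) else ""
        p4 <- substr(s, off + 4L, off + 4L)
        c1 <- m3 %in% c("A", "G"); c2 <- identical(p4, "G")
        if (c1 && c2) "strong" else if (c1 || c2) "moderate" else "weak"
    }
    for (i in which(survives)) {
        kR <- re$klass[i]
        j <- match(reMapped[i], ae$utr_offset)
        kA <- ae$klass[j]
        if (kR %in% orfish && !(kA %in% orfish)) eff <- c(eff, "uSTOP_lost")
        else if (!(kR %in% orfish) && kA %in% orfish) eff <- c(eff, "uSTOP_gained")
        else if (kz(utr, re$utr_offset[i]) != kz(altSeq, reMapped[i]))
            eff <- c(eff, "kozak_changed")
    }
    eff <- unique(eff)
    if (!length(eff)) eff <- "none"
    sort(eff)
}

# a small hand-checkable transcript model on a toy contig
toyModel <- function(utr = "ACGTTTAG", cds = "ATGAAATGA",
                     exons = IRanges::IRanges(c(1, 11), c(4, 14)),
                     strand = "+", contig = "chr_t") {
    TranscriptModel("gToy", "tToy", contig, strand, exons, utr, cds)
}

# write a minimal GTF + FASTA pair for loader tests
writeToyGenome <- function(dir, contigs, gtfLines) {
    fa <- file.path(dir, "toy.fa")
    con <- file(fa, "w")
    for (nm in names(contigs)) {
        writeLines(paste0(">", nm), con)
        writeLines(contigs[[nm]], con)
    }
    close(con)
    gtf <- file.path(dir, "toy.gtf")
    writeLines(gtfLines, gtf)
    list(fa = fa, gtf = gtf)
}

gtfLine <- function(contig, type, start, end, strand, gene, tx) {
    paste(contig, "toy", type, start, end, ".", strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s";', gene, tx),
          sep = "\t")
}
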