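#' Load representative transcript models from a GTF and genome FASTA
#'
#' Reads exon and CDS features grouped by transcript, derives the 5'UTR of
#' each transcript, splices its sequence from the genome (reverse
#' complementing minus-strand transcripts) and returns one validated
#' [TranscriptModel-class] per retained gene. Explicit `five_prime_utr`
#' features are honoured where present; otherwise the 5'UTR is inferred as
#' the exonic sequence 5' of the first CDS base.
#'
#' Transcripts with an empty 5'UTR (CDS starting at the transcript start) are
#' excluded and counted; transcripts without CDS features are skipped with a
#' warning; an exon extending beyond its contig is a hard error naming the
#' transcript. When a gene has several transcripts the first encountered is
#' kept with a warning, mirroring a single-representative-transcript design.
#'
#' @param gtfPath path to a GTF/GFF file with `exon` and `CDS` features
#'   carrying `gene_id` and `transcript_id` attributes.
#' @param fastaPath path to the genome FASTA.
#' @return A [TranscriptModelList-class] ordered by gene id.
#'   `S4Vectors::metadata()` holds `transcriptsSeen`, `excludedEmptyUTR` and
#'   `skippedNoCDS`, so `retained + excludedEmptyUTR + skippedNoCDS ==
#'   transcriptsSeen`.
#' @export
loadTranscripts <- function(gtfPath, fastaPath) {
    gr <- rtracklayer::import(gtfPath)
    genome <- Biostrings::readDNAStringSet(fastaPath)
    names(genome) <- sub("\\s.*$", "", names(genome))

    typ <- as.character(gr$type)
    keep <- typ %in% c("exon", "CDS", "five_prime_utr")
    gr <- gr[keep]; typ <- typ[keep]
    txids <- unique(gr$transcript_id)

    models <- list()
    seenGene <- character(0)
    excludedEmptyUTR <- 0L
    skippedNoCDS <- 0L

    for (tx in txids) {
        sel <- gr[gr$transcript_id == tx]
        exons <- sel[sel$type == "exon"]
        cds <- sel[sel$type == "CDS"]
        u5 <- sel[sel$type == "five_prime_utr"]
        gid <- unique(exons$gene_id)
        if (length(gid) == 0L) gid <- unique(sel$gene_id)
        gid <- gid[1L]
        if (length(cds) == 0L) {
            warning("transcript ", tx, " has no CDS features; skipped")
            skippedNoCDS <- skippedNoCDS + 1L
            next
        }
        std <- as.character(GenomicRanges::strand(cds))[1L]
        if (!std %in% c("+", "-")) std <- "+"
        contig <- as.character(GenomicRanges::seqnames(cds))[1L]
        if (!contig %in% names(genome))
            stop("transcript ", tx, ": contig ", contig, " absent from FASTA")
        clen <- length(genome[[contig]])
        exons <- exons[order(GenomicRanges::start(exons))]
        if (length(exons) &&
            (min(GenomicRanges::start(exons)) < 1L ||
             max(GenomicRanges::end(exons)) > clen))
            stop("transcript ", tx, ": exon beyond bounds of contig ", contig)

        exR <- IRanges::IRanges(GenomicRanges::start(exons),
                                GenomicRanges::end(exons))
        # first CDS base in genomic coordinates, on the transcript strand
        cdsStart <- if (std == "+") min(GenomicRanges::start(cds))
                    else            max(GenomicRanges::end(cds))

        if (length(u5) > 0L) {
            u5 <- u5[order(GenomicRanges::start(u5))]
            utrR <- IRanges::IRanges(GenomicRanges::start(u5),
                                     GenomicRanges::end(u5))
        } else {
            utrR <- .utrFromExons(exR, cdsStart, std)
        }
        if (sum(IRanges::width(utrR)) == 0L) {
            excludedEmptyUTR <- excludedEmptyUTR + 1L
            next
        }
        if (gid %in% seenGene) {
            warning("gene ", gid, " has multiple transcripts; keeping first")
            next
        }
        seenGene <- c(seenGene, gid)

        # transcript order: genomic-descending blocks on the minus strand
        if (std == "-") utrR <- rev(utrR)
        utrSeq <- .spliceSeq(genome[[contig]], utrR, std)
        cdsR <- IRanges::IRanges(GenomicRanges::start(cds),
                                 GenomicRanges::end(cds))
        cdsR <- if (std == "-") rev(cdsR[order(IRanges::start(cdsR))])
                else cdsR[order(IRanges::start(cdsR))]
        cdsSeqStr <- .spliceSeq(genome[[contig]], cdsR, std)
        mlen <- sum(IRanges::width(exR))

        models[[gid]] <- TranscriptModel(
            geneId = gid, transcriptId = tx, contig = contig, strand = std,
            utr5Exons = utrR, utr5Seq = utrSeq, cdsSeq = cdsSeqStr,
            mrnaLength = mlen)
    }

    out <- TranscriptModelList(models)
    S4Vectors::metadata(out) <- list(
        transcriptsSeen = length(txids),
        excludedEmptyUTR = excludedEmptyUTR,
        skippedNoCDS = skippedNoCDS)
    out
}

# exonic intervals strictly 5' of the first CDS base, in transcript order for +
.utrFromExons <- function(exR, cdsStart, strand) {
    if (strand == "+") {
        keep <- IRanges::start(exR) < cdsStart
        out <- exR[keep]
        n <- length(out)
        if (n && IRanges::end(out)[n] >= cdsStart)
            IRanges::end(out)[n] <- cdsStart - 1L
    } else {
        keep <- IRanges::end(exR) > cdsStart
        out <- exR[keep]
        if (length(out) && IRanges::start(out)[1L] <= cdsStart)
            IRanges::start(out)[1L] <- cdsStart + 1L
    }
    out[IRanges::width(out) > 0L]
}

# splice genomic blocks (IRanges, transcript order) into a transcript-strand string
.spliceSeq <- function(contigSeq, blocks, strand) {
    if (length(blocks) == 0L) return("")
    pieces <- vapply(seq_along(blocks), function(i) {
        s <- Biostrings::subseq(contigSeq, IRanges::start(blocks)[i],
                                IRanges::end(blocks)[i])
        if (strand == "-") s <- Biostrings::reverseComplement(s)
        as.character(s)
    }, character(1))
    toupper(paste0(pieces, collapse = ""))
}

#' Load and merge per-gene metadata tables
#'
#' Reads the LOEUF constraint table (duplicate rows per gene resolved by
#' keeping the *higher* score), optional gene-set membership flags, CAGE peak
#' counts and mean expression, and merges them into one row per gene. LOEUF
#' deciles are assigned by rank (ascending; decile 1 = most LoF intolerant)
#' with populations differing by at most one gene; ties are broken by gene id
#' for determinism. Genes absent from a metadata file carry `NA`, never zero.
#'
#' @param loeufPath TSV with columns `gene_id`, `loeuf` (one row per
#'   transcript allowed).
#' @param genesetPath optional TSV with `gene_id` plus logical/0-1 columns
#'   `DD_dominant`, `DD_recessive`, `oncogene`, `TSG`, `HS`, `TS` (any
#'   subset).
#' @param cagePath optional TSV with `gene_id`, `cage_peaks`.
#' @param tpmPath optional TSV with `gene_id`, `mean_tpm`.
#' @param geneIds optional character vector of the gene universe (e.g. from a
#'   [TranscriptModelList-class]); genes absent from all files are kept with
#'   missing values.
#' @return data.frame with columns `gene_id`, `loeuf`, `loeuf_decile`,
#'   the gene-set flags, `cage_peaks`, `mean_tpm`.
#' @export
loadGeneMeta <- function(loeufPath, genesetPath = NULL, cagePath = NULL,
                         tpmPath = NULL, geneIds = NULL) {
    loeuf <- .readTsvChecked(loeufPath, numeric = "loeuf")
    # duplicate LOEUF rows: keep the transcript with the higher score
    loeuf <- loeuf[order(loeuf$gene_id, -loeuf$loeuf), , drop = FALSE]
    loeuf <- loeuf[!duplicated(loeuf$gene_id), c("gene_id", "loeuf")]

    ids <- unique(c(geneIds, loeuf$gene_id))
    meta <- data.frame(gene_id = sort(ids), stringsAsFactors = FALSE)
    meta$loeuf <- loeuf$loeuf[match(meta$gene_id, loeuf$gene_id)]
    meta$loeuf_decile <- rankBins(meta$loeuf, meta$gene_id, nBins = 10L)

    setCols <- c("DD_dominant", "DD_recessive", "oncogene", "TSG", "HS", "TS")
    for (sc in setCols) meta[[sc]] <- FALSE
    if (!is.null(genesetPath)) {
        gs <- utils::read.delim(genesetPath, stringsAsFactors = FALSE)
        for (sc in intersect(setCols, names(gs))) {
            on <- gs$gene_id[as.logical(gs[[sc]])]
            meta[[sc]] <- meta$gene_id %in% on
        }
    }
    meta$cage_peaks <- NA_integer_
    if (!is.null(cagePath)) {
        cg <- .readTsvChecked(cagePath, numeric = "cage_peaks")
        meta$cage_peaks <- as.integer(cg$cage_peaks[match(meta$gene_id, cg$gene_id)])
    }
    meta$mean_tpm <- NA_real_
    if (!is.null(tpmPath)) {
        tp <- .readTsvChecked(tpmPath, numeric = "mean_tpm")
        meta$mean_tpm <- tp$mean_tpm[match(meta$gene_id, tp$gene_id)]
    }
    meta
}

# read a headered TSV, validating numeric columns with a line number on failure
.readTsvChecked <- function(path, numeric = character(0)) {
    x <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    for (col in numeric) {
        if (!col %in% names(x))
            stop("file ", path, " lacks required column '", col, "'")
        v <- suppressWarnings(as.numeric(x[[col]]))
        bad <- which(is.na(v) & !(x[[col]] %in% c("", "NA")))
        if (length(bad))
            stop("file ", path, ", line ", bad[1L] + 1L,
                 ": unparseable numeric value '", x[[col]][bad[1L]],
                 "' in column '", col, "'")
        x[[col]] <- v
    }
    x
}

#' Equal-population rank binning
#'
#' Bins non-missing values into `nBins` groups by ascending rank with
#' populations differing by at most one; ties are broken by `tieBreak`
#' (typically the gene id) so assignment is deterministic. `NA` values get
#' `NA` bins.
#'
#' @param x numeric vector.
#' @param tieBreak vector of the same length used to order ties.
#' @param nBins number of bins (10 for deciles, 4 for quartiles).
#' @return integer vector of bin labels in `1:nBins`.
#' @export
rankBins <- function(x, tieBreak = seq_along(x), nBins = 10L) {
    out <- rep(NA_integer_, length(x))
    ok <- which(!is.na(x))
    if (!length(ok)) return(out)
    n <- length(ok)
    ord <- ok[order(x[ok], tieBreak[ok])]
    base <- n %/% nBins
    extra <- n %% nBins
    sizes <- base + (seq_len(nBins) <= extra)
    out[ord] <- rep(seq_len(nBins), times = sizes)
    out
}

#' Load an experimentally supported uORF evidence set
#'
#' Reads a TSV of translated upstream elements (e.g. from ribosome
#' profiling), keeps only records typed `uORF` (dropping dORFs and other
#' classes), and tallies canonical (`ATG`) versus non-canonical start codons.
#' Coordinates are transcript-space, 0-based half-open over the full element
#' (start codon through stop codon).
#'
#' @param path TSV with columns `gene_id`, `start`, `end`, `type`,
#'   `start_codon`.
#' @return data.frame of retained records with attributes `nCanonical`,
#'   `nNonCanonical`.
#' @export
loadEvidenceUORFs <- function(path) {
    x <- .readTsvChecked(path, numeric = c("start", "end"))
    if (any(x$end <= x$start))
        stop("evidence file ", path, " rejected: record with end <= start")
    x$start <- as.integer(x$start); x$end <- as.integer(x$end)
    x <- x[x$type == "uORF", , drop = FALSE]
    x$canonical <- x$start_codon == "ATG"
    attr(x, "nCanonical") <- sum(x$canonical)
    attr(x, "nNonCanonical") <- sum(!x$canonical)
    x
}

#' Read a per-base score track
#'
#' Accepts a bedGraph (`contig start end score`, 0-based half-open; intervals
#' wider than one base are expanded) or a headered TSV with columns `contig`,
#' `pos` (0-based), `score` and optionally `alt` (several rows per base, e.g.
#' per alternative allele).
#'
#' @param path track file.
#' @param format `"bedGraph"` or `"tsv"`; guessed from the extension.
#' @return A [ScoreTrack-class].
#' @export
readScoreTrack <- function(path, format = c("auto", "bedGraph", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
            "bedGraph" else "tsv"
    if (format == "bedGraph") {
        gr <- rtracklayer::import(path, format = "bedGraph")
        w <- GenomicRanges::width(gr)
        contig <- rep(as.character(GenomicRanges::seqnames(gr)), w)
        pos <- unlist(lapply(seq_along(gr), function(i)
            seq(GenomicRanges::start(gr)[i] - 1L,
                GenomicRanges::end(gr)[i] - 1L)))
        score <- rep(gr$score, w)
    } else {
        x <- .readTsvChecked(path, numeric = c("pos", "score"))
        contig <- x$contig; pos <- as.integer(x$pos); score <- x$score
    }
    new("ScoreTrack", contig = as.character(contig), pos = as.integer(pos),
        score = as.numeric(score))
}

#' @rdname readScoreTrack
#' @param contig,pos,score parallel vectors defining the track directly
#'   (`pos` 0-based).
#' @export
ScoreTrack <- function(contig, pos, score) {
    new("ScoreTrack", contig = as.character(contig), pos = as.integer(pos),
        score = as.numeric(score))
}

setMethod("show", "ScoreTrack", function(object) {
    cat("ScoreTrack:", length(object@score), "scored bases on",
        length(unique(object@contig)), "contig(s)\n")
})
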