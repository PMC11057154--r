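#' Apply a variant to a spliced 5'UTR
#'
#' Edits the spliced 5'UTR in transcript space. The variant is given as a
#' 0-based UTR offset with explicit `ref`/`alt` allele strings (SNVs
#' substitute in place; insertions and deletions shift downstream offsets).
#' The returned coordinate map sends every reference offset to its offset in
#' the altered sequence, with `NA` for deleted bases; in-place substitutions
#' keep every coordinate, so the identity of elements whose position merely
#' shifts is preserved.
#'
#' @param utr5Seq spliced reference 5'UTR.
#' @param offset 0-based offset of the first `ref` base.
#' @param ref,alt allele strings over `ACGT` (either may be longer; a shared
#'   prefix is treated as anchored, VCF-style).
#' @return list with `seq` (altered 5'UTR) and `map` (integer vector of
#'   length `nchar(utr5Seq)`; `map[i + 1]` is the altered offset of reference
#'   offset `i`, or `NA`).
#' @examples
#' applyUTRVariant("CCTTGCCC", 2, "T", "A")$seq        # "CCATGCCC"
#' applyUTRVariant("CCTTGCCC", 3, "TG", "")$seq        # 2 bp deletion
#' @export
applyUTRVariant <- function(utr5Seq, offset, ref, alt) {
    L <- nchar(utr5Seq)
    r <- nchar(ref); a <- nchar(alt)
    if (offset < 0L || offset + r > L)
        stop("variant at offset ", offset,
             " spans beyond the 5'UTR; boundary-spanning variants are rejected")
    if (r > 0L && substr(utr5Seq, offset + 1L, offset + r) != ref)
        stop("reference allele mismatch at 5'UTR offset ", offset,
             ": expected '", ref, "', found '",
             substr(utr5Seq, offset + 1L, offset + r), "'")
    seqOut <- paste0(substr(utr5Seq, 1L, offset), alt,
                     substring(utr5Seq, offset + r + 1L))

    map <- rep(NA_integer_, L)
    if (r == a) {
        # in-place substitution: every position keeps its coordinate
        map <- seq_len(L) - 1L
    } else {
        before <- seq_len(offset)                # offsets 0..offset-1
        map[before] <- before - 1L
        if (r > 0L && a > 0L) {
            # shared leading bases keep their identity (anchored indels)
            common <- 0L
            while (common < min(r, a) &&
                   substr(ref, common + 1L, common + 1L) ==
                   substr(alt, common + 1L, common + 1L)) common <- common + 1L
            if (common > 0L)
                map[offset + seq_len(common)] <- offset + seq_len(common) - 1L
        }
        after <- offset + r + seq_len(max(0L, L - offset - r))
        map[after] <- after - 1L + (a - r)
    }
    list(seq = seqOut, map = map)
}

#' @rdname applyUTRVariant
#' @param model a [TranscriptModel-class].
#' @param pos 1-based genomic position of the first `ref` base (VCF
#'   convention); alleles are on the genomic strand. The variant must lie
#'   within a 5'UTR exon; indels on minus-strand transcripts are not
#'   supported and raise an error.
#' @export
applyVariant <- function(model, pos, ref, alt) {
    off <- genomicToTranscript(model, pos - 1L)
    if (is.na(off))
        stop("position ", pos, " does not fall in a 5'UTR exon of ",
             transcriptId(model))
    if (model@strand == "-") {
        if (nchar(ref) != 1L || nchar(alt) != 1L)
            stop("indels on minus-strand transcripts are not supported")
        ref <- .revcomp(ref); alt <- .revcomp(alt)
    } else {
        endOff <- genomicToTranscript(model, pos - 1L + nchar(ref) - 1L)
        if (nchar(ref) > 1L && is.na(endOff))
            stop("variant at position ", pos,
                 " spans the 5'UTR/CDS or exon boundary; rejected")
    }
    applyUTRVariant(utr5Seq(model), off, ref, alt)
}

.revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Classify a variant's effect on the upstream ORF landscape
#'
#' Compares the reference and altered element sets, tracking element identity
#' through the variant's coordinate map so an indel that merely shifts an
#' existing uAUG is not reported as lost-and-gained:
#'
#' * `uAUG_gained` -- the altered UTR has an element start with no reference
#'   counterpart;
#' * `uAUG_lost` -- a reference element's start has no surviving counterpart;
#' * `uSTOP_lost` -- a reference uORF/start-stop keeps its start but loses
#'   its in-UTR stop (its class becomes `oORF_out_of_frame` or `NTE`);
#' * `uSTOP_gained` -- a reference oORF/NTE gains an in-UTR stop;
#' * `kozak_changed` -- a surviving element of unchanged class changes Kozak
#'   strength class;
#' * `none` -- otherwise (never co-occurring with another label).
#'
#' @param refElements,altElements [scanUpstreamAUGs()] outputs for the
#'   reference and altered 5'UTR.
#' @param map coordinate map from [applyUTRVariant()].
#' @return list with `effects` (character vector), `created` and `destroyed`
#'   (row indices into `altElements` / `refElements`), and
#'   `resulting_klass` (class of the first created or altered element, or
#'   `NA`).
#' @export
classifyVariantEffect <- function(refElements, altElements, map) {
    refStart <- refElements$utr_offset
    altStart <- altElements$utr_offset
    mapped <- map[refStart + 1L]                  # NA = start base destroyed

    survives <- !is.na(mapped) & mapped %in% altStart
    altIdx <- match(mapped, altStart)

    effects <- character(0)
    created <- which(!(altStart %in% mapped[survives]))
    destroyed <- which(!survives)
    resulting <- NA_character_

    if (length(created)) {
        effects <- c(effects, "uAUG_gained")
        resulting <- altElements$klass[created[1L]]
    }
    if (length(destroyed)) effects <- c(effects, "uAUG_lost")

    orfish <- c("uORF", "start_stop")
    for (i in which(survives)) {
        kRef <- refElements$klass[i]
        kAlt <- altElements$klass[altIdx[i]]
        if (kRef %in% orfish && !(kAlt %in% orfish)) {
            effects <- c(effects, "uSTOP_lost")
            if (is.na(resulting)) resulting <- kAlt
        } else if (!(kRef %in% orfish) && kAlt %in% orfish) {
            effects <- c(effects, "uSTOP_gained")
            if (is.na(resulting)) resulting <- kAlt
        } else if (refElements$kozak[i] != altElements$kozak[altIdx[i]]) {
            effects <- c(effects, "kozak_changed")
            if (is.na(resulting)) resulting <- kAlt
        }
    }
    effects <- unique(effects)
    if (!length(effects)) effects <- "none"
    list(effects = effects, created = created, destroyed = destroyed,
         resulting_klass = resulting)
}

#' Annotate a table of 5'UTR variants
#'
#' Applies each variant to its transcript, rescans the altered 5'UTR and
#' classifies the effect on the uAUG landscape. Variants that cannot be
#' applied (outside 5'UTR exons, boundary-spanning, reference mismatch) are
#' returned with `effects = "rejected"` and the reason.
#'
#' @param models a [TranscriptModelList-class].
#' @param variants data.frame with columns `contig`, `pos` (1-based genomic),
#'   `ref`, `alt` and either `gene_id` or `transcript_id` identifying the
#'   model (see [readVariants()]).
#' @return `variants` with added columns `effects` (comma-joined labels),
#'   `resulting_klass`, `reject_reason`.
#' @export
annotateVariants <- function(models, variants) {
    byGene <- stats::setNames(seq_along(models), names(models))
    txIds <- vapply(models, transcriptId, character(1))
    effects <- character(nrow(variants))
    resulting <- rep(NA_character_, nrow(variants))
    reason <- rep(NA_character_, nrow(variants))
    for (i in seq_len(nrow(variants))) {
        mi <- if ("gene_id" %in% names(variants))
            unname(byGene[variants$gene_id[i]])
        else match(variants$transcript_id[i], txIds)
        if (length(mi) != 1L || is.na(mi)) {
            effects[i] <- "rejected"; reason[i] <- "unknown_gene"; next
        }
        m <- models[[mi]]
        res <- tryCatch(
            applyVariant(m, variants$pos[i], variants$ref[i],
                         variants$alt[i]),
            error = function(e) conditionMessage(e))
        if (is.character(res)) {
            effects[i] <- "rejected"; reason[i] <- res; next
        }
        refEl <- scanUpstreamAUGs(utr5Seq(m), cdsSeq(m))
        altEl <- scanUpstreamAUGs(res$seq, cdsSeq(m))
        cls <- classifyVariantEffect(refEl, altEl, res$map)
        effects[i] <- paste(cls$effects, collapse = ",")
        resulting[i] <- cls$resulting_klass
    }
    variants$effects <- effects
    variants$resulting_klass <- resulting
    variants$reject_reason <- reason
    variants
}

#' Saturation enumeration of small 5'UTR variants
#'
#' Enumerates, in transcript space, every possible single-nucleotide variant
#' (3 per `N`-free base), every deletion of length 1 to `maxIndel` starting
#' at each base (so position `p`, 0-based, has `min(maxIndel, L - p)`
#' deletion lengths), and every insertion of each of the `4^k` sequences of
#' length `k <= maxIndel` before each position, classifying each against the
#' reference landscape. Output order is deterministic: position, then
#' variant type (SNV, deletion, insertion), then allele.
#'
#' @param model a [TranscriptModel-class].
#' @param maxIndel maximum indel length (default 3).
#' @return data.frame with `utr_offset` (0-based), `type`, `ref`, `alt`,
#'   `effects`, `resulting_klass`.
#' @export
saturateVariants <- function(model, maxIndel = 3L) {
    utr <- utr5Seq(model)
    cds <- cdsSeq(model)
    L <- nchar(utr)
    refEl <- scanUpstreamAUGs(utr, cds)
    nts <- c("A", "C", "G", "T")
    insSeqs <- unlist(lapply(seq_len(maxIndel), function(k)
        Biostrings::mkAllStrings(nts, k)))

    rows <- vector("list", L)
    for (p in 0:(L - 1L)) {
        refBase <- substr(utr, p + 1L, p + 1L)
        recs <- list()
        if (refBase %in% nts) {
            for (nt in setdiff(nts, refBase))
                recs[[length(recs) + 1L]] <-
                    list(off = p, type = "SNV", ref = refBase, alt = nt)
        }
        for (k in seq_len(min(maxIndel, L - p)))
            recs[[length(recs) + 1L]] <-
                list(off = p, type = "del",
                     ref = substr(utr, p + 1L, p + k), alt = "")
        for (ins in insSeqs)
            recs[[length(recs) + 1L]] <-
                list(off = p, type = "ins", ref = "", alt = ins)
        rows[[p + 1L]] <- recs
    }
    recs <- do.call(c, rows)

    out <- data.frame(
        utr_offset = vapply(recs, `[[`, numeric(1), "off"),
        type = vapply(recs, `[[`, character(1), "type"),
        ref = vapply(recs, `[[`, character(1), "ref"),
        alt = vapply(recs, `[[`, character(1), "alt"),
        stringsAsFactors = FALSE)
    out$effects <- NA_character_
    out$resulting_klass <- NA_character_
    for (i in seq_len(nrow(out))) {
        ap <- applyUTRVariant(utr, out$utr_offset[i], out$ref[i], out$alt[i])
        altEl <- scanUpstreamAUGs(ap$seq, cds)
        cls <- classifyVariantEffect(refEl, altEl, ap$map)
        out$effects[i] <- paste(cls$effects, collapse = ",")
        out$resulting_klass[i] <- cls$resulting_klass
    }
    out
}

#' Read variants from a VCF
#'
#' Thin wrapper over [VariantAnnotation::readVcf()] returning the flat table
#' [annotateVariants()] consumes; multi-allelic records are expanded to one
#' row per alternative allele. The optional `GENE` INFO field is carried
#' through as `gene_id`.
#'
#' @param path uncompressed or bgzipped VCF.
#' @return data.frame with `contig`, `pos`, `ref`, `alt` and, when present,
#'   `gene_id`.
#' @export
readVariants <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    altList <- VariantAnnotation::alt(vcf)
    n <- S4Vectors::elementNROWS(altList)
    idx <- rep(seq_along(rr), n)
    out <- data.frame(
        contig = as.character(GenomicRanges::seqnames(rr))[idx],
        pos = GenomicRanges::start(rr)[idx],
        ref = as.character(VariantAnnotation::ref(vcf))[idx],
        alt = as.character(unlist(altList)),
        stringsAsFactors = FALSE)
    info <- VariantAnnotation::info(vcf)
    if ("GENE" %in% names(info))
        out$gene_id <- as.character(info$GENE)[idx]
    out
}

#' Write a minimal VCF of 5'UTR variants
#'
#' Emits VCF 4.2 with a `GENE` INFO field (and `U5_EFFECT` when an `effects`
#' column is present), one record per row.
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt` and
#'   optionally `gene_id`, `effects`.
#' @param path output path.
#' @export
writeVariantVCF <- function(variants, path) {
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
        "##INFO=<ID=U5_EFFECT,Number=1,Type=String,Description=\"5'UTR uAUG landscape effect\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- rep(".", nrow(variants))
    if ("gene_id" %in% names(variants))
        info <- paste0("GENE=", variants$gene_id)
    if ("effects" %in% names(variants))
        info <- paste0(info, ";U5_EFFECT=", variants$effects)
    body <- paste(variants$contig, variants$pos, ".", variants$ref,
                  variants$alt, ".", "PASS", info, sep = "\t")
    writeLines(c(hdr, body), path)
}
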