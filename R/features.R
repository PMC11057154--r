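#' Assemble the per-gene 5'UTR feature vector
#'
#' Combines the scanned upstream elements with sequence statistics,
#' conservation/deleteriousness aggregates, secondary-structure energy and
#' evidence-set counts into the one-row feature vector the cohort statistics
#' consume. Fields that cannot be computed (no uORF, no track, no folding
#' backend, no evidence) are `NA` by contract, never zero.
#'
#' Conventions: `n_oorf` pools out-of-frame oORFs and N-terminal extensions
#' (`n_nte` also reports the latter alone); start-stops are a class of their
#' own and are *not* counted in `n_uorf`; `closest_stop_distance` is the
#' smallest `distance_to_cds` over uORFs and start-stops (the potential
#' re-initiation distance); `mean_uorf_length_bp` averages uORF and
#' start-stop lengths (start through stop codon inclusive). PhyloP-style
#' aggregation follows the study design: one mean over all 5'UTR bases, one
#' over all uORF start+stop codon bases pooled across uORFs, one over all
#' bases of start-stops.
#'
#' @param model a [TranscriptModel-class].
#' @param elements optional pre-computed [scanUpstreamAUGs()] output for the
#'   model (recomputed when `NULL`).
#' @param phylop,cadd optional [ScoreTrack-class] objects.
#' @param evidence optional evidence data.frame (see [loadEvidenceUORFs()])
#'   for this gene's transcript.
#' @param mfeBackend folding backend passed to [foldMFE()]; `NA` skips
#'   folding entirely.
#' @return one-row data.frame (see Details for the column conventions).
#' @export
buildFeatures <- function(model, elements = NULL, phylop = NULL, cadd = NULL,
                          evidence = NULL, mfeBackend = NA) {
    utr <- utr5Seq(model)
    L <- nchar(utr)
    if (is.null(elements)) elements <- scanUpstreamAUGs(utr, cdsSeq(model))

    isUorf <- elements$klass == "uORF"
    isSS <- elements$klass == "start_stop"
    isNte <- elements$klass == "NTE"
    isOof <- elements$klass == "oORF_out_of_frame"
    orfLike <- isUorf | isSS

    closest <- if (any(orfLike)) min(elements$distance_to_cds[orfLike])
               else NA_integer_
    meanLen <- if (any(orfLike)) mean(elements$length_bp[orfLike])
               else NA_real_

    phUtr <- phOrf <- phSS <- caddUtr <- NA_real_
    if (!is.null(phylop)) {
        phUtr <- aggregateTrack(model, phylop)$mean
        if (any(orfLike)) {
            iv <- .orfBoundIntervals(elements[orfLike & isUorf, , drop = FALSE])
            if (nrow(iv)) phOrf <- aggregateTrack(model, phylop, iv)$mean
        }
        if (any(isSS)) {
            ss <- elements[isSS, , drop = FALSE]
            iv <- data.frame(start = ss$utr_offset, end = ss$stop_offset)
            phSS <- aggregateTrack(model, phylop, iv)$mean
        }
    }
    if (!is.null(cadd)) caddUtr <- aggregateTrack(model, cadd)$mean

    mfe <- if (length(mfeBackend) == 1L && !is.function(mfeBackend) &&
               is.na(mfeBackend)) NA_real_ else foldMFE(utr, mfeBackend)

    nRibo <- NA_integer_; nRiboCanon <- NA_integer_; riboFrac <- NA_real_
    if (!is.null(evidence)) {
        nRibo <- nrow(evidence)
        nRiboCanon <- sum(evidence$canonical)
        riboFrac <- if (nRibo > 0L) nRiboCanon / nRibo else NA_real_
    }

    data.frame(
        gene_id = geneId(model),
        utr_length = L,
        gc_fraction = gcContent(utr),
        intron_count = utr5IntronCount(model),
        n_uaug = nrow(elements),
        n_uorf = sum(isUorf),
        n_oorf = sum(isNte | isOof),
        n_nte = sum(isNte),
        n_start_stop = sum(isSS),
        uaug_per_bp = nrow(elements) / L,
        has_uorf = any(isUorf),
        has_oorf = any(isNte | isOof),
        has_start_stop = any(isSS),
        closest_stop_distance = closest,
        mean_uorf_length_bp = meanLen,
        mean_phylop_utr = phUtr,
        mean_phylop_uorf_bounds = phOrf,
        mean_phylop_startstop = phSS,
        mean_cadd_utr = caddUtr,
        mfe = mfe,
        utr_mrna_fraction = L / mrnaLength(model),
        n_riboseq_uorf = nRibo,
        n_riboseq_canonical = nRiboCanon,
        riboseq_canonical_fraction = riboFrac,
        stringsAsFactors = FALSE)
}

# start-codon and stop-codon intervals of uORFs, pooled
.orfBoundIntervals <- function(uorfs) {
    if (!nrow(uorfs)) return(data.frame(start = integer(0), end = integer(0)))
    data.frame(
        start = c(uorfs$utr_offset, uorfs$stop_offset - 3L),
        end = c(uorfs$utr_offset + 3L, uorfs$stop_offset))
}

#' Build the cohort feature table
#'
#' Runs [buildFeatures()] over every model and returns one row per gene,
#' ordered by gene id. The per-gene evidence subset is selected by
#' `gene_id`.
#'
#' @param models a [TranscriptModelList-class].
#' @param phylop,cadd optional [ScoreTrack-class] objects.
#' @param evidence optional cohort evidence data.frame with a `gene_id`
#'   column; genes absent from it get missing evidence fields, genes present
#'   with zero uORF rows get zeros.
#' @param mfeBackend folding backend (see [buildFeatures()]); default `NA`
#'   (skip).
#' @return data.frame, one row per gene.
#' @export
buildFeatureTable <- function(models, phylop = NULL, cadd = NULL,
                              evidence = NULL, mfeBackend = NA) {
    phSplit <- if (!is.null(phylop)) .splitTrack(phylop) else NULL
    cdSplit <- if (!is.null(cadd)) .splitTrack(cadd) else NULL
    rows <- lapply(models, function(m) {
        ev <- NULL
        if (!is.null(evidence)) {
            ev <- evidence[evidence$gene_id == geneId(m), , drop = FALSE]
        }
        buildFeatures(m,
                      phylop = .trackForContig(phSplit, m@contig),
                      cadd = .trackForContig(cdSplit, m@contig),
                      evidence = ev, mfeBackend = mfeBackend)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$gene_id), , drop = FALSE]
}

# index a ScoreTrack by contig once, so per-gene aggregation over a large
# cohort does not rescan the whole track for every gene
.splitTrack <- function(track) {
    idx <- split(seq_along(track@contig), track@contig)
    list(track = track, idx = idx)
}

.trackForContig <- function(sp, contig) {
    if (is.null(sp)) return(NULL)
    i <- sp$idx[[contig]]
    if (is.null(i)) i <- integer(0)
    new("ScoreTrack", contig = sp$track@contig[i], pos = sp$track@pos[i],
        score = sp$track@score[i])
}
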