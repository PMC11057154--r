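#' Assign cohort strata to gene metadata
#'
#' Adds `loeuf_decile` (rank-binned, ascending LOEUF, decile 1 = most LoF
#' intolerant, populations differing by at most one, ties broken by gene id),
#' `loeuf_quintile_group` (`"intolerant"` for deciles 1-2, `"tolerant"` for
#' deciles 9-10, `NA` between) and `tpm_quartile` (rank quartiles of mean
#' expression over genes with a defined value; Q1 = lowest). Genes with
#' missing LOEUF or TPM get `NA` labels and drop out of the corresponding
#' stratified tests.
#'
#' @param meta data.frame with `gene_id`, `loeuf` and optionally
#'   `loeuf_decile`, `mean_tpm`.
#' @return `meta` with the stratum columns added.
#' @export
assignStrata <- function(meta) {
    if (!"loeuf_decile" %in% names(meta) || all(is.na(meta$loeuf_decile)))
        meta$loeuf_decile <- rankBins(meta$loeuf, meta$gene_id, 10L)
    meta$loeuf_quintile_group <- ifelse(
        is.na(meta$loeuf_decile), NA_character_,
        ifelse(meta$loeuf_decile <= 2L, "intolerant",
               ifelse(meta$loeuf_decile >= 9L, "tolerant", NA_character_)))
    if ("mean_tpm" %in% names(meta))
        meta$tpm_quartile <- rankBins(meta$mean_tpm, meta$gene_id, 4L)
    meta
}

#' Two-group comparison of a continuous feature
#'
#' `wilcoxon_rank_sum`: two-sided rank-sum test. When the full permutation
#' distribution is enumerable (at most `maxPerm` group assignments) the exact
#' permutation p-value is computed by exhaustive enumeration, handling ties;
#' otherwise the normal approximation with tie correction is used
#' (equivalently `stats::wilcox.test(exact = FALSE, correct = FALSE)`).
#' The two-sided exact p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#' `welch_t`: Welch's unequal-variance t-test; both groups need n >= 2.
#'
#' @param a,b numeric vectors (NAs dropped).
#' @param kind `"wilcoxon_rank_sum"` or `"welch_t"`.
#' @param maxPerm enumeration budget for the exact path.
#' @return one-row data.frame: `test_kind`, `statistic`, `p_value`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`, `median_a`, `median_b`.
#' @export
compareContinuous <- function(a, b,
                              kind = c("wilcoxon_rank_sum", "welch_t"),
                              maxPerm = 2e5) {
    kind <- match.arg(kind)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b))
        stop("compareContinuous: both groups must be non-empty")
    if (kind == "welch_t") {
        if (length(a) < 2L || length(b) < 2L)
            stop("welch_t requires at least 2 observations per group")
        tt <- stats::t.test(a, b)
        stat <- unname(tt$statistic); p <- tt$p.value
    } else {
        n1 <- length(a); n2 <- length(b)
        r <- rank(c(a, b))
        w <- sum(r[seq_len(n1)])
        if (choose(n1 + n2, n1) <= maxPerm) {
            combos <- utils::combn(n1 + n2, n1)
            ws <- colSums(matrix(r[combos], nrow = n1))
            pLo <- mean(ws <= w + 1e-9)
            pHi <- mean(ws >= w - 1e-9)
            p <- min(1, 2 * min(pLo, pHi))
        } else {
            mu <- n1 * (n1 + n2 + 1) / 2
            ties <- table(r)
            n <- n1 + n2
            sig2 <- n1 * n2 / 12 *
                ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
            z <- (w - mu) / sqrt(sig2)
            p <- 2 * stats::pnorm(-abs(z))
        }
        stat <- w
    }
    data.frame(test_kind = kind, statistic = stat, p_value = p,
               n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               median_a = stats::median(a), median_b = stats::median(b))
}

#' Two-group comparison of proportions
#'
#' 2x2 chi-square without continuity correction by default (the study's
#' regime is large-sample; Yates correction is exposed as configuration).
#' An expected cell below 1 attaches a warning flag rather than failing.
#'
#' @param kA,nA successes and totals in group A.
#' @param kB,nB successes and totals in group B.
#' @param correct apply Yates continuity correction.
#' @return one-row data.frame: `test_kind`, `statistic`, `p_value`, `n_a`,
#'   `n_b`, `prop_a`, `prop_b`, `low_expected`.
#' @export
compareProportions <- function(kA, nA, kB, nB, correct = FALSE) {
    stopifnot(kA <= nA, kB <= nB, nA > 0, nB > 0)
    tab <- rbind(c(kA, nA - kA), c(kB, nB - kB))
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    data.frame(test_kind = "chi_square",
               statistic = unname(ct$statistic), p_value = ct$p.value,
               n_a = nA, n_b = nB, prop_a = kA / nA, prop_b = kB / nB,
               low_expected = any(expd < 1))
}

#' TSS diversity comparison from CAGE peak counts
#'
#' Compares, between two groups of genes, the proportion with more than one
#' CAGE peak and the proportion with at least `thresholdHigh` peaks (the two
#' thresholds used in the study: `>1` and `>=6`).
#'
#' @param cageA,cageB integer CAGE peak counts per gene (NAs dropped).
#' @param thresholdHigh the high-diversity threshold (default 6, inclusive).
#' @return data.frame with one row per threshold (`threshold` column `">1"`,
#'   `">=6"`) in [compareProportions()] format.
#' @export
cageDiversity <- function(cageA, cageB, thresholdHigh = 6L) {
    cageA <- cageA[!is.na(cageA)]; cageB <- cageB[!is.na(cageB)]
    r1 <- compareProportions(sum(cageA > 1L), length(cageA),
                             sum(cageB > 1L), length(cageB))
    r2 <- compareProportions(sum(cageA >= thresholdHigh), length(cageA),
                             sum(cageB >= thresholdHigh), length(cageB))
    out <- rbind(r1, r2)
    out$threshold <- c(">1", paste0(">=", thresholdHigh))
    out
}

.LEDGER_GROUPINGS <- c("loeuf_extreme_quintiles", "disease_set_vs_rest",
                       "dd_recessive_vs_middle_deciles")
.PROP_FEATURES <- c("has_uorf", "has_oorf", "has_nte", "has_start_stop",
                    "has_intron", "has_riboseq_uorf", "cage_gt1", "cage_ge6")
.POOLED_FEATURES <- c("uaug_per_bp", "riboseq_canonical_fraction")

#' The default study-wide test ledger
#'
#' The analysis plans its statistical comparisons up front so the
#' Bonferroni threshold is `alpha / ledger size` regardless of which tests
#' end up running. This function returns the package's default plan -- 77
#' tests across constraint-quintile contrasts (continuous features by
#' rank-sum, conservation by Welch's t, prevalences and rates by
#' chi-square, TSS diversity overall and within expression quartiles),
#' disease-set-versus-rest contrasts for six gene sets, and the
#' recessive-versus-middle-deciles control contrasts. The plan is
#' documented in the methods vignette; the count, not the exact membership,
#' is what fixes the threshold.
#'
#' @return data.frame, one row per planned test: `test_id`, `grouping`,
#'   `set_name`, `feature`, `test_kind`, `length_lo`, `length_hi`,
#'   `cds_exclusion`, `tpm_quartile`, `description`.
#' @export
ledgerDesigns <- function() {
    row <- function(grouping, feature, kind, set = NA, lo = NA, hi = NA,
                    cds = FALSE, q = NA, desc = "")
        data.frame(grouping = grouping, set_name = set, feature = feature,
                   test_kind = kind, length_lo = lo, length_hi = hi,
                   cds_exclusion = cds, tpm_quartile = q,
                   description = desc, stringsAsFactors = FALSE)
    W <- "wilcoxon_rank_sum"; t <- "welch_t"; X <- "chi_square"
    q <- "loeuf_extreme_quintiles"
    d <- "disease_set_vs_rest"
    m <- "dd_recessive_vs_middle_deciles"
    sets <- c("DD_dominant", "DD_recessive", "oncogene", "TSG", "HS", "TS")

    designs <- rbind(
        row(q, "utr_length", W, desc = "5'UTR length, extreme quintiles"),
        row(q, "utr_length", W, cds = TRUE,
            desc = "5'UTR length, bottom-10%-CDS-length genes removed"),
        row(q, "utr_mrna_fraction", W, desc = "5'UTR share of spliced mRNA"),
        row(q, "mfe", W, desc = "minimum free energy"),
        row(q, "mfe", W, lo = 100, hi = 300, desc = "MFE, 100-300 nt 5'UTRs"),
        row(q, "gc_fraction", W, desc = "GC content"),
        row(q, "gc_fraction", W, lo = 100, hi = 300,
            desc = "GC content, 100-300 nt 5'UTRs"),
        row(q, "mean_uorf_length_bp", W, desc = "mean predicted uORF length"),
        row(q, "closest_stop_distance", W, desc = "re-initiation distance"),
        row(q, "n_uaug", W, desc = "uAUG count per gene"),
        row(q, "mean_phylop_utr", t, desc = "PhyloP over all 5'UTR bases"),
        row(q, "mean_phylop_uorf_bounds", t,
            desc = "PhyloP over uORF start/stop codons"),
        row(q, "mean_phylop_startstop", t, desc = "PhyloP over start-stops"),
        row(q, "mean_cadd_utr", t, desc = "CADD over all 5'UTR bases"),
        row(q, "has_uorf", X, desc = "uORF prevalence"),
        row(q, "has_start_stop", X, desc = "start-stop prevalence"),
        row(q, "has_oorf", X, desc = "oORF prevalence"),
        row(q, "has_nte", X, desc = "NTE prevalence"),
        row(q, "has_intron", X, desc = "5'UTR intron prevalence"),
        row(q, "has_riboseq_uorf", X, desc = "Ribo-seq uORF prevalence"),
        row(q, "uaug_per_bp", X, desc = "uAUGs per bp, pooled rate"),
        row(q, "riboseq_canonical_fraction", X,
            desc = "canonical Ribo-seq start usage"),
        row(q, "cage_gt1", X, desc = "TSS diversity, >1 CAGE peak"),
        row(q, "cage_ge6", X, desc = "TSS diversity, >=6 CAGE peaks"))
    for (qt in 1:4) {
        designs <- rbind(designs,
            row(q, "cage_gt1", X, q = qt,
                desc = paste0(">1 CAGE peak, expression Q", qt)),
            row(q, "cage_ge6", X, q = qt,
                desc = paste0(">=6 CAGE peaks, expression Q", qt)),
            row(q, "has_riboseq_uorf", X, q = qt,
                desc = paste0("Ribo-seq uORF prevalence, expression Q", qt)))
    }
    for (s in sets) {
        designs <- rbind(designs,
            row(d, "utr_length", W, set = s,
                desc = paste(s, "5'UTR length vs rest")),
            row(d, "gc_fraction", W, set = s,
                desc = paste(s, "GC content vs rest")),
            row(d, "mean_phylop_utr", t, set = s,
                desc = paste(s, "PhyloP vs rest")),
            row(d, "has_uorf", X, set = s,
                desc = paste(s, "uORF prevalence vs rest")),
            row(d, "has_start_stop", X, set = s,
                desc = paste(s, "start-stop prevalence vs rest")),
            row(d, "has_intron", X, set = s,
                desc = paste(s, "intron prevalence vs rest")))
    }
    designs <- rbind(designs,
        row(m, "utr_length", W, desc = "DD recessive vs middle deciles: length"),
        row(m, "has_uorf", X, desc = "DD recessive vs middle deciles: uORFs"),
        row(m, "mean_phylop_utr", t,
            desc = "DD recessive vs middle deciles: PhyloP"),
        row(m, "has_intron", X,
            desc = "DD recessive vs middle deciles: introns"),
        row(m, "gc_fraction", W,
            desc = "DD recessive vs middle deciles: GC content"))
    designs$test_id <- sprintf("T%02d", seq_len(nrow(designs)))
    designs[c("test_id", setdiff(names(designs), "test_id"))]
}

#' Run the planned test ledger over a cohort
#'
#' Executes every planned comparison and flags each result against the
#' study-wide Bonferroni threshold `alpha / nrow(designs)` (the ledger size
#' is the count of *planned* tests). Designs referencing an unknown feature
#' fail before any test runs; an empty design list is an error, not an empty
#' report. p-values below 1e-15 are rendered `"<1e-15"` in `p_text` while
#' the numeric value is retained.
#'
#' @param features cohort feature table from [buildFeatureTable()].
#' @param meta stratified metadata from [assignStrata()] (must include
#'   `cds_length` when any design uses the CDS-length exclusion, and
#'   `cage_peaks` / `tpm_quartile` for the TSS and expression designs).
#' @param designs planned tests (default [ledgerDesigns()]).
#' @param alpha study-wide significance level.
#' @return data.frame of [compareContinuous()] / [compareProportions()] rows
#'   joined to their designs, with `p_text` and `significant_at_ledger`;
#'   `attr(, "threshold")` holds the Bonferroni threshold.
#' @export
runLedger <- function(features, meta, designs = ledgerDesigns(),
                      alpha = 0.05) {
    if (is.null(designs) || nrow(designs) == 0L)
        stop("runLedger: empty design list")
    known <- c(names(features), .PROP_FEATURES, .POOLED_FEATURES)
    bad <- setdiff(designs$feature, known)
    if (length(bad))
        stop("runLedger: unknown feature(s) in designs: ",
             paste(bad, collapse = ", "))
    if (!all(designs$grouping %in% .LEDGER_GROUPINGS))
        stop("runLedger: unknown grouping in designs")

    threshold <- alpha / nrow(designs)
    dat <- merge(features, meta, by = "gene_id", all.x = TRUE)

    rows <- lapply(seq_len(nrow(designs)), function(i)
        .runOneDesign(dat, designs[i, , drop = FALSE]))
    out <- cbind(designs, do.call(rbind, rows))
    out$significant_at_ledger <- !is.na(out$p_value) &
        out$p_value < threshold
    out$p_text <- ifelse(is.na(out$p_value), NA_character_,
                         ifelse(out$p_value < 1e-15, "<1e-15",
                                formatC(out$p_value, format = "g",
                                        digits = 3)))
    attr(out, "threshold") <- threshold
    out
}

.emptyResult <- function(kind, note) {
    data.frame(test_kind = kind, statistic = NA_real_, p_value = NA_real_,
               n_a = 0L, n_b = 0L, mean_a = NA_real_, mean_b = NA_real_,
               median_a = NA_real_, median_b = NA_real_, prop_a = NA_real_,
               prop_b = NA_real_, low_expected = NA, note = note)
}

.padResult <- function(r, note = NA_character_) {
    for (col in c("mean_a", "mean_b", "median_a", "median_b",
                  "prop_a", "prop_b"))
        if (!col %in% names(r)) r[[col]] <- NA_real_
    if (!"low_expected" %in% names(r)) r$low_expected <- NA
    r$note <- note
    r[c("test_kind", "statistic", "p_value", "n_a", "n_b", "mean_a",
        "mean_b", "median_a", "median_b", "prop_a", "prop_b",
        "low_expected", "note")]
}

.runOneDesign <- function(dat, design) {
    # filters compose and commute: each is a row predicate, with the
    # bottom-10%-CDS-length cutoff anchored to the full cohort
    if (isTRUE(design$cds_exclusion)) {
        if (!"cds_length" %in% names(dat))
            stop("design ", design$test_id,
                 " needs a cds_length column in meta")
        cut10 <- stats::quantile(dat$cds_length, 0.10, na.rm = TRUE,
                                 names = FALSE)
        dat <- dat[!is.na(dat$cds_length) & dat$cds_length > cut10, ,
                   drop = FALSE]
    }
    if (!is.na(design$length_lo))
        dat <- lengthRestrictedView(dat, design$length_lo, design$length_hi)
    if (!is.na(design$tpm_quartile))
        dat <- dat[!is.na(dat$tpm_quartile) &
                   dat$tpm_quartile == design$tpm_quartile, , drop = FALSE]

    grp <- design$grouping
    if (grp == "loeuf_extreme_quintiles") {
        selA <- !is.na(dat$loeuf_quintile_group) &
            dat$loeuf_quintile_group == "intolerant"
        selB <- !is.na(dat$loeuf_quintile_group) &
            dat$loeuf_quintile_group == "tolerant"
    } else if (grp == "disease_set_vs_rest") {
        flag <- dat[[design$set_name]]
        selA <- !is.na(flag) & flag
        selB <- !selA          # full cohort with the set removed
    } else {                   # dd_recessive_vs_middle_deciles
        selA <- !is.na(dat$DD_recessive) & dat$DD_recessive
        selB <- !selA & !is.na(dat$loeuf_decile) & dat$loeuf_decile %in% 5:6
    }
    if (!any(selA) || !any(selB))
        return(.emptyResult(design$test_kind, "empty_group"))

    f <- design$feature
    tryCatch({
        if (f %in% .PROP_FEATURES) {
            va <- .propVector(dat[selA, , drop = FALSE], f)
            vb <- .propVector(dat[selB, , drop = FALSE], f)
            .padResult(compareProportions(sum(va, na.rm = TRUE),
                                          sum(!is.na(va)),
                                          sum(vb, na.rm = TRUE),
                                          sum(!is.na(vb))))
        } else if (f == "uaug_per_bp") {
            # pooled rate: uAUG-start positions vs all 5'UTR positions
            .padResult(compareProportions(
                sum(dat$n_uaug[selA]), sum(dat$utr_length[selA]),
                sum(dat$n_uaug[selB]), sum(dat$utr_length[selB])))
        } else if (f == "riboseq_canonical_fraction") {
            .padResult(compareProportions(
                sum(dat$n_riboseq_canonical[selA], na.rm = TRUE),
                sum(dat$n_riboseq_uorf[selA], na.rm = TRUE),
                sum(dat$n_riboseq_canonical[selB], na.rm = TRUE),
                sum(dat$n_riboseq_uorf[selB], na.rm = TRUE)))
        } else {
            .padResult(compareContinuous(dat[[f]][selA], dat[[f]][selB],
                                         design$test_kind))
        }
    }, error = function(e)
        .emptyResult(design$test_kind, conditionMessage(e)))
}

.propVector <- function(d, feature) {
    switch(feature,
        has_uorf = d$has_uorf,
        has_oorf = d$has_oorf,
        has_nte = d$n_nte > 0L,
        has_start_stop = d$has_start_stop,
        has_intron = d$intron_count > 0L,
        has_riboseq_uorf = ifelse(is.na(d$n_riboseq_uorf), NA,
                                  d$n_riboseq_uorf > 0L),
        cage_gt1 = ifelse(is.na(d$cage_peaks), NA, d$cage_peaks > 1L),
        cage_ge6 = ifelse(is.na(d$cage_peaks), NA, d$cage_peaks >= 6L),
        stop("unknown proportion feature ", feature))
}
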