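#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- isTRUEorFALSE
#' @importFrom GenomicRanges GRanges granges countOverlaps findOverlaps pintersect
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
NULL

REG_CATEGORIES <- c("transcriptional", "balanced", "post_transcriptional")
PEAK_SOURCES <- c("atac", "pop")

#' PeakSet: a set of called peaks from one assay
#'
#' A `PeakSet` is a [GenomicRanges::GRanges] of called peaks from a single
#' assay, tagged with its source: `"atac"` for chromatin-accessibility peaks
#' (ATAC-seq, typically MACS narrowPeak output) or `"pop"` for RNA-protein
#' occupancy peaks (POP-seq, typically Piranha BED output). Metadata columns
#' carry, when available, `name`, `score`, `signalValue`, `pValue` and
#' `qValue` (both on the linear scale, in (0, 1]) and the narrowPeak summit
#' offset `peak`.
#'
#' @slot peakSource single string, `"atac"` or `"pop"`.
#' @seealso [readNarrowPeak()], [readPeakBed()], [filterSignificant()]
#' @exportClass PeakSet
setClass("PeakSet",
    contains = "GRanges",
    representation(peakSource = "character")
)

setValidity("PeakSet", function(object) {
    msg <- NULL
    if (length(object@peakSource) != 1L || !object@peakSource %in% PEAK_SOURCES)
        msg <- c(msg, sprintf("peakSource must be one of %s",
                              paste(dQuote(PEAK_SOURCES, q = FALSE), collapse = ", ")))
    mc <- mcols(object)
    for (col in c("pValue", "qValue")) {
        if (col %in% colnames(mc)) {
            v <- mc[[col]]
            bad <- !is.na(v) & (v <= 0 | v > 1)
            if (any(bad))
                msg <- c(msg, sprintf("%s must lie in (0, 1]; first offending record: %d",
                                      col, which(bad)[1L]))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a PeakSet from a GRanges
#'
#' @param gr a `GRanges` of peak intervals.
#' @param source `"atac"` or `"pop"`.
#' @return A [PeakSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), qValue = 0.01)
#' PeakSet(gr, source = "atac")
#' @export
PeakSet <- function(gr, source = c("atac", "pop")) {
    source <- match.arg(source)
    new("PeakSet", gr, peakSource = source)
}

#' @describeIn PeakSet-class the assay the peaks came from (`"atac"` or `"pop"`).
#' @param x a `PeakSet`.
#' @export
peakSource <- function(x) {
    stopifnot(is(x, "PeakSet"))
    x@peakSource
}

setMethod("show", "PeakSet", function(object) {
    cat(sprintf("PeakSet of %d %s peak(s)\n", length(object),
                toupper(object@peakSource)))
    callNextMethod()
})

#' RegulationProfiles: per-gene regulation-ratio results
#'
#' Container for the per-gene output of [buildProfiles()]: significant peak
#' counts in the relevant windows, peak densities (peaks per kb), the
#' Regulation Ratio RR = pop_count / atac_count, its log2, and the three-way
#' regulatory classification. Genes lacking a peak in either assay fail the
#' filter and have `NA` ratio and category.
#'
#' @slot table a `DataFrame`, one row per gene, with columns `gene_id`,
#'   `length_bp`, `atac_count`, `pop_count`, `td` (transcriptional density,
#'   significant ATAC peaks per kb of gene), `ptd` (post-transcriptional
#'   density, significant POP peaks per kb), `rr`, `log2_rr`, `category`
#'   (factor over transcriptional/balanced/post_transcriptional) and
#'   `passes_filter`, plus any gene covariates that were attached to the
#'   annotation (`isoform_count`, `fpkm`, `protein_expr`, `biotypes`).
#' @slot params list of the window and counting parameters used.
#' @seealso [buildProfiles()], [profileTable()], [densityCorrelation()]
#' @exportClass RegulationProfiles
setClass("RegulationProfiles",
    representation(table = "DataFrame", params = "list")
)

setValidity("RegulationProfiles", function(object) {
    tab <- object@table
    need <- c("gene_id", "length_bp", "atac_count", "pop_count", "td", "ptd",
              "rr", "log2_rr", "category", "passes_filter")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        return(sprintf("missing profile column(s): %s", paste(miss, collapse = ", ")))
    if (anyDuplicated(tab$gene_id))
        return("gene_id values must be unique")
    pf <- tab$atac_count >= 1L & tab$pop_count >= 1L
    if (!identical(unname(as.logical(tab$passes_filter)), unname(as.logical(pf))))
        return("passes_filter must equal (atac_count >= 1 & pop_count >= 1)")
    ok <- which(tab$passes_filter)
    if (length(ok)) {
        if (any(tab$rr[ok] != tab$pop_count[ok] / tab$atac_count[ok]))
            return("rr must equal pop_count / atac_count exactly for passing genes")
        expected <- ifelse(tab$pop_count[ok] > tab$atac_count[ok], "post_transcriptional",
                    ifelse(tab$pop_count[ok] < tab$atac_count[ok], "transcriptional",
                           "balanced"))
        if (!identical(unname(as.character(tab$category[ok])), unname(expected)))
            return("category inconsistent with the RR > 1 / = 1 / < 1 rule")
    }
    if (any(!is.na(tab$category[!pf])))
        return("failing genes must have NA category")
    TRUE
})

setMethod("show", "RegulationProfiles", function(object) {
    s <- runSummary(object)
    cat(sprintf("RegulationProfiles: %d gene(s), %d passing the >=1 peak/assay filter (%.1f%%)\n",
                s$n_genes, s$n_passing, 100 * s$n_passing / max(1L, s$n_genes)))
    if (s$n_passing > 0) {
        pct <- 100 * s$category_counts / s$n_passing
        cat(sprintf("  RR < 1 (transcriptional):        %6d  (%.1f%%)\n",
                    s$category_counts[["transcriptional"]], pct[["transcriptional"]]))
        cat(sprintf("  RR = 1 (balanced):               %6d  (%.1f%%)\n",
                    s$category_counts[["balanced"]], pct[["balanced"]]))
        cat(sprintf("  RR > 1 (post_transcriptional):   %6d  (%.1f%%)\n",
                    s$category_counts[["post_transcriptional"]], pct[["post_transcriptional"]]))
    }
    p <- object@params
    if (length(p))
        cat(sprintf("  windows: %d bp upstream / %d bp downstream (%s), min overlap %d bp\n",
                    p$upstream, p$downstream,
                    if (isTRUE(p$stranded)) "strand-aware" else "unstranded",
                    p$min_overlap))
    invisible(NULL)
})

#' CategoryComparison: one covariate contrasted across regulatory categories
#'
#' Result of [compareCovariate()]: a Kruskal-Wallis test across the populated
#' regulatory categories followed by pairwise Mann-Whitney U tests with
#' Bonferroni correction, Cliff's delta effect sizes, per-category medians and
#' median fold changes.
#'
#' @slot covariate name of the covariate compared.
#' @slot kw list with elements `h` and `p` from the Kruskal-Wallis test.
#' @slot pairwise `DataFrame` with one row per category pair: `group1`,
#'   `group2`, `u` (U statistic of group1 over group2), `p_raw`,
#'   `p_bonferroni`, `cliffs_delta`, `median_fold_change`.
#' @slot medians named numeric, per-category medians.
#' @slot nExcluded genes dropped for missing covariate values.
#' @exportClass CategoryComparison
setClass("CategoryComparison",
    representation(covariate = "character", kw = "list", pairwise = "DataFrame",
                   medians = "numeric", nExcluded = "integer")
)

setValidity("CategoryComparison", function(object) {
    pw <- object@pairwise
    if (nrow(pw)) {
        if (any(!is.na(pw$cliffs_delta) & abs(pw$cliffs_delta) > 1))
            return("cliffs_delta must lie in [-1, 1]")
        ok <- !is.na(pw$p_raw)
        if (any(abs(pw$p_bonferroni[ok] - pmin(1, nrow(pw) * pw$p_raw[ok])) > 1e-12))
            return("p_bonferroni must equal min(1, m * p_raw)")
    }
    TRUE
})

setMethod("show", "CategoryComparison", function(object) {
    cat(sprintf("CategoryComparison of %s across regulatory categories\n", object@covariate))
    cat(sprintf("  Kruskal-Wallis: H = %.4g, p = %.3g\n", object@kw$h, object@kw$p))
    cat(sprintf("  medians: %s\n",
                paste(sprintf("%s = %.4g", names(object@medians), object@medians),
                      collapse = ", ")))
    if (object@nExcluded > 0)
        cat(sprintf("  (%d gene(s) excluded for missing values)\n", object@nExcluded))
    print(as.data.frame(object@pairwise), row.names = FALSE)
    invisible(NULL)
})

#' AgreementSummary: classification concordance across samples
#'
#' Result of [agreementBreakdown()] over 2 or 3 samples: every gene passing
#' the RR filter in all samples is assigned to exactly one agreement class --
#' `full` (identical category everywhere), one exactly-one-pair-agrees class
#' per sample pair (3-sample case only), or `none`. Class percentages
#' partition 100%.
#'
#' @slot samples ordered sample names.
#' @slot commonGenes number of genes passing the filter in every sample.
#' @slot classes `DataFrame` with columns `class`, `n`, `pct`.
#' @slot perGene `DataFrame`: `gene_id`, one category column per sample,
#'   and the assigned `agreement_class`.
#' @exportClass AgreementSummary
setClass("AgreementSummary",
    representation(samples = "character", commonGenes = "integer",
                   classes = "DataFrame", perGene = "DataFrame")
)

setValidity("AgreementSummary", function(object) {
    if (object@commonGenes > 0 && abs(sum(object@classes$pct) - 100) > 0.01)
        return("agreement class percentages must sum to 100")
    if (sum(object@classes$n) != object@commonGenes)
        return("agreement class counts must sum to the common gene count")
    TRUE
})

setMethod("show", "AgreementSummary", function(object) {
    cat(sprintf("AgreementSummary over %d sample(s): %s\n",
                length(object@samples), paste(object@samples, collapse = ", ")))
    cat(sprintf("  %d gene(s) pass the filter in every sample\n", object@commonGenes))
    print(as.data.frame(object@classes), row.names = FALSE)
    invisible(NULL)
})
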