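#' Per-kb peak densities
#'
#' The two per-gene density metrics underlying the Regulation Ratio:
#' `transcriptionalDensity` is the number of significant ATAC-seq peaks in
#' the promoter-expanded gene window per kb of gene length, and
#' `posttranscriptionalDensity` is the number of significant POP-seq peaks in
#' the gene body per kb of gene length. Both normalise by the *gene* length,
#' so the ratio of the two densities reduces exactly to the ratio of the two
#' peak counts.
#'
#' @param atac_count,pop_count nonnegative integer peak counts.
#' @param length_bp gene length in bp (>= 1).
#' @return Peaks per kb.
#' @examples
#' transcriptionalDensity(4, 2000)     # 2 peaks/kb
#' posttranscriptionalDensity(6, 3000) # 2 peaks/kb
#' @export
transcriptionalDensity <- function(atac_count, length_bp) {
    stopifnot(all(length_bp >= 1), all(atac_count >= 0))
    atac_count * 1000 / length_bp
}

#' @rdname transcriptionalDensity
#' @export
posttranscriptionalDensity <- function(pop_count, length_bp) {
    stopifnot(all(length_bp >= 1), all(pop_count >= 0))
    pop_count * 1000 / length_bp
}

#' Regulation Ratio
#'
#' RR = (significant POP-seq peaks) / (significant ATAC-seq peaks) for a gene
#' carrying at least one peak of each kind. Because both density metrics
#' normalise by the same gene length, this equals the ratio of the
#' post-transcriptional to the transcriptional density. Genes with a zero
#' count in either assay fail the filter and must be excluded by the caller.
#'
#' @param pop_count,atac_count integer peak counts, both >= 1.
#' @return RR as a numeric; exact ratio of the two integers.
#' @examples
#' regulationRatio(4, 2)  # 2: post-transcriptionally dominated
#' regulationRatio(3, 3)  # 1: balanced
#' @export
regulationRatio <- function(pop_count, atac_count) {
    if (any(pop_count < 1) || any(atac_count < 1))
        stop("gene fails the regulation filter: both assays must have >= 1 ",
             "significant peak; exclude genes with a zero count")
    pop_count / atac_count
}

#' Three-way regulatory classification
#'
#' RR > 1: predominantly post-transcriptionally regulated; RR = 1: balanced;
#' RR < 1: predominantly transcriptionally regulated. To avoid floating-point
#' misclassification at the boundary, pass the integer counts when available:
#' balance is then decided by exact count equality.
#'
#' @param rr Regulation Ratio values (> 0).
#' @param pop_count,atac_count optional integer counts; when given, the
#'   RR = 1 case is decided by `pop_count == atac_count` exactly.
#' @return Factor with levels transcriptional, balanced, post_transcriptional.
#' @export
classifyRR <- function(rr, pop_count = NULL, atac_count = NULL) {
    stopifnot(all(rr > 0, na.rm = TRUE))
    if (!is.null(pop_count) && !is.null(atac_count)) {
        out <- ifelse(pop_count > atac_count, "post_transcriptional",
               ifelse(pop_count < atac_count, "transcriptional", "balanced"))
    } else {
        out <- ifelse(rr > 1, "post_transcriptional",
               ifelse(rr < 1, "transcriptional", "balanced"))
    }
    factor(out, levels = REG_CATEGORIES)
}

#' Build per-gene regulation profiles
#'
#' The core pipeline step: counts significant ATAC-seq peaks in each gene's
#' promoter-expanded window and significant POP-seq peaks in each gene body,
#' computes both per-kb densities, and -- for genes carrying at least one
#' peak of each kind -- the Regulation Ratio, its log2, and the three-way
#' classification. Peak sets are expected to be significance-filtered
#' already (see [filterSignificant()]); a warning is raised if sources are
#' swapped.
#'
#' @param genes gene `GRanges` from [loadGeneAnnotation()].
#' @param atac a [PeakSet-class] with source `"atac"`.
#' @param pop a [PeakSet-class] with source `"pop"`.
#' @param upstream,downstream,stranded window parameters, see
#'   [expandWindows()].
#' @param minOverlap minimum peak/window intersection in bp.
#' @return A [RegulationProfiles-class]; row order follows annotation order.
#' @export
buildProfiles <- function(genes, atac, pop, upstream = 5000L, downstream = 500L,
                          stranded = TRUE, minOverlap = 1L) {
    if (length(genes) == 0L)
        stop("empty gene set")
    stopifnot(is(atac, "PeakSet"), is(pop, "PeakSet"))
    if (peakSource(atac) != "atac" || peakSource(pop) != "pop")
        warning("peak set sources do not match the atac/pop argument order")
    ew <- expandWindows(genes, upstream = upstream, downstream = downstream,
                        stranded = stranded)
    bw <- bodyWindows(genes)
    atac_count <- countOverlappingPeaks(atac, ew, minOverlap = minOverlap)
    pop_count <- countOverlappingPeaks(pop, bw, minOverlap = minOverlap)
    length_bp <- BiocGenerics::width(genes)
    passes <- atac_count >= 1L & pop_count >= 1L
    rr <- ifelse(passes, pop_count / atac_count, NA_real_)
    category <- factor(rep(NA_character_, length(genes)), levels = REG_CATEGORIES)
    category[passes] <- classifyRR(rr[passes], pop_count[passes], atac_count[passes])
    tab <- DataFrame(
        gene_id = genes$gene_id,
        length_bp = length_bp,
        atac_count = unname(atac_count),
        pop_count = unname(pop_count),
        td = transcriptionalDensity(unname(atac_count), length_bp),
        ptd = posttranscriptionalDensity(unname(pop_count), length_bp),
        rr = unname(rr),
        log2_rr = log2(unname(rr)),
        category = category,
        passes_filter = unname(passes)
    )
    for (cov in c("isoform_count", "fpkm", "protein_expr", "biotypes"))
        if (cov %in% colnames(mcols(genes)))
            tab[[cov]] <- mcols(genes)[[cov]]
    new("RegulationProfiles", table = tab,
        params = list(upstream = as.integer(upstream),
                      downstream = as.integer(downstream),
                      stranded = isTRUE(stranded),
                      min_overlap = as.integer(minOverlap)))
}

#' Correlation between the two regulatory densities
#'
#' Pearson correlation of log10 transcriptional density versus log10
#' post-transcriptional density over genes passing the filter (both
#' densities strictly positive there). The squared correlation is the
#' comparable headline quantity; the sign of any axis flip used for plotting
#' does not affect it.
#'
#' @param profiles a [RegulationProfiles-class].
#' @return A list with `pearson_r`, `r_squared` and `n`. When either axis is
#'   constant the correlation is undefined and reported as `NA` with a
#'   warning.
#' @export
densityCorrelation <- function(profiles) {
    stopifnot(is(profiles, "RegulationProfiles"))
    tab <- passingProfiles(profiles)
    if (nrow(tab) < 3L)
        stop("need >= 3 passing genes to compute a correlation")
    x <- log10(tab$td)
    y <- log10(tab$ptd)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero variance in a density axis; correlation undefined")
        return(list(pearson_r = NA_real_, r_squared = NA_real_, n = nrow(tab)))
    }
    r <- stats::cor(x, y, method = "pearson")
    list(pearson_r = r, r_squared = r^2, n = nrow(tab))
}

#' Write / read the per-gene profile table
#'
#' Serialises a [RegulationProfiles-class] to the pipeline's primary TSV
#' output (one row per gene, annotation order) and reads it back.
#'
#' @param profiles a [RegulationProfiles-class].
#' @param path TSV path.
#' @return `writeProfiles` returns `path` invisibly; `readProfiles` the
#'   reconstructed object (window parameters are not stored in the TSV and
#'   come back empty).
#' @export
writeProfiles <- function(profiles, path) {
    tab <- profiles@table
    df <- as.data.frame(tab[, setdiff(colnames(tab), "biotypes")])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = c(gene_id = "character"))
    tab <- DataFrame(df)
    tab$category <- factor(df$category, levels = REG_CATEGORIES)
    tab$passes_filter <- as.logical(df$passes_filter)
    # derived columns are recomputed from the integer counts so that the
    # exact rational identities survive the text round-trip
    tab$td <- transcriptionalDensity(tab$atac_count, tab$length_bp)
    tab$ptd <- posttranscriptionalDensity(tab$pop_count, tab$length_bp)
    tab$rr <- ifelse(tab$passes_filter, tab$pop_count / tab$atac_count, NA_real_)
    tab$log2_rr <- log2(tab$rr)
    new("RegulationProfiles", table = tab, params = list())
}
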