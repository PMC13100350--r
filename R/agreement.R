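#' Genes passing the filter in every sample
#'
#' @param profileList a list of >= 2 [RegulationProfiles-class] objects, one
#'   per sample or cell line.
#' @return Character vector of gene_ids passing the at-least-one-peak-per-
#'   assay filter in every sample, in the order of the first sample.
#' @export
intersectPassing <- function(profileList) {
    stopifnot(is.list(profileList), length(profileList) >= 2L)
    ids <- lapply(profileList, function(p) {
        stopifnot(is(p, "RegulationProfiles"))
        passingProfiles(p)$gene_id
    })
    Reduce(intersect, ids)
}

#' Cross-sample classification agreement breakdown
#'
#' Assigns every gene passing the RR filter in all samples to exactly one
#' agreement class: `full` when its regulatory category is identical in
#' every sample; for three samples, one exactly-one-pair-agrees class per
#' sample pair (the third sample differs); and `none` when no two samples
#' agree. These classes partition the common gene set, so the percentages
#' sum to 100. More than three samples are not supported: with four or more,
#' two disjoint pairs can agree simultaneously and the single-pair classes
#' no longer partition.
#'
#' @param profileList a list of 2 or 3 [RegulationProfiles-class] objects.
#' @param sampleNames names for the samples; defaults to the list names or
#'   `sample1..k`.
#' @return An [AgreementSummary-class].
#' @export
agreementBreakdown <- function(profileList, sampleNames = NULL) {
    stopifnot(is.list(profileList))
    k <- length(profileList)
    if (k < 2L || k > 3L)
        stop("agreement breakdown is defined for 2 or 3 samples, got ", k)
    if (is.null(sampleNames))
        sampleNames <- if (!is.null(names(profileList))) names(profileList)
                       else paste0("sample", seq_len(k))
    stopifnot(length(sampleNames) == k)
    common <- intersectPassing(profileList)
    if (length(common) == 0L)
        stop("no genes pass the filter in every sample")
    cats <- vapply(profileList, function(p) {
        tab <- profileTable(p)
        as.character(tab$category)[match(common, tab$gene_id)]
    }, character(length(common)))
    cats <- matrix(cats, nrow = length(common))
    class_names <- c("full",
                     if (k == 3L) apply(utils::combn(sampleNames, 2L), 2L,
                                        paste, collapse = "+"),
                     "none")
    assign_class <- function(v) {
        if (all(v == v[1L])) return("full")
        if (k == 2L) return("none")
        pairs <- utils::combn(k, 2L)
        agree <- pairs[, v[pairs[1L, ]] == v[pairs[2L, ]], drop = FALSE]
        if (ncol(agree) == 0L) return("none")
        # at most one pair can agree when not all three do
        paste(sampleNames[agree[, 1L]], collapse = "+")
    }
    cls <- apply(cats, 1L, assign_class)
    n <- vapply(class_names, function(cn) sum(cls == cn), integer(1))
    classes <- DataFrame(class = class_names, n = unname(n),
                         pct = unname(100 * n / length(common)))
    per_gene <- DataFrame(gene_id = common)
    for (i in seq_len(k)) per_gene[[sampleNames[i]]] <- cats[, i]
    per_gene$agreement_class <- cls
    new("AgreementSummary", samples = sampleNames,
        commonGenes = length(common), classes = classes, perGene = per_gene)
}

#' Write agreement results
#'
#' Writes the class-percentage summary and the per-gene category vectors as
#' two TSVs.
#'
#' @param agreement an [AgreementSummary-class].
#' @param summaryPath,perGenePath output paths.
#' @return `summaryPath`, invisibly.
#' @export
writeAgreement <- function(agreement, summaryPath, perGenePath = NULL) {
    utils::write.table(as.data.frame(agreement@classes), summaryPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(perGenePath))
        utils::write.table(as.data.frame(agreement@perGene), perGenePath,
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(summaryPath)
}
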