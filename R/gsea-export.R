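#' Export a GSEA pre-ranked list of log2 Regulation Ratios
#'
#' Writes the genes passing the RR filter as a two-column, headerless .rnk
#' file (gene identifier, log2 RR) sorted by score in descending order with
#' ties broken by gene_id in lexicographic order -- the input format of
#' GSEA's pre-ranked mode. The identifier column carries whatever the
#' annotation provided; an optional two-column mapping table (TSV with
#' header: source id, target id) translates identifiers, e.g. Ensembl gene
#' ids to the gene symbols GSEA's gene sets use. Running GSEA itself is out
#' of scope -- this is its input.
#'
#' @param profiles a [RegulationProfiles-class].
#' @param path output .rnk path.
#' @param idMap optional path to an id-mapping TSV; genes without a mapping
#'   are dropped with a warning.
#' @return Invisibly, a data.frame of the written (gene_id, score) pairs in
#'   file order.
#' @export
exportRnk <- function(profiles, path, idMap = NULL) {
    stopifnot(is(profiles, "RegulationProfiles"))
    tab <- passingProfiles(profiles)
    if (nrow(tab) == 0L)
        stop("no passing genes to rank")
    ids <- tab$gene_id
    scores <- tab$log2_rr
    if (!is.null(idMap)) {
        map <- utils::read.delim(idMap, header = TRUE, sep = "\t",
                                 colClasses = "character")
        idx <- match(ids, map[[1L]])
        if (anyNA(idx))
            warning(sum(is.na(idx)), " gene(s) without an id mapping dropped")
        keep <- !is.na(idx)
        ids <- map[[2L]][idx[keep]]
        scores <- scores[keep]
    }
    if (anyDuplicated(ids))
        stop("duplicate gene identifier in ranked list: ",
             ids[duplicated(ids)][1L])
    ord <- order(-scores, ids, method = "radix")
    out <- data.frame(gene_id = ids[ord], score = scores[ord],
                      stringsAsFactors = FALSE)
    writeLines(sprintf("%s\t%.6f", out$gene_id, out$score), path)
    invisible(out)
}

#' Read a .rnk file
#'
#' @param path a two-column, headerless tab-separated ranked list.
#' @return data.frame with `gene_id` and `score`.
#' @export
readRnk <- function(path) {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            colClasses = c("character", "numeric"))
    names(df) <- c("gene_id", "score")
    df
}
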