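#' @rdname RegulationProfiles-class
#' @param x a `RegulationProfiles` object.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname RegulationProfiles-class
#' @export
setGeneric("passingProfiles", function(x) standardGeneric("passingProfiles"))

#' @rdname RegulationProfiles-class
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname RegulationProfiles-class
#' @export
setGeneric("runSummary", function(x) standardGeneric("runSummary"))

#' @describeIn RegulationProfiles-class the full per-gene table (`DataFrame`).
setMethod("profileTable", "RegulationProfiles", function(x) x@table)

#' @describeIn RegulationProfiles-class rows for genes passing the
#'   at-least-one-peak-per-assay filter.
setMethod("passingProfiles", "RegulationProfiles", function(x) {
    x@table[x@table$passes_filter, , drop = FALSE]
})

#' @describeIn RegulationProfiles-class named integer vector of passing genes
#'   per regulatory category.
setMethod("categoryCounts", "RegulationProfiles", function(x) {
    tab <- table(factor(x@table$category[x@table$passes_filter],
                        levels = REG_CATEGORIES))
    stats::setNames(as.integer(tab), names(tab))
})

#' @describeIn RegulationProfiles-class run summary: total genes, passing
#'   genes, and per-category counts.
setMethod("runSummary", "RegulationProfiles", function(x) {
    list(n_genes = nrow(x@table),
         n_passing = sum(x@table$passes_filter),
         category_counts = categoryCounts(x),
         params = x@params)
})
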