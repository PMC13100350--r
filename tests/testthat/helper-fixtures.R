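# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

library(GenomicRanges)
library(S4Vectors)

# Genes at well-separated positions on one chromosome, with atac peaks in the
# gene body (hence also in any expanded window) and pop peaks in the body.
# Lets tests dial in exact per-gene (atac_count, pop_count, length) triples.
mkDataset <- function(atac_counts, pop_counts, lengths,
                      chrom = "chr1", gap = 50000L) {
    n <- length(lengths)
    stopifnot(length(atac_counts) == n, length(pop_counts) == n)
    starts <- cumsum(c(10000L, head(lengths, -1) + gap))
    genes <- GRanges(chrom, IRanges(starts, width = lengths), strand = "+",
                     gene_id = paste0("G", seq_len(n)))
    place <- function(counts, width) {
        idx <- rep(seq_len(n), counts)
        if (length(idx) == 0L)
            return(GRanges())
        offset <- unlist(lapply(counts, function(k) seq_len(k)), use.names = FALSE)
        GRanges(chrom, IRanges(starts[idx] + (offset - 1L) * (width + 2L),
                               width = width))
    }
    list(genes = genes,
         atac = PeakSet(place(atac_counts, 20L), source = "atac"),
         pop = PeakSet(place(pop_counts, 5L), source = "pop"))
}

# A RegulationProfiles with prescribed categories (and optional biotypes),
# built through counts so the class invariants hold by construction.
mkProfFromCategories <- function(gene_ids, categories, biotypes = NULL,
                                 length_bp = 1000L) {
    counts <- list(transcriptional = c(atac = 2L, pop = 1L),
                   balanced = c(atac = 1L, pop = 1L),
                   post_transcriptional = c(atac = 1L, pop = 2L),
                   fail = c(atac = 0L, pop = 3L))
    atac <- unname(vapply(categories, function(cc) counts[[cc]][["atac"]], integer(1)))
    pop <- unname(vapply(categories, function(cc) counts[[cc]][["pop"]], integer(1)))
    passes <- atac >= 1L & pop >= 1L
    rr <- ifelse(passes, pop / atac, NA_real_)
    category <- unname(ifelse(!passes, NA_character_,
                ifelse(pop > atac, "post_transcriptional",
                ifelse(pop < atac, "transcriptional", "balanced"))))
    tab <- DataFrame(
        gene_id = gene_ids,
        length_bp = rep(as.integer(length_bp), length(gene_ids)),
        atac_count = atac, pop_count = pop,
        td = atac * 1000 / length_bp, ptd = pop * 1000 / length_bp,
        rr = rr, log2_rr = log2(rr),
        category = factor(category, levels = c("transcriptional", "balanced",
                                               "post_transcriptional")),
        passes_filter = passes)
    if (!is.null(biotypes))
        tab$biotypes <- IRanges::CharacterList(biotypes)
    new("RegulationProfiles", table = tab, params = list())
}

# O(n*m) per-pair intersection oracle for overlap counting, on plain vectors
# (1-based closed coordinates, matching the GRanges the package builds).
bruteOverlapCount <- function(wchrom, wstart, wend, pchrom, pstart, pend,
                              min_overlap = 1L) {
    vapply(seq_along(wstart), function(i) {
        same <- pchrom == wchrom[i]
        ov <- pmin(pend[same], wend[i]) - pmax(pstart[same], wstart[i]) + 1L
        sum(ov >= min_overlap)
    }, integer(1))
}

# Exact Mann-Whitney oracle: U by direct pair comparison and p by full
# enumeration of group assignments, independent of the midrank route the
# package uses.
bruteMWU <- function(x, y, alternative = "two.sided") {
    u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    u <- u_of(x, y)
    v <- c(x, y)
    n1 <- length(x)
    sel <- utils::combn(length(v), n1)
    u_all <- apply(sel, 2L, function(s) u_of(v[s], v[-s]))
    mu <- n1 * length(y) / 2
    eps <- 1e-9
    p <- switch(alternative,
        two.sided = mean(abs(u_all - mu) >= abs(u - mu) - eps),
        greater = mean(u_all >= u - eps),
        less = mean(u_all <= u + eps))
    list(u = u, p = p)
}

# Two-sided Fisher oracle by hypergeometric tail summation over all tables
# with the observed margins.
bruteFisherP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0L, k - n); hi <- min(k, m)
    support <- lo:hi
    dens <- stats::dhyper(support, m, n, k)
    sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Textbook covariance-formula Pearson correlation.
brutePearson <- function(x, y) {
    n <- length(x)
    sxy <- sum(x * y) - sum(x) * sum(y) / n
    sxx <- sum(x^2) - sum(x)^2 / n
    syy <- sum(y^2) - sum(y)^2 / n
    sxy / sqrt(sxx * syy)
}

readSigToyPeaks <- function() {
    atac <- filterSignificant(
        readNarrowPeak(system.file("extdata", "toy_atac.narrowPeak",
                                   package = "RegRatio"), "atac"),
        method = "qvalue")
    pop <- filterSignificant(
        readPeakBed(system.file("extdata", "toy_pop.bed", package = "RegRatio"),
                    "pop", pvalue_col = 7),
        method = "bh")
    list(atac = atac, pop = pop)
}
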