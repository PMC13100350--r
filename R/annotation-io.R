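#' Load gene models from a GTF file
#'
#' Reads an Ensembl-dialect GTF, keeps `gene` features as the gene universe,
#' and aggregates `transcript` children into a per-gene multiset of transcript
#' biotypes (attribute `transcript_biotype`, with `transcript_type` accepted
#' as a synonym) and an isoform count. Optional two-column covariate tables
#' (TSV with header, columns `gene_id` and `value`) attach isoform counts,
#' transcript abundance (FPKM) and protein expression; covariate rows whose
#' gene_id is absent from the annotation are dropped with a warning, and a
#' supplied isoform table overrides the GTF-derived transcript count.
#'
#' Genes without strand annotation are treated as `+` strand with a warning,
#' so that the promoter-expanded window of [expandWindows()] is well defined.
#'
#' @param gtf path to a GTF file (1-based, closed intervals; converted to the
#'   GRanges representation on load).
#' @param isoforms,fpkm,protein optional paths to covariate TSVs.
#' @return A `GRanges`, one range per gene, with metadata columns `gene_id`,
#'   `biotypes` (a `CharacterList`, one label per transcript),
#'   `isoform_count`, `fpkm` and `protein_expr` (`NA` where not supplied).
#' @examples
#' gtf <- system.file("extdata", "toy_genes.gtf", package = "RegRatio")
#' genes <- loadGeneAnnotation(gtf)
#' genes
#' @export
loadGeneAnnotation <- function(gtf, isoforms = NULL, fpkm = NULL, protein = NULL) {
    if (!file.exists(gtf))
        stop("GTF file not found: ", gtf)
    .validateGtfLines(gtf)
    gr <- rtracklayer::import(gtf, format = "gtf")
    if (!"type" %in% colnames(mcols(gr)) || !"gene_id" %in% colnames(mcols(gr)))
        stop("GTF lacks the required 'type'/'gene_id' attributes")
    genes <- gr[gr$type == "gene"]
    if (length(genes) == 0L)
        stop("no 'gene' features in ", gtf)
    if (anyDuplicated(genes$gene_id)) {
        dup <- genes$gene_id[duplicated(genes$gene_id)][1L]
        stop("duplicate gene_id in annotation: ", dup)
    }
    tx <- gr[gr$type == "transcript"]
    bt_col <- intersect(c("transcript_biotype", "transcript_type"),
                        colnames(mcols(tx)))
    bt <- if (length(bt_col)) as.character(mcols(tx)[[bt_col[1L]]])
          else rep(NA_character_, length(tx))
    by_gene <- split(bt, factor(tx$gene_id, levels = genes$gene_id))
    biotypes <- unname(CharacterList(lapply(by_gene, function(v) v[!is.na(v)])))

    out <- granges(genes)
    mcols(out) <- DataFrame(
        gene_id = genes$gene_id,
        biotypes = biotypes,
        isoform_count = unname(lengths(by_gene)),
        fpkm = NA_real_,
        protein_expr = NA_real_
    )
    unstranded <- as.character(BiocGenerics::strand(out)) == "*"
    if (any(unstranded)) {
        warning(sum(unstranded), " gene(s) lack strand annotation; treated as '+'")
        BiocGenerics::strand(out)[unstranded] <- "+"
    }
    if (!is.null(isoforms))
        out$isoform_count <- .joinCovariate(out$gene_id, isoforms, "isoform_count",
                                            default = out$isoform_count, integer = TRUE)
    if (!is.null(fpkm))
        out$fpkm <- .joinCovariate(out$gene_id, fpkm, "fpkm")
    if (!is.null(protein))
        out$protein_expr <- .joinCovariate(out$gene_id, protein, "protein_expr")
    out
}

# every non-comment GTF line must carry 9 tab-separated fields
.validateGtfLines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    data <- !startsWith(lines, "#") & nzchar(lines)
    nf <- lengths(strsplit(lines[data], "\t", fixed = TRUE))
    if (any(nf != 9L)) {
        bad <- which(data)[which(nf != 9L)[1L]]
        stop(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields, found %d",
                     bad, path, nf[which(nf != 9L)[1L]]))
    }
    invisible(TRUE)
}

.joinCovariate <- function(gene_ids, path, what, default = NA_real_, integer = FALSE) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = c("character", "numeric"))
    if (ncol(tab) < 2L)
        stop("covariate table ", path, " must have two columns (gene_id, value)")
    names(tab)[1:2] <- c("gene_id", "value")
    missing <- !tab$gene_id %in% gene_ids
    if (any(missing))
        warning(sum(missing), " ", what,
                " row(s) with gene_ids absent from the annotation were dropped")
    tab <- tab[!missing, , drop = FALSE]
    out <- rep(if (integer) NA_integer_ else NA_real_, length(gene_ids))
    if (length(default) == length(gene_ids)) out <- default
    idx <- match(tab$gene_id, gene_ids)
    out[idx] <- if (integer) as.integer(tab$value) else tab$value
    out
}

#' Promoter-expanded gene windows
#'
#' Extends each gene by a fixed distance on its upstream (promoter) side and
#' its downstream (3') side -- by default 5,000 bp upstream and 500 bp
#' downstream -- giving the window in which significant ATAC-seq peaks are
#' counted. Expansion is strand-aware by default: for a `-` strand gene the
#' upstream extension is applied at the right end. `stranded = FALSE` applies
#' the upstream extension on the left for every gene regardless of strand.
#' Windows are clipped at position 1 and, when `seqlengths` are known on the
#' input, at the chromosome end.
#'
#' @param genes a `GRanges` of genes (see [loadGeneAnnotation()]).
#' @param upstream,downstream nonnegative expansion distances in bp.
#' @param stranded logical; strand-aware expansion (default `TRUE`).
#' @return A `GRanges` of windows carrying `gene_id` and `kind = "expanded"`.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
#'                             strand = "+", gene_id = "G1")
#' expandWindows(g)   # 5001-20500
#' @export
expandWindows <- function(genes, upstream = 5000L, downstream = 500L,
                          stranded = TRUE) {
    stopifnot(upstream >= 0, downstream >= 0)
    s <- as.character(BiocGenerics::strand(genes))
    minus <- stranded & s == "-"
    left <- ifelse(minus, downstream, upstream)
    right <- ifelse(minus, upstream, downstream)
    out <- granges(genes)
    new_start <- pmax(1L, BiocGenerics::start(out) - left)
    new_end <- BiocGenerics::end(out) + right
    sl <- seqlengths(out)[as.character(seqnames(out))]
    new_end <- ifelse(is.na(sl), new_end, pmin(new_end, sl))
    BiocGenerics::start(out) <- new_start
    BiocGenerics::end(out) <- new_end
    mcols(out) <- DataFrame(gene_id = genes$gene_id, kind = "expanded")
    out
}

#' Gene-body windows
#'
#' The window in which significant POP-seq peaks are counted: the gene's own
#' span, independent of strand.
#'
#' @inheritParams expandWindows
#' @return A `GRanges` of windows carrying `gene_id` and `kind = "body"`.
#' @export
bodyWindows <- function(genes) {
    out <- granges(genes)
    mcols(out) <- DataFrame(gene_id = genes$gene_id, kind = "body")
    out
}

#' Write / read the internal gene table
#'
#' Serialises the gene annotation (coordinates, strand, biotype multiset and
#' covariates) to a TSV and reads it back losslessly; biotypes are
#' comma-joined in the file.
#'
#' @param genes a gene `GRanges` as returned by [loadGeneAnnotation()].
#' @param path output / input TSV path.
#' @return `writeGeneTable` returns `path` invisibly; `readGeneTable` returns
#'   the reconstructed `GRanges`.
#' @export
writeGeneTable <- function(genes, path) {
    df <- data.frame(
        gene_id = genes$gene_id,
        chrom = as.character(seqnames(genes)),
        start = BiocGenerics::start(genes),
        end = BiocGenerics::end(genes),
        strand = as.character(BiocGenerics::strand(genes)),
        biotypes = vapply(genes$biotypes, paste, character(1), collapse = ","),
        isoform_count = genes$isoform_count,
        fpkm = genes$fpkm,
        protein_expr = genes$protein_expr,
        stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGeneTable
#' @export
readGeneTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = c(gene_id = "character",
                                           chrom = "character",
                                           biotypes = "character",
                                           strand = "character"))
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    bt <- strsplit(df$biotypes, ",", fixed = TRUE)
    bt[!nzchar(df$biotypes) | is.na(df$biotypes)] <- list(character(0))
    mcols(gr) <- DataFrame(
        gene_id = df$gene_id,
        biotypes = CharacterList(bt),
        isoform_count = as.integer(df$isoform_count),
        fpkm = as.numeric(df$fpkm),
        protein_expr = as.numeric(df$protein_expr)
    )
    gr
}
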