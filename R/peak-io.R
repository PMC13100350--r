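#' Read an ENCODE narrowPeak file
#'
#' Parses a 10-column ENCODE narrowPeak file (BED6+4, the MACS output
#' dialect) into a [PeakSet-class]. The `-log10` p and q columns (7th and 8th
#' extra fields) are converted to linear-scale `pValue` / `qValue`; the
#' narrowPeak sentinel `-1` maps to `NA`. Files that do not carry exactly 10
#' columns fall back to [readPeakBed()] with a warning.
#'
#' @param path path to the peak file.
#' @param source `"atac"` or `"pop"`.
#' @return A [PeakSet-class].
#' @examples
#' np <- system.file("extdata", "toy_atac.narrowPeak", package = "RegRatio")
#' readNarrowPeak(np, source = "atac")
#' @export
readNarrowPeak <- function(path, source = c("atac", "pop")) {
    source <- match.arg(source)
    if (!file.exists(path))
        stop("peak file not found: ", path)
    ncol1 <- .peekColumnCount(path)
    if (identical(ncol1, 0L)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(name = character(0), score = numeric(0),
                               signalValue = numeric(0), pValue = numeric(0),
                               qValue = numeric(0), peak = integer(0))
        return(PeakSet(gr, source = source))
    }
    if (!identical(ncol1, 10L)) {
        warning("file does not look like 10-column narrowPeak (", ncol1,
                " columns); falling back to generic BED parsing")
        return(readPeakBed(path, source = source))
    }
    gr <- rtracklayer::import(path, format = "narrowPeak")
    mcols(gr) <- DataFrame(
        name = gr$name,
        score = gr$score,
        signalValue = gr$signalValue,
        pValue = ifelse(gr$pValue == -1, NA_real_, 10^(-gr$pValue)),
        qValue = ifelse(gr$qValue == -1, NA_real_, 10^(-gr$qValue)),
        peak = gr$peak
    )
    BiocGenerics::strand(gr) <- "*"
    PeakSet(gr, source = source)
}

.peekColumnCount <- function(path) {
    for (line in readLines(path, n = 50L, warn = FALSE)) {
        if (!nzchar(line) || startsWith(line, "#") ||
            startsWith(line, "track") || startsWith(line, "browser")) next
        return(length(strsplit(line, "\t", fixed = TRUE)[[1L]]))
    }
    0L
}

#' Read a generic BED peak file
#'
#' Parses a tab-separated BED file with at least 3 columns (0-based,
#' half-open coordinates) into a [PeakSet-class]. A p-value column -- e.g.
#' column 7 of Piranha POP-seq output -- can be named with `pvalue_col` and
#' is stored on the linear scale as `pValue`. Records with `start >= end` are
#' rejected with a warning; the rejection count is available as
#' `S4Vectors::metadata(x)$n_rejected`.
#'
#' @inheritParams readNarrowPeak
#' @param pvalue_col optional 1-based column index holding a p-value.
#' @return A [PeakSet-class].
#' @export
readPeakBed <- function(path, source = c("atac", "pop"), pvalue_col = NULL) {
    source <- match.arg(source)
    if (!file.exists(path))
        stop("peak file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(lines) & !startsWith(lines, "#") &
        !startsWith(lines, "track") & !startsWith(lines, "browser")
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (length(fields) == 0L) {
        out <- PeakSet(GRanges(), source = source)
        metadata(out)$n_rejected <- 0L
        return(out)
    }
    if (any(nf < 3L))
        stop("BED file ", path, " must have >= 3 tab-separated columns on every record")
    ncols <- max(nf)
    # ragged files are tolerated: missing trailing fields read as NA
    col <- function(i) vapply(fields, function(f)
        if (length(f) >= i) f[[i]] else NA_character_, character(1))
    start0 <- suppressWarnings(as.numeric(col(2L)))
    end <- suppressWarnings(as.numeric(col(3L)))
    if (anyNA(start0) || anyNA(end))
        stop("non-numeric coordinates in ", path)
    bad <- start0 >= end
    n_rejected <- sum(bad)
    if (n_rejected > 0)
        warning(n_rejected, " record(s) with start >= end rejected from ", path)
    ok <- !bad
    gr <- GRanges(col(1L)[ok], IRanges(start0[ok] + 1, end[ok]))
    mc <- S4Vectors::make_zero_col_DFrame(sum(ok))
    if (ncols >= 4L) mc$name <- col(4L)[ok]
    if (ncols >= 5L) mc$score <- suppressWarnings(as.numeric(col(5L)[ok]))
    if (!is.null(pvalue_col)) {
        if (pvalue_col > ncols)
            stop("pvalue_col = ", pvalue_col, " but file has ", ncols, " columns")
        raw <- col(as.integer(pvalue_col))[ok]
        pv <- suppressWarnings(as.numeric(raw))
        if (any(!is.na(raw) & is.na(pv)))
            stop("non-numeric p-value in column ", pvalue_col, " of ", path)
        mc$pValue <- pv
    }
    mcols(gr) <- mc
    out <- PeakSet(gr, source = source)
    metadata(out)$n_rejected <- n_rejected
    out
}

#' Keep significant peaks (FDR < alpha)
#'
#' Applies the significance filter used throughout the Regulation Ratio
#' pipeline: peaks with FDR-corrected p strictly below `alpha` (default
#' 0.05). Two routes are supported: `method = "qvalue"` uses the q-values the
#' peak caller already reports (the MACS narrowPeak case), while
#' `method = "bh"` computes Benjamini-Hochberg adjusted values from the raw
#' p-values across the whole set (the Piranha BED case) and filters on those.
#' Input order is preserved.
#'
#' @param x a [PeakSet-class].
#' @param alpha significance threshold (strict `<`).
#' @param method `"qvalue"` or `"bh"`.
#' @return The filtered [PeakSet-class]; under `method = "bh"` a
#'   `p_adjusted` metadata column records the adjusted values.
#' @export
filterSignificant <- function(x, alpha = 0.05, method = c("qvalue", "bh")) {
    method <- match.arg(method)
    stopifnot(is(x, "PeakSet"))
    if (method == "qvalue") {
        q <- mcols(x)$qValue
        if (is.null(q))
            stop("method = 'qvalue' but peaks carry no qValue column")
        if (anyNA(q))
            stop("qValue missing on record ", which(is.na(q))[1L],
                 "; use method = 'bh' or supply q-values")
        keep <- q < alpha
    } else {
        p <- mcols(x)$pValue
        if (is.null(p))
            stop("method = 'bh' but peaks carry no pValue column")
        if (anyNA(p))
            stop("pValue missing on record ", which(is.na(p))[1L])
        adj <- stats::p.adjust(p, method = "BH")
        mcols(x)$p_adjusted <- adj
        keep <- adj < alpha
    }
    x[keep]
}

#' Count peaks overlapping each gene window
#'
#' For every window, counts the peaks whose intersection with the window is
#' at least `minOverlap` bp (default 1: any overlap). A peak overlapping k
#' windows contributes to all k counts -- peaks in overlapping expanded gene
#' boundaries are deliberately counted for every gene involved, with no
#' deduplication. Strand is ignored. Chromosomes absent from the peak set
#' yield a count of 0.
#'
#' @param peaks a [PeakSet-class] (already significance-filtered for the RR
#'   pipeline).
#' @param windows a `GRanges` of gene windows carrying a `gene_id` column
#'   (see [expandWindows()], [bodyWindows()]).
#' @param minOverlap minimum intersection width in bp (>= 1).
#' @return A named integer vector, gene_id -> peak count.
#' @export
countOverlappingPeaks <- function(peaks, windows, minOverlap = 1L) {
    stopifnot(minOverlap >= 1L, !is.null(windows$gene_id))
    n <- countOverlaps(windows, peaks, minoverlap = minOverlap,
                       ignore.strand = TRUE)
    stats::setNames(as.integer(n), windows$gene_id)
}

#' Write a PeakSet back to disk
#'
#' Writes narrowPeak (10 columns, linear p/q converted back to `-log10`
#' scale, `NA` written as the `-1` sentinel) when the peak set carries the
#' narrowPeak columns, and BED (+ a trailing p-value column when present)
#' otherwise. Coordinates are written 0-based half-open per the BED family
#' convention; numeric significance columns are written to 6 significant
#' digits and round-trip through the matching reader.
#'
#' @param x a [PeakSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(x, path) {
    mc <- mcols(x)
    chrom <- as.character(seqnames(x))
    start0 <- BiocGenerics::start(x) - 1L
    end <- BiocGenerics::end(x)
    fmt <- function(v) ifelse(is.na(v), "-1", sprintf("%.6g", v))
    if (all(c("signalValue", "peak", "pValue", "qValue") %in% colnames(mc))) {
        lines <- paste(chrom, start0, end, mc$name,
                       ifelse(is.na(mc$score), 0, mc$score), ".",
                       fmt(mc$signalValue),
                       fmt(-log10(mc$pValue)),
                       fmt(-log10(mc$qValue)),
                       ifelse(is.na(mc$peak), -1L, mc$peak),
                       sep = "\t")
    } else {
        name <- if ("name" %in% colnames(mc)) mc$name else paste0("peak_", seq_along(x))
        score <- if ("score" %in% colnames(mc)) ifelse(is.na(mc$score), 0, mc$score) else 0
        lines <- paste(chrom, start0, end, name, score, ".", sep = "\t")
        if ("pValue" %in% colnames(mc))
            lines <- paste(lines, fmt(mc$pValue), sep = "\t")
    }
    writeLines(lines, path)
    invisible(path)
}
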