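#' Configuration for the synthetic regulation dataset
#'
#' Builds the parameter set for the fully self-contained synthetic fixture
#' generator: a gene annotation with log-normal gene lengths, per-gene
#' Poisson peak counts for both assays with regime-controlled density
#' ratios, peak significance values, and expression covariates with
#' regime-specific medians. Defaults emulate the statistical structure of
#' the human cell-line analyses the package targets: a 41/9.9/49.1 percent
#' split of transcriptional / balanced / post-transcriptional genes, FPKM
#' medians of 34 / 6.75 / 310, isoform-count medians of 5 / 2 / 7, a mild
#' (1.2x) protein-expression shift for post-transcriptional genes, and gene
#' lengths centred near 13 kb. Identical seeds yield byte-identical output
#' files.
#'
#' @param nGenes number of genes.
#' @param nChroms,chromLength chromosome count and length in bp; genes are
#'   placed non-uniformly (geometrically decaying chromosome weights).
#' @param lengthLog10Mean,lengthLog10Sd log10-normal gene-length parameters;
#'   the median gene length is `10^lengthLog10Mean` bp.
#' @param regimeFractions target fractions of the three regimes, summing
#'   to 1, in the order transcriptional, balanced, post_transcriptional.
#' @param lambdaAtac,lambdaPop per-regime significant-peak densities, peaks
#'   per kb of gene, for the ATAC (expanded window) and POP (gene body)
#'   assays. Balanced genes reuse one shared Poisson draw for both assays so
#'   exact RR = 1 cases exist at any rate.
#' @param sigFraction fraction of generated gene-window peaks that are
#'   significant (q < 0.05 for ATAC, BH-significant p for POP); the rest are
#'   decoys above the threshold.
#' @param isoformMedians,fpkmMedians,proteinMedians per-regime covariate
#'   medians (same regime order); covariates are log-normal around them.
#' @param activitySdlog log-scale sd of the shared per-gene regulatory
#'   activity factor that multiplies both assays' peak rates; it induces the
#'   positive correlation between the two densities seen in real data and
#'   cancels out of the Regulation Ratio.
#' @param covariateSdlog log-scale sd of the covariate distributions.
#' @param missingFraction fraction of genes dropped at random from each
#'   covariate table.
#' @param biotypeProbs named probabilities for transcript-biotype labels.
#' @param nIntergenicDecoys non-significant decoy peaks placed anywhere on
#'   the chromosomes, per assay.
#' @param upstream,downstream window used to place ATAC peaks.
#' @param seed integer seed; every generator call derives its stream from it.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 2000L,
                            nChroms = 4L,
                            chromLength = 5e7,
                            lengthLog10Mean = 4.1,
                            lengthLog10Sd = 0.45,
                            regimeFractions = c(transcriptional = 0.41,
                                                balanced = 0.099,
                                                post_transcriptional = 0.491),
                            lambdaAtac = c(transcriptional = 0.6,
                                           balanced = 0.4,
                                           post_transcriptional = 0.3),
                            lambdaPop = c(transcriptional = 0.15,
                                          balanced = 0.4,
                                          post_transcriptional = 0.6),
                            sigFraction = 0.8,
                            isoformMedians = c(transcriptional = 5,
                                               balanced = 2,
                                               post_transcriptional = 7),
                            fpkmMedians = c(transcriptional = 34,
                                            balanced = 6.75,
                                            post_transcriptional = 310),
                            proteinMedians = c(transcriptional = 1,
                                               balanced = 1.05,
                                               post_transcriptional = 1.2),
                            activitySdlog = 1.0,
                            covariateSdlog = 0.8,
                            missingFraction = 0,
                            biotypeProbs = c(protein_coding = 0.35,
                                             processed_transcript = 0.16,
                                             retained_intron = 0.15,
                                             nonsense_mediated_decay = 0.12,
                                             lncRNA = 0.10,
                                             processed_pseudogene = 0.05,
                                             misc_RNA = 0.04,
                                             miRNA = 0.03),
                            nIntergenicDecoys = 200L,
                            upstream = 5000L,
                            downstream = 500L,
                            seed = 1729L) {
    cfg <- list(nGenes = as.integer(nGenes), nChroms = as.integer(nChroms),
                chromLength = chromLength,
                lengthLog10Mean = lengthLog10Mean, lengthLog10Sd = lengthLog10Sd,
                regimeFractions = regimeFractions,
                lambdaAtac = lambdaAtac, lambdaPop = lambdaPop,
                sigFraction = sigFraction,
                isoformMedians = isoformMedians, fpkmMedians = fpkmMedians,
                proteinMedians = proteinMedians,
                activitySdlog = activitySdlog,
                covariateSdlog = covariateSdlog,
                missingFraction = missingFraction,
                biotypeProbs = biotypeProbs,
                nIntergenicDecoys = as.integer(nIntergenicDecoys),
                upstream = as.integer(upstream), downstream = as.integer(downstream),
                seed = as.integer(seed))
    stopifnot(cfg$nGenes >= 1, cfg$nChroms >= 1, cfg$chromLength > 1e5,
              abs(sum(cfg$regimeFractions) - 1) < 1e-8,
              all(names(cfg$regimeFractions) == REG_CATEGORIES),
              all(cfg$lambdaAtac >= 0), all(cfg$lambdaPop >= 0),
              cfg$sigFraction > 0, cfg$sigFraction <= 1,
              cfg$missingFraction >= 0, cfg$missingFraction < 1)
    class(cfg) <- "SyntheticConfig"
    cfg
}

#' Generate a synthetic gene annotation
#'
#' Draws gene positions, strands, lengths, regimes, per-gene transcript
#' (isoform) counts and transcript biotypes under `config`, optionally
#' writing an Ensembl-dialect GTF (gene + transcript features). Balanced-
#' regime genes also receive their shared peak-count draw here so that both
#' assay generators can reuse it.
#'
#' @param config a [syntheticConfig()] list.
#' @param gtfPath optional GTF output path.
#' @return A gene `GRanges` with metadata columns `gene_id`, `regime`,
#'   `isoform_count`, `biotypes` and `shared_count`, and seqlengths set.
#' @export
generateAnnotation <- function(config, gtfPath = NULL) {
    stopifnot(inherits(config, "SyntheticConfig"))
    set.seed(config$seed)
    n <- config$nGenes
    chroms <- paste0("chr", seq_len(config$nChroms))
    w <- 2^-(seq_len(config$nChroms) - 1)
    chrom <- sample(chroms, n, replace = TRUE, prob = w / sum(w))
    len <- pmin(pmax(round(10^stats::rnorm(n, config$lengthLog10Mean,
                                           config$lengthLog10Sd)), 200),
                floor(config$chromLength / 20))
    margin <- config$upstream + config$downstream + 1
    start <- floor(stats::runif(n, margin, config$chromLength - len - margin))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    regime <- factor(sample(REG_CATEGORIES, n, replace = TRUE,
                            prob = config$regimeFractions),
                     levels = REG_CATEGORIES)
    iso_med <- config$isoformMedians[as.integer(regime)]
    isoform_count <- pmax(1L, as.integer(round(stats::rlnorm(n, log(iso_med), 0.6))))
    biotypes <- CharacterList(lapply(isoform_count, function(k)
        sample(names(config$biotypeProbs), k, replace = TRUE,
               prob = config$biotypeProbs)))
    activity <- stats::rlnorm(n, 0, config$activitySdlog)
    shared_count <- rep(NA_integer_, n)
    bal <- regime == "balanced"
    if (any(bal))
        shared_count[bal] <- stats::rpois(sum(bal),
            config$lambdaAtac[["balanced"]] * activity[bal] * len[bal] / 1000)
    genes <- GRanges(chrom, IRanges(start, width = len), strand = strand,
                     seqlengths = stats::setNames(rep(config$chromLength,
                                                      config$nChroms), chroms))
    mcols(genes) <- DataFrame(
        gene_id = sprintf("G%05d", seq_len(n)),
        regime = regime,
        isoform_count = isoform_count,
        biotypes = biotypes,
        activity = activity,
        shared_count = shared_count)
    if (!is.null(gtfPath))
        .writeSyntheticGtf(genes, gtfPath)
    genes
}

.writeSyntheticGtf <- function(genes, path) {
    gl <- sprintf('%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                  as.character(seqnames(genes)), BiocGenerics::start(genes),
                  BiocGenerics::end(genes),
                  as.character(BiocGenerics::strand(genes)), genes$gene_id)
    tx_lines <- lapply(seq_along(genes), function(i) {
        bt <- genes$biotypes[[i]]
        sprintf(paste0('%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t',
                       'gene_id "%s"; transcript_id "%s.t%d"; transcript_biotype "%s";'),
                as.character(seqnames(genes))[i], BiocGenerics::start(genes)[i],
                BiocGenerics::end(genes)[i],
                as.character(BiocGenerics::strand(genes))[i],
                genes$gene_id[i], genes$gene_id[i], seq_along(bt), bt)
    })
    lines <- unlist(Map(c, gl, tx_lines), use.names = FALSE)
    writeLines(lines, path)
    invisible(path)
}

#' Generate a synthetic peak file for one assay
#'
#' Per-gene significant-peak counts are Poisson with rate
#' `lambda[regime] * gene length in kb`; balanced genes reuse the shared
#' count drawn at annotation time for both assays. Significant ATAC peaks
#' receive q-values below 0.05 (POP peaks: raw p-values small enough that a
#' per-file Benjamini-Hochberg adjustment at 0.05 retains exactly them) and
#' are placed uniformly in the promoter-expanded window (ATAC) or the gene
#' body (POP). Decoy peaks above the threshold are added per gene in
#' proportion `(1 - sigFraction) / sigFraction`, plus intergenic decoys.
#' Output is narrowPeak for ATAC and BED6+1 with the p-value in column 7
#' for POP.
#'
#' @param config a [syntheticConfig()] list.
#' @param genes annotation from [generateAnnotation()].
#' @param source `"atac"` or `"pop"`.
#' @param path output file path.
#' @return The written [PeakSet-class], invisibly.
#' @export
generatePeaks <- function(config, genes, source = c("atac", "pop"), path) {
    source <- match.arg(source)
    stopifnot(inherits(config, "SyntheticConfig"))
    set.seed(config$seed + if (source == "atac") 1L else 2L)
    lambda <- if (source == "atac") config$lambdaAtac else config$lambdaPop
    lam <- lambda[as.integer(genes$regime)] * genes$activity *
        BiocGenerics::width(genes) / 1000
    n_sig <- stats::rpois(length(genes), lam)
    bal <- as.character(genes$regime) == "balanced"
    n_sig[bal] <- genes$shared_count[bal]
    n_decoy <- stats::rpois(length(genes),
                            lam * (1 - config$sigFraction) / config$sigFraction)
    win <- if (source == "atac")
        expandWindows(genes, config$upstream, config$downstream, stranded = TRUE)
    else bodyWindows(genes)
    wr <- if (source == "atac") c(150L, 400L) else c(20L, 60L)

    place <- function(counts, significant) {
        idx <- rep(seq_along(genes), counts)
        k <- length(idx)
        if (k == 0L) return(NULL)
        width <- sample(seq(wr[1L], wr[2L]), k, replace = TRUE)
        ws <- BiocGenerics::start(win)[idx]
        we <- BiocGenerics::end(win)[idx]
        start <- floor(stats::runif(k, ws, pmax(ws, we - width) + 1))
        list(chrom = as.character(seqnames(win))[idx], start = start,
             width = width, significant = rep(significant, k))
    }
    sig <- place(n_sig, TRUE)
    dec <- place(n_decoy, FALSE)
    ni <- config$nIntergenicDecoys
    inter <- if (ni > 0) {
        chroms <- seqlevels(genes)
        width <- sample(seq(wr[1L], wr[2L]), ni, replace = TRUE)
        list(chrom = sample(chroms, ni, replace = TRUE),
             start = floor(stats::runif(ni, 1, config$chromLength - max(wr))),
             width = width, significant = rep(FALSE, ni))
    } else NULL
    parts <- Filter(Negate(is.null), list(sig, dec, inter))
    if (length(parts) == 0L) {
        out <- PeakSet(GRanges(seqlengths = seqlengths(genes)), source = source)
        writeLines(character(0), path)
        return(invisible(out))
    }
    chrom <- unlist(lapply(parts, `[[`, "chrom"))
    start <- unlist(lapply(parts, `[[`, "start"))
    width <- unlist(lapply(parts, `[[`, "width"))
    significant <- unlist(lapply(parts, `[[`, "significant"))
    m <- length(chrom)
    gr <- GRanges(chrom, IRanges(start, width = width),
                  seqlengths = seqlengths(genes))
    if (source == "atac") {
        q <- ifelse(significant, stats::runif(m, 1e-6, 0.049),
                    stats::runif(m, 0.06, 0.5))
        mcols(gr) <- DataFrame(
            name = sprintf("%s_peak_%d", source, seq_len(m)),
            score = pmin(1000L, as.integer(round(-10 * log10(q)))),
            signalValue = round(stats::runif(m, 1, 50), 3),
            pValue = q / 3,
            qValue = q,
            peak = as.integer(floor(width / 2)))
    } else {
        p <- ifelse(significant, stats::runif(m, 1e-8, 1e-4),
                    stats::runif(m, 0.3, 0.99))
        mcols(gr) <- DataFrame(
            name = sprintf("%s_peak_%d", source, seq_len(m)),
            score = as.integer(pmin(1000, round(-10 * log10(p)))),
            pValue = p)
    }
    out <- PeakSet(gr, source = source)
    writePeaks(out, path)
    invisible(out)
}

#' Generate synthetic covariate tables
#'
#' Writes the three two-column covariate TSVs (isoform counts as annotated;
#' FPKM and protein expression drawn log-normal with regime-specific
#' medians), optionally with a fraction of genes missing at random.
#'
#' @param config a [syntheticConfig()] list.
#' @param genes annotation from [generateAnnotation()].
#' @param dir output directory.
#' @return Named character vector of the written paths, invisibly.
#' @export
generateCovariates <- function(config, genes, dir) {
    stopifnot(inherits(config, "SyntheticConfig"))
    set.seed(config$seed + 3L)
    n <- length(genes)
    regime_i <- as.integer(genes$regime)
    draw <- function(medians)
        stats::rlnorm(n, log(medians[regime_i]), config$covariateSdlog)
    tabs <- list(
        isoforms = data.frame(gene_id = genes$gene_id,
                              value = genes$isoform_count),
        fpkm = data.frame(gene_id = genes$gene_id,
                          value = round(draw(config$fpkmMedians), 4)),
        protein = data.frame(gene_id = genes$gene_id,
                             value = round(draw(config$proteinMedians), 4)))
    paths <- stats::setNames(file.path(dir, paste0(names(tabs), ".tsv")),
                             names(tabs))
    for (nm in names(tabs)) {
        tab <- tabs[[nm]]
        if (config$missingFraction > 0) {
            keep <- stats::runif(n) >= config$missingFraction
            tab <- tab[keep, , drop = FALSE]
        }
        utils::write.table(tab, paths[[nm]], sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(paths)
}

#' Generate a complete synthetic dataset
#'
#' Runs the whole generator under one seed, writing `genes.gtf`,
#' `atac.narrowPeak`, `pop.bed`, `isoforms.tsv`, `fpkm.tsv`, `protein.tsv`
#' and `truth.tsv` (gene_id -> generating regime) into `outdir`. Each stage
#' derives its random stream from `config$seed`, so one seed determines
#' every output byte.
#'
#' @param config a [syntheticConfig()] list.
#' @param outdir output directory, created if needed.
#' @return Invisibly, a list with the gene `GRanges` and the file paths.
#' @export
simulateRegulationData <- function(config, outdir) {
    stopifnot(inherits(config, "SyntheticConfig"))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gtf = file.path(outdir, "genes.gtf"),
                  atac = file.path(outdir, "atac.narrowPeak"),
                  pop = file.path(outdir, "pop.bed"),
                  truth = file.path(outdir, "truth.tsv"))
    genes <- generateAnnotation(config, gtfPath = paths$gtf)
    generatePeaks(config, genes, "atac", paths$atac)
    generatePeaks(config, genes, "pop", paths$pop)
    cov <- generateCovariates(config, genes, outdir)
    paths <- c(paths, as.list(cov))
    utils::write.table(
        data.frame(gene_id = genes$gene_id, regime = as.character(genes$regime)),
        paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(list(genes = genes, paths = paths))
}
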