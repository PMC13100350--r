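test_that("narrowPeak significance columns convert from -log10 with the -1 sentinel", {
    np <- tempfile(fileext = ".narrowPeak")
    writeLines(c(
        "chr1\t100\t200\tp1\t500\t.\t5.5\t3.0\t2.0\t50",
        "chr1\t300\t400\tp2\t200\t.\t2.2\t1.0\t-1\t-1",
        "chr2\t0\t150\tp3\t100\t.\t1.0\t-1\t0.5\t10"
    ), np)
    ps <- readNarrowPeak(np, source = "atac")
    expect_s4_class(ps, "PeakSet")
    expect_equal(peakSource(ps), "atac")
    expect_equal(length(ps), 3L)
    expect_equal(start(ps), c(101, 301, 1))   # BED 0-based -> GRanges 1-based
    expect_equal(end(ps), c(200, 400, 150))
    expect_equal(ps$qValue, c(0.01, NA, 10^-0.5))
    expect_equal(ps$pValue, c(1e-3, 0.1, NA))
})

test_that("non-10-column files fall back to BED parsing with a warning", {
    bed <- tempfile(fileext = ".bed")
    writeLines("chr1\t10\t60\tpk\t5\t.\t0.001", bed)
    expect_warning(ps <- readNarrowPeak(bed, source = "pop"),
                   "falling back")
    expect_equal(length(ps), 1L)
    expect_null(mcols(ps)$qValue)
})

test_that("BED parsing maps columns, rejects degenerate intervals, and counts them", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c(
        "chr1\t0\t100",
        "chr1\t500\t500\tdegenerate\t0\t.\t0.5",
        "chr1\t200\t260\tpk2\t7\t.\t0.004"
    ), bed)
    expect_warning(ps <- readPeakBed(bed, source = "pop", pvalue_col = 7),
                   "start >= end")
    expect_equal(length(ps), 2L)
    expect_equal(metadata(ps)$n_rejected, 1L)
    expect_equal(start(ps), c(1, 201))
    # 3-column records carry no significance fields; p parsed when asked
    expect_equal(ps$pValue, c(NA, 0.004))
    bad <- tempfile(fileext = ".bed")
    writeLines("chr1\t0\t100\tpk\t1\t.\tnot_a_p", bad)
    expect_error(readPeakBed(bad, source = "pop", pvalue_col = 7),
                 "non-numeric p-value")
})

test_that("significance filtering is strict at the threshold and preserves order", {
    gr <- GRanges("chr1", IRanges(c(1, 101, 201, 301), width = 50),
                  qValue = c(0.01, 0.049, 0.05, 0.2))
    ps <- PeakSet(gr, source = "atac")
    kept <- filterSignificant(ps, alpha = 0.05, method = "qvalue")
    expect_equal(length(kept), 2L)
    expect_equal(start(kept), c(1, 101))
    # alpha above every value keeps everything, in order
    all_kept <- filterSignificant(ps, alpha = 1.01, method = "qvalue")
    expect_equal(start(all_kept), start(ps))
    # missing q on one record is an error naming it
    gr$qValue[3] <- NA
    expect_error(filterSignificant(PeakSet(gr, "atac"), method = "qvalue"),
                 "record 3")
})

test_that("BH filtering reproduces the step-up adjustment", {
    # hand-computed: p = {.01,.02,.03,.04}, m = 4 -> adjusted all 0.04
    gr <- GRanges("chr1", IRanges(c(1, 101, 201, 301), width = 50),
                  pValue = c(0.01, 0.02, 0.03, 0.04))
    kept <- filterSignificant(PeakSet(gr, "pop"), alpha = 0.05, method = "bh")
    expect_equal(length(kept), 4L)
    expect_equal(kept$p_adjusted, rep(0.04, 4))
    # adjusted values dominate the raw p and respect the threshold strictly
    gr2 <- GRanges("chr1", IRanges(seq(1, 901, 100), width = 50),
                   pValue = c(1e-5, 2e-4, 0.012, 0.025, 0.04, 0.2, 0.5, 0.6, 0.9, 1))
    kept2 <- filterSignificant(PeakSet(gr2, "pop"), alpha = 0.05, method = "bh")
    expect_true(all(kept2$p_adjusted >= kept2$pValue))
    expect_true(all(kept2$p_adjusted < 0.05))
    # empty set in, empty set out
    empty <- PeakSet(GRanges(qValue = numeric(0)), source = "pop")
    expect_equal(length(filterSignificant(empty, method = "qvalue")), 0L)
})

test_that("overlap counting uses half-open file semantics and counts shared peaks for every gene", {
    # window [1000, 2000) with peaks [1500,1600), [1990,2100), [2000,2100):
    # the third abuts the window end and must not count
    win <- GRanges("chr1", IRanges(1001, 2000), gene_id = "G1")
    pk <- PeakSet(GRanges("chr1", IRanges(c(1501, 1991, 2001),
                                          c(1600, 2100, 2100))), "atac")
    expect_equal(unname(countOverlappingPeaks(pk, win)), 2L)
    # one peak spanning two overlapping windows contributes to both counts
    win2 <- GRanges("chr1", IRanges(c(51, 151), c(150, 250)),
                    gene_id = c("A", "B"))
    pk2 <- PeakSet(GRanges("chr1", IRanges(101, 200)), "pop")
    expect_equal(countOverlappingPeaks(pk2, win2), c(A = 1L, B = 1L))
    # chromosome with no peaks yields zero, and the minimum-overlap knob bites
    win3 <- GRanges(c("chr9", "chr1"), IRanges(c(1, 101), c(100, 200)),
                    gene_id = c("C", "D"))
    expect_equal(countOverlappingPeaks(pk2, win3, minOverlap = 100L),
                 c(C = 0L, D = 1L))
    expect_equal(unname(countOverlappingPeaks(pk2, win3, minOverlap = 101L)),
                 c(0L, 0L))
})

test_that("indexed overlap counting agrees with the linear-scan oracle", {
    set.seed(23)
    for (i in 1:200) {
        nw <- sample(1:20, 1); np <- sample(0:60, 1)
        chroms <- c("chr1", "chr2")
        ws <- sample(1:9500, nw, replace = TRUE)
        we <- pmin(10000L, ws + sample(1:800, nw, replace = TRUE))
        wc <- sample(chroms, nw, replace = TRUE)
        win <- GRanges(wc, IRanges(ws, we), gene_id = paste0("g", seq_len(nw)))
        mo <- sample(c(1L, 5L, 25L), 1)
        if (np == 0) {
            pk <- PeakSet(GRanges(), "atac")
            expect_equal(unname(countOverlappingPeaks(pk, win, mo)),
                         rep(0L, nw))
            next
        }
        ps <- sample(1:9900, np, replace = TRUE)
        pe <- pmin(10000L, ps + sample(1:400, np, replace = TRUE))
        pc <- sample(chroms, np, replace = TRUE)
        pk <- PeakSet(GRanges(pc, IRanges(ps, pe)), "atac")
        got <- countOverlappingPeaks(pk, win, minOverlap = mo)
        want <- bruteOverlapCount(wc, ws, we, pc, ps, pe, mo)
        expect_equal(unname(got), want)
        # double counting only inflates the total
        expect_gte(sum(got), length(unique(
            subjectHits(findOverlaps(win, pk, minoverlap = mo)))))
    }
})

test_that("peak files round-trip through the writers", {
    toy <- system.file("extdata", "toy_atac.narrowPeak", package = "RegRatio")
    a1 <- readNarrowPeak(toy, "atac")
    out <- tempfile(fileext = ".narrowPeak")
    writePeaks(a1, out)
    a2 <- readNarrowPeak(out, "atac")
    expect_equal(ranges(a1), ranges(a2))
    expect_equal(a1$name, a2$name)
    expect_equal(a2$qValue, a1$qValue, tolerance = 1e-6)
    expect_equal(a2$pValue, a1$pValue, tolerance = 1e-6)
    expect_equal(a1$peak, a2$peak)

    toyp <- system.file("extdata", "toy_pop.bed", package = "RegRatio")
    p1 <- readPeakBed(toyp, "pop", pvalue_col = 7)
    outp <- tempfile(fileext = ".bed")
    writePeaks(p1, outp)
    p2 <- readPeakBed(outp, "pop", pvalue_col = 7)
    expect_equal(ranges(p1), ranges(p2))
    expect_equal(p2$pValue, p1$pValue, tolerance = 1e-6)
})
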