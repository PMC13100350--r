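test_that("Mann-Whitney U counts wins and half-ties and matches hand-enumerated p", {
    expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$u, 0)
    expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$u, 4.5)
    # exact p over the 2 arrangements of {5}, {1}
    r <- mannWhitneyU(5, 1, alternative = "greater")
    expect_equal(r$u, 1)
    expect_equal(r$p, 0.5)
    expect_equal(r$method, "exact")
    expect_error(mannWhitneyU(numeric(0), 1), "nonempty")
})

test_that("exact MWU p agrees with wilcox.test on tie-free samples", {
    set.seed(7)
    for (i in 1:20) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        v <- sample(1:100, n1 + n2)   # distinct values: wilcox.test stays exact
        x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
        for (alt in c("two.sided", "greater", "less")) {
            got <- mannWhitneyU(x, y, alternative = alt)
            ref <- stats::wilcox.test(x, y, alternative = alt, exact = TRUE)
            expect_equal(got$u, unname(ref$statistic))
            expect_equal(got$p, ref$p.value, tolerance = 1e-12)
        }
    }
})

test_that("exact MWU p matches full-enumeration oracle under ties", {
    set.seed(13)
    for (i in 1:15) {
        n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
        x <- sample(1:4, n1, replace = TRUE)   # small alphabet forces ties
        y <- sample(1:4, n2, replace = TRUE)
        for (alt in c("two.sided", "greater", "less")) {
            got <- mannWhitneyU(x, y, alternative = alt)
            ref <- bruteMWU(x, y, alternative = alt)
            expect_equal(got$u, ref$u)
            expect_equal(got$p, ref$p, tolerance = 1e-12)
        }
    }
})

test_that("large-sample MWU approximates the two-group Kruskal-Wallis p", {
    set.seed(99)
    x <- rnorm(200); y <- rnorm(200, 0.25)
    p_mwu <- mannWhitneyU(x, y)$p
    p_kw <- kruskalWallis(list(x, y))$p
    expect_equal(p_mwu, p_kw, tolerance = 0.15)
    expect_equal(mannWhitneyU(x, y)$method, "normal")
})

test_that("Kruskal-Wallis matches the rank-sum formula and handles degeneracy", {
    groups <- list(c(1, 2), c(3, 4), c(5, 6))
    got <- kruskalWallis(groups)
    # H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2, no ties here
    n <- lengths(groups); N <- sum(n)
    rk <- rank(unlist(groups))
    rbar <- tapply(rk, rep(seq_along(groups), n), mean)
    h_oracle <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
    expect_equal(got$h, h_oracle, tolerance = 1e-12)
    expect_equal(got$p, stats::pchisq(h_oracle, df = 2, lower.tail = FALSE))
    expect_warning(deg <- kruskalWallis(list(c(2, 2), c(2, 2, 2))),
                   "identical")
    expect_equal(deg$h, 0)
    expect_true(is.na(deg$p))
    expect_error(kruskalWallis(list(1:3)), ">= 2")
})

test_that("Cliff's delta enumerates pair dominance with its documented symmetries", {
    expect_equal(cliffsDelta(c(4, 5, 6), c(1, 2, 3)), 1)
    expect_equal(cliffsDelta(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(cliffsDelta(c(1, 2), c(2, 3)), -0.75)
    set.seed(17)
    for (i in 1:20) {
        x <- sample(1:6, sample(2:8, 1), replace = TRUE)
        y <- sample(1:6, sample(2:8, 1), replace = TRUE)
        d <- cliffsDelta(x, y)
        # O(nm) pair-enumeration oracle
        d_oracle <- (sum(outer(x, y, ">")) - sum(outer(x, y, "<"))) /
            (length(x) * length(y))
        expect_equal(d, d_oracle)
        expect_equal(cliffsDelta(y, x), -d)
        # invariant under joint strictly monotone transform
        expect_equal(cliffsDelta(exp(x), exp(y)), d)
        # delta = 2U/(nm) - 1 under the half-tie U convention
        u <- mannWhitneyU(x, y)$u
        expect_equal(d, 2 * u / (length(x) * length(y)) - 1)
    }
})

test_that("Bonferroni correction clips at 1 and preserves order", {
    expect_equal(bonferroniCorrect(c(0.01, 0.02, 0.03), m = 3),
                 c(0.03, 0.06, 0.09))
    expect_equal(bonferroniCorrect(0.5, m = 3), 1.0)
    expect_equal(bonferroniCorrect(numeric(0)), numeric(0))
})

test_that("median fold change divides sample medians", {
    expect_equal(medianFoldChange(c(2, 4, 6), c(1, 2, 3)), 2)
    expect_equal(medianFoldChange(c(1, 5, 9), c(1, 5, 9)), 1)
    expect_equal(medianFoldChange(10, 4), 2.5)
    expect_error(medianFoldChange(1:3, c(-1, 0, 1)), "positive")
})

test_that("biotype enrichment builds transcript-level tables with sample odds ratios", {
    # one post category gene set with transcripts {A:10, B:90} against a
    # background {A:50, B:950}: OR for A = (10*950)/(90*50)
    bt <- c(lapply(1:10, function(i) c("A", rep("B", 9))))
    prof <- mkProfFromCategories(paste0("g", 1:10),
                                 rep("post_transcriptional", 10), biotypes = bt)
    bg <- c(rep("A", 50), rep("B", 950))
    enr <- biotypeEnrichment(prof, background = bg)
    rowA <- enr[enr$label == "A", ]
    expect_equal(rowA$in_category_with_label, 10L)
    expect_equal(rowA$background_with_label, 50L)
    expect_equal(rowA$odds_ratio, (10 * 950) / (90 * 50))
    expect_equal(rowA$p_value,
                 stats::fisher.test(matrix(c(10, 90, 50, 950), 2))$p.value)
    expect_false(rowA$haldane)
    # category composition identical to background: OR = 1 everywhere
    bt_same <- rep(list(c("A", "B", "B", "B")), 8)
    prof2 <- mkProfFromCategories(paste0("g", 1:8),
                                  rep("transcriptional", 8), biotypes = bt_same)
    enr2 <- biotypeEnrichment(prof2,
                              background = rep(c("A", "B", "B", "B"), 100))
    expect_true(all(abs(enr2$odds_ratio - 1) < 1e-12))
    # labels at or below the abundance cutoff are dropped
    bt3 <- c(list(c("rare", rep("common", 199))), rep(list("common"), 3))
    prof3 <- mkProfFromCategories(paste0("g", 1:4), rep("balanced", 4),
                                  biotypes = bt3)
    enr3 <- biotypeEnrichment(prof3, background = c("rare", rep("common", 999)))
    expect_false("rare" %in% enr3$label)   # 0.5% <= 1% cutoff
    expect_true("common" %in% enr3$label)
    # zero background cell triggers the flagged Haldane-Anscombe ratio
    enr4 <- biotypeEnrichment(prof3, background = rep("common", 500),
                              minAbundancePct = 0.4)
    rowR <- enr4[enr4$label == "rare", ]
    expect_true(rowR$haldane)
    expect_equal(rowR$odds_ratio,
                 (1.5 * 500.5) / (202.5 * 0.5))
})

test_that("Fisher p-values match hypergeometric tail summation on small tables", {
    set.seed(19)
    for (i in 1:40) {
        cells <- as.integer(rmultinom(1, sample(20:200, 1), runif(4, 0.05, 1)))
        p_pkg <- stats::fisher.test(matrix(cells, 2))$p.value
        p_oracle <- bruteFisherP(cells[1], cells[2], cells[3], cells[4])
        expect_equal(p_pkg, p_oracle, tolerance = 1e-9)
    }
})

test_that("covariate comparison runs KW, Bonferroni-corrected pairwise MWU and effect sizes", {
    set.seed(29)
    # medians shifted 1 < 2 < 4 across categories
    cats <- rep(c("transcriptional", "balanced", "post_transcriptional"),
                each = 40)
    prof <- mkProfFromCategories(paste0("g", seq_along(cats)), cats)
    tab <- profileTable(prof)
    tab$fpkm <- c(rlnorm(40, log(2), 0.3), rlnorm(40, log(1), 0.3),
                  rlnorm(40, log(4), 0.3))
    prof@table <- tab
    cmp <- compareCovariate(prof, "fpkm")
    expect_s4_class(cmp, "CategoryComparison")
    expect_lt(cmp@kw$p, 0.01)
    pw <- cmp@pairwise
    expect_equal(nrow(pw), 3L)
    expect_equal(pw$p_bonferroni, pmin(1, 3 * pw$p_raw))
    # delta signs follow the configured ordering: trans > balanced,
    # trans < post, balanced < post
    d <- structure(pw$cliffs_delta, names = paste(pw$group1, pw$group2))
    expect_gt(d[["transcriptional balanced"]], 0)
    expect_lt(d[["transcriptional post_transcriptional"]], 0)
    expect_lt(d[["balanced post_transcriptional"]], 0)
    expect_equal(unname(cmp@medians["post_transcriptional"]),
                 median(tab$fpkm[81:120]))
    # genes missing the covariate are excluded and counted
    tab$fpkm[1:5] <- NA
    prof@table <- tab
    expect_equal(compareCovariate(prof, "fpkm")@nExcluded, 5L)
    # an empty category degrades to the populated pair with a warning
    tab2 <- profileTable(mkProfFromCategories(
        paste0("g", 1:20), rep(c("transcriptional", "balanced"), each = 10)))
    tab2$fpkm <- rlnorm(20)
    prof2 <- mkProfFromCategories(paste0("g", 1:20),
                                  rep(c("transcriptional", "balanced"), each = 10))
    prof2@table <- tab2
    expect_warning(cmp2 <- compareCovariate(prof2, "fpkm"), "degrades")
    expect_equal(nrow(cmp2@pairwise), 1L)
})
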