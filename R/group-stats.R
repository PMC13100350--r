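#' Mann-Whitney U test
#'
#' U statistic for the first sample over the second, counting 1 for each
#' pair with `x_i > y_j` and 1/2 for each tie, with a p-value by exact
#' enumeration of all group assignments when the combined sample size is at
#' most 16 (ties handled naturally through midranks) and by the normal
#' approximation with tie correction and continuity correction otherwise.
#' `stats::wilcox.test` refuses exact p-values in the presence of ties, which
#' the peak-density and covariate distributions here contain routinely; the
#' enumeration route keeps small-sample comparisons exact regardless.
#'
#' @param x,y nonempty numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   stated in terms of `x` tending larger than `y`.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` enumerates when `length(x) + length(y) <= 16`.
#' @return List with `u`, `p`, and `method` (`"exact"` or `"normal"`).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$u   # 0: complete separation
#' mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$u   # 4.5: ties count half
#' @export
mannWhitneyU <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact = NULL) {
    alternative <- match.arg(alternative)
    if (length(x) == 0L || length(y) == 0L)
        stop("both samples must be nonempty")
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    r <- rank(c(x, y))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (is.null(exact)) exact <- n <= 16L
    eps <- sqrt(.Machine$double.eps)
    if (exact) {
        sel <- utils::combn(n, n1)
        offset <- n1 * (n1 + 1) / 2
        u_all <- colSums(matrix(r[sel], nrow = n1)) - offset
        p <- switch(alternative,
            two.sided = mean(abs(u_all - n1 * n2 / 2) >= abs(u - n1 * n2 / 2) - eps),
            greater = mean(u_all >= u - eps),
            less = mean(u_all <= u + eps))
        return(list(u = u, p = p, method = "exact"))
    }
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    if (sigma == 0)
        return(list(u = u, p = NA_real_, method = "normal"))
    p <- switch(alternative,
        two.sided = {
            z <- (u - mu - sign(u - mu) * 0.5) / sigma
            min(1, 2 * stats::pnorm(-abs(z)))
        },
        greater = stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
        less = stats::pnorm((u - mu + 0.5) / sigma))
    list(u = u, p = p, method = "normal")
}

#' Kruskal-Wallis test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (rank statistic H with tie
#' correction, chi-square p on k - 1 degrees of freedom) with a defined
#' contract for the fully degenerate case: when every observation in every
#' group has the same value, H is 0 and the p-value is undefined, reported
#' as `NA` with a warning.
#'
#' @param groups a list of >= 2 nonempty numeric samples, total n >= 3.
#' @return List with `h`, `p`, `df`.
#' @export
kruskalWallis <- function(groups) {
    stopifnot(is.list(groups), length(groups) >= 2L)
    if (any(lengths(groups) == 0L))
        stop("all groups must be nonempty")
    if (sum(lengths(groups)) < 3L)
        stop("need a total of >= 3 observations")
    values <- unlist(groups, use.names = FALSE)
    if (length(unique(values)) == 1L) {
        warning("all observations identical; Kruskal-Wallis p undefined")
        return(list(h = 0, p = NA_real_, df = length(groups) - 1L))
    }
    kt <- stats::kruskal.test(groups)
    list(h = unname(kt$statistic), p = kt$p.value,
         df = unname(kt$parameter))
}

#' Cliff's delta effect size
#'
#' delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n m), in [-1, 1]; computed by
#' sorted-search pair counting rather than through the U statistic, so it
#' serves as an independent route to the dominance structure. Positive values
#' mean `x` tends to exceed `y`.
#'
#' @param x,y nonempty numeric samples.
#' @return A number in [-1, 1].
#' @examples
#' cliffsDelta(c(4, 5, 6), c(1, 2, 3))  #  1: complete dominance
#' cliffsDelta(c(1, 2), c(2, 3))        # -0.75
#' @export
cliffsDelta <- function(x, y) {
    if (length(x) == 0L || length(y) == 0L)
        stop("both samples must be nonempty")
    sy <- sort(y)
    m <- length(y)
    wins <- sum(findInterval(x, sy, left.open = TRUE))   # {y_j < x_i}
    losses <- sum(m - findInterval(x, sy))               # {y_j > x_i}
    (wins - losses) / (length(x) * m)
}

#' Bonferroni correction
#'
#' `p -> min(1, m p)`, order preserved; `m` defaults to the number of tests.
#'
#' @param p p-values in (0, 1].
#' @param m number of tests in the family.
#' @return Corrected p-values.
#' @export
bonferroniCorrect <- function(p, m = length(p)) {
    if (length(p) == 0L) return(numeric(0))
    stopifnot(all(p > 0 & p <= 1, na.rm = TRUE), m >= 1)
    pmin(1, m * p)
}

#' Ratio of sample medians
#'
#' @param x,y numeric samples; `median(y)` must be positive.
#' @return `median(x) / median(y)`.
#' @export
medianFoldChange <- function(x, y) {
    my <- stats::median(y)
    if (!is.finite(my) || my <= 0)
        stop("median of the denominator sample must be positive")
    stats::median(x) / my
}

#' Transcript-biotype enrichment per regulatory category
#'
#' For each regulatory category, the transcript-type composition is computed
#' over *transcripts* (a gene contributes one label per annotated
#' transcript), labels below the abundance cutoff (default: not more than 1%
#' of the category's transcripts) are dropped, and each retained
#' (label, category) pair is tested for enrichment against the background
#' transcript-type distribution with Fisher's exact test on the 2x2
#' transcript-count table. The reported odds ratio is the sample odds ratio
#' ad/bc; tables with a zero cell use the Haldane-Anscombe 0.5 correction
#' for the odds ratio and are flagged.
#'
#' @param profiles a classified [RegulationProfiles-class] whose table
#'   carries the `biotypes` column (built from an annotation loaded with
#'   [loadGeneAnnotation()]).
#' @param background optional character vector of background transcript-type
#'   labels; defaults to the transcripts of every gene in the annotation
#'   behind `profiles`.
#' @param minAbundancePct abundance cutoff in percent (strict `>` retains).
#' @return A `DataFrame` with one row per retained (category, label) pair:
#'   the 2x2 cells, `abundance_pct`, `odds_ratio`, `p_value`, `haldane`.
#' @export
biotypeEnrichment <- function(profiles, background = NULL, minAbundancePct = 1) {
    stopifnot(is(profiles, "RegulationProfiles"))
    tab <- profileTable(profiles)
    if (!"biotypes" %in% colnames(tab))
        stop("profiles carry no biotype annotation; build them from a GTF-loaded gene set")
    if (is.null(background))
        background <- unlist(tab$biotypes, use.names = FALSE)
    bg_tab <- table(background)
    bg_total <- length(background)
    res <- list()
    for (cat in REG_CATEGORIES) {
        in_cat <- !is.na(tab$category) & tab$category == cat
        labels <- unlist(tab$biotypes[in_cat], use.names = FALSE)
        total <- length(labels)
        if (total == 0L) next
        counts <- table(labels)
        pct <- 100 * counts / total
        for (lab in names(counts)[pct > minAbundancePct]) {
            a <- as.integer(counts[[lab]])
            b <- total - a
            cc <- if (lab %in% names(bg_tab)) as.integer(bg_tab[[lab]]) else 0L
            d <- bg_total - cc
            haldane <- any(c(a, b, cc, d) == 0L)
            or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
                  else (a * d) / (b * cc)
            pv <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2))$p.value
            res[[length(res) + 1L]] <- DataFrame(
                category = cat, label = lab,
                in_category_with_label = a, in_category_without = b,
                background_with_label = cc, background_without = d,
                abundance_pct = as.numeric(pct[[lab]]),
                odds_ratio = or, p_value = pv, haldane = haldane)
        }
    }
    if (length(res) == 0L)
        return(DataFrame(category = character(0), label = character(0)))
    do.call(rbind, res)
}

#' Compare one covariate across the regulatory categories
#'
#' Runs the full nonparametric comparison used for gene length, isoform
#' count, transcript abundance and protein expression: a Kruskal-Wallis test
#' across the populated categories, followed by pairwise Mann-Whitney U
#' tests with Bonferroni correction over the pairs, Cliff's delta per pair,
#' per-category medians and median fold changes. Genes missing the covariate
#' are excluded and counted; a category with no genes degrades the
#' comparison to the populated pairs with a warning.
#'
#' @param profiles a [RegulationProfiles-class].
#' @param covariate one of `length_bp`, `isoform_count`, `fpkm`,
#'   `protein_expr`, `td`, `ptd`.
#' @return A [CategoryComparison-class].
#' @export
compareCovariate <- function(profiles,
                             covariate = c("length_bp", "isoform_count",
                                           "fpkm", "protein_expr", "td", "ptd")) {
    covariate <- match.arg(covariate)
    stopifnot(is(profiles, "RegulationProfiles"))
    tab <- passingProfiles(profiles)
    if (!covariate %in% colnames(tab))
        stop("profiles carry no ", covariate, " column")
    v <- as.numeric(tab[[covariate]])
    keep <- !is.na(v)
    n_excluded <- sum(!keep)
    groups <- split(v[keep], factor(tab$category[keep], levels = REG_CATEGORIES))
    populated <- names(groups)[lengths(groups) > 0L]
    if (length(populated) < 2L)
        stop("need >= 2 populated categories to compare ", covariate)
    if (length(populated) < length(REG_CATEGORIES))
        warning("empty categor(ies) ",
                paste(setdiff(REG_CATEGORIES, populated), collapse = ", "),
                "; comparison degrades to the populated pairs")
    kw <- kruskalWallis(groups[populated])
    pairs <- utils::combn(populated, 2L)
    m <- ncol(pairs)
    rows <- lapply(seq_len(m), function(i) {
        g1 <- groups[[pairs[1L, i]]]; g2 <- groups[[pairs[2L, i]]]
        mw <- mannWhitneyU(g1, g2)
        fc <- if (stats::median(g2) > 0) stats::median(g1) / stats::median(g2)
              else NA_real_
        DataFrame(group1 = pairs[1L, i], group2 = pairs[2L, i],
                  u = mw$u, p_raw = mw$p, p_bonferroni = NA_real_,
                  cliffs_delta = cliffsDelta(g1, g2), median_fold_change = fc)
    })
    pw <- do.call(rbind, rows)
    pw$p_bonferroni <- bonferroniCorrect(pw$p_raw, m = m)
    medians <- vapply(groups[populated], stats::median, numeric(1))
    new("CategoryComparison", covariate = covariate,
        kw = kw, pairwise = pw, medians = medians,
        nExcluded = as.integer(n_excluded))
}
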