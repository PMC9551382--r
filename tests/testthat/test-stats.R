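test_that("paired t handles identical, constant-shift and random pairs", {
    expect_equal(pairedT(1:5, 1:5)$statistic, 0)
    expect_equal(pairedT(1:5, 1:5)$p, 1)
    expect_error(pairedT(c(1, 2, 3), c(0, 1, 2)),
                 class = "spermFISH_degenerate_error")
    expect_error(pairedT(1:3, 1:4), class = "spermFISH_validation_error")

    set.seed(11)
    x <- rnorm(12); y <- rnorm(12, 0.5)
    res <- pairedT(x, y)
    d <- x - y
    expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(12)),
                 tolerance = 1e-12)
    ht <- t.test(x, y, paired = TRUE)
    expect_equal(res$p, ht$p.value, tolerance = 1e-12)
    expect_equal(res$df, 11)
})

test_that("two-group methods match their closed forms", {
    ## equal proportions -> statistic exactly 0
    res <- twoGroupCompare(c(6, 1000), c(6, 1000), "two_proportion")
    expect_equal(res$statistic, 0)
    expect_equal(res$p, 1)

    ## z^2 equals the (uncorrected) chi-square of prop.test
    res <- twoGroupCompare(c(30, 1000), c(12, 900), "two_proportion")
    pt <- prop.test(c(30, 12), c(1000, 900), correct = FALSE)
    expect_equal(res$statistic^2, unname(pt$statistic), tolerance = 1e-12)
    expect_equal(res$p, pt$p.value, tolerance = 1e-12)

    set.seed(3)
    x <- rnorm(8); y <- rnorm(9, 1)
    for (m in c("student_t", "welch_t")) {
        res <- twoGroupCompare(x, y, m)
        ht <- t.test(x, y, var.equal = m == "student_t")
        expect_equal(res$p, ht$p.value)
    }
    expect_equal(twoGroupCompare(c(1, 2, 3), c(1, 2, 3),
                                 "mann_whitney")$p, 1)
    expect_error(twoGroupCompare(1:3, 1:3, "anova"),
                 class = "spermFISH_config_error")
})

test_that("rank-sum p agrees with exact permutation enumeration", {
    set.seed(5)
    x <- rnorm(4); y <- rnorm(4, 2)
    res <- kruskalSteelDwass(c(x, y), rep(c("a", "b"), each = 4))
    expect_equal(res$p, exactRankP(x, y), tolerance = 1e-12)
    ## and the wilcoxon route gives the same exact tail for untied data
    wil <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(res$p, wil, tolerance = 1e-12)
})

test_that("ANOVA + SNK: degenerate, two-group, and shifted-mean cases", {
    v <- rep(c(5, 5, 5), each = 4)
    g <- rep(c("a", "b", "c"), each = 4)
    res <- anovaSNK(v, g)
    ov <- attr(res, "anova")
    expect_equal(ov$F, 0)
    expect_false(any(res$significant))

    ## two groups: SNK collapses to one studentized-range test whose
    ## decision agrees with the pooled t-test (q = sqrt(2) * t)
    set.seed(21)
    x <- rnorm(6); y <- rnorm(6, 1.8)
    res2 <- anovaSNK(c(x, y), rep(c("a", "b"), each = 6))
    tp <- t.test(x, y, var.equal = TRUE)$p.value
    expect_equal(nrow(res2), 1L)
    expect_equal(res2$p, tp, tolerance = 1e-8)
    expect_equal(abs(res2$statistic),
                 sqrt(2) * abs(unname(t.test(x, y,
                     var.equal = TRUE)$statistic)),
                 tolerance = 1e-10)

    ## three groups, one clearly shifted: the shifted pairs are the
    ## significant ones and agree with a Tukey HSD oracle on the same data
    set.seed(8)
    v3 <- c(rnorm(8), rnorm(8), rnorm(8, 3))
    g3 <- rep(c("a", "b", "c"), each = 8)
    res3 <- anovaSNK(v3, g3)
    sig <- res3[res3$significant, "comparison"]
    expect_setequal(sig, c("c vs a", "c vs b"))
    hsd <- TukeyHSD(aov(v3 ~ g3))$g3
    tukeySig <- rownames(hsd)[hsd[, "p adj"] < 0.05]
    tukeySig <- gsub("-", " vs ", tukeySig)
    expect_true(all(tukeySig %in% sig))  # SNK is never more conservative
})

test_that("SNK statistic grows monotonically with the group shift", {
    set.seed(9)
    base <- rnorm(6)
    qs <- vapply(c(0.5, 1, 2, 4), function(shift) {
        v <- c(base, base + shift)
        res <- anovaSNK(v, rep(c("a", "b"), each = 6))
        abs(res$statistic)
    }, numeric(1))
    expect_true(all(diff(qs) > 0))
})

test_that("Kruskal-Wallis + Steel-Dwass handle ties and identical groups", {
    v <- rep(1.5, 12)
    g <- rep(c("a", "b", "c"), each = 4)
    res <- kruskalSteelDwass(v, g)
    expect_equal(attr(res, "kruskal")$H, 0)
    expect_true(all(res$p == 1))

    set.seed(13)
    v2 <- c(rnorm(5), rnorm(5), rnorm(5, 4))
    g2 <- rep(c("a", "b", "c"), each = 5)
    res2 <- kruskalSteelDwass(v2, g2)
    kw <- kruskal.test(v2, factor(g2))
    expect_equal(attr(res2, "kruskal")$H, unname(kw$statistic))
    expect_true(all(res2$p_adjusted >= 0 & res2$p_adjusted <= 1))
    ## the clearly shifted group is the one flagged
    expect_lt(res2$p_adjusted[res2$comparison == "a vs c"], 0.05)
})

test_that("binomial GLM contrasts recover a 2x2 log-odds ratio", {
    counts <- data.frame(chromosome = "1", group = c("g1", "g2"),
                         abnormal = c(30, 60), total = c(1000, 1000))
    res <- glmSeverity(counts)
    lor <- log((60 / 940) / (30 / 970))
    expect_equal(res$estimate, lor, tolerance = 1e-8)
    ## Wald z matches the closed-form SE of a 2x2 log-odds ratio
    seLor <- sqrt(1 / 30 + 1 / 970 + 1 / 60 + 1 / 940)
    expect_equal(res$statistic, lor / seLor, tolerance = 1e-6)
})

test_that("binomial GLM with equal rates finds nothing", {
    counts <- expand.grid(chromosome = as.character(1:5),
                          group = c("g1", "g2", "g3"))
    counts$total <- 2000L
    counts$abnormal <- 20L
    res <- glmSeverity(counts)
    expect_true(all(abs(res$estimate) < 1e-8))
    expect_true(all(res$p_adjusted > 0.99))
    expect_true(all(res$p_adjusted >= res$p))
})

test_that("statistics are invariant to observation order", {
    set.seed(2)
    v <- c(rnorm(6), rnorm(6, 1), rnorm(6, 2))
    g <- rep(c("a", "b", "c"), each = 6)
    perm <- sample(length(v))
    expect_equal(anovaSNK(v, g), anovaSNK(v[perm], g[perm]))
    expect_equal(kruskalSteelDwass(v, g),
                 kruskalSteelDwass(v[perm], g[perm]))
})
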