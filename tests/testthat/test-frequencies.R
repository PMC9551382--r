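## build a SlideClassification from a pattern table
triSlide <- function(patterns) {
    classifySlide(expandTriCells(patterns), translocatedPanel())
}

autoSlide <- function(nNormal, nNull = 0, nDis = 0, nDip = 0, nOth = 0,
                      chrom = 1) {
    cells <- data.frame(
        n_test1 = c(rep(1, nNormal), rep(0, nNull), rep(2, nDis),
                    rep(2, nDip), rep(3, nOth)),
        n_ctrl = c(rep(1, nNormal + nNull + nDis), rep(2, nDip),
                   rep(1, nOth)))
    cells$n_test2 <- NA_integer_
    classifySlide(cells, autosomePanel(chrom))
}

test_that("segregation frequencies are direct ratios summing to 100", {
    sl <- triSlide(data.frame(n13 = 1, n14 = 1, nctrl = 1, count = 500))
    expect_equal(unlist(segregationFrequencies(sl)[1, 1:5]),
                 c(alternate = 100, adjacent = 0, three_to_zero = 0,
                   diploidy = 0, others = 0))

    set.seed(7)
    counts <- stats::setNames(as.integer(stats::rmultinom(
        1, 2000, prob = c(70, 8, 7, 6, 5, 1, 1, 1, 1))),
        setdiff(modeCalls(), "unscorable"))
    fr <- segregationFrequencies(counts)
    n <- sum(counts)
    expect_equal(fr$alternate, 100 * counts[["alternate_balanced"]] / n)
    expect_equal(fr$adjacent,
                 100 * sum(counts[c("adjacent_disomy13",
                                    "adjacent_nullisomy13",
                                    "adjacent_disomy14",
                                    "adjacent_nullisomy14")]) / n)
    expect_equal(fr$alternate + fr$adjacent + fr$three_to_zero +
                 fr$diploidy + fr$others, 100)
})

test_that("translocated abnormality rows pool adjacent and 3:0 products", {
    ## pure 3:0, noise-free: both chromosomes 50% nullisomic, 50% disomic
    sl <- triSlide(data.frame(n13 = c(2, 0), n14 = c(2, 0),
                              nctrl = 1, count = c(100, 100)))
    ab <- translocatedAbnormalities(sl)
    expect_equal(ab$nullisomy, c(50, 50))
    expect_equal(ab$disomy, c(50, 50))
    expect_equal(ab$aneuploidy, c(100, 100))

    ## mixed slide: identities hold exactly
    sl <- triSlide(data.frame(
        n13 = c(1, 2, 0, 1, 1, 2, 0, 2, 3),
        n14 = c(1, 1, 1, 2, 0, 2, 0, 2, 1),
        nctrl = c(1, 1, 1, 1, 1, 1, 1, 2, 1),
        count = c(800, 40, 50, 35, 45, 10, 12, 6, 2)))
    ab <- translocatedAbnormalities(sl)
    expect_equal(ab$aneuploidy, ab$nullisomy + ab$disomy)
    expect_equal(ab$total, ab$aneuploidy + ab$diploidy + ab$others)
    n <- 1000
    expect_equal(ab$nullisomy[1], 100 * (50 + 12) / n)
    expect_equal(ab$disomy[1], 100 * (40 + 10) / n)
    expect_equal(ab$nullisomy[2], 100 * (45 + 12) / n)
})

test_that("per-chromosome table reports direct ratios and identities", {
    sl <- autoSlide(985, nNull = 6, nDis = 4, nDip = 5)
    tab <- nontranslocatedTable(list("7" = sl))
    expect_equal(tab$nullisomy, 0.6)
    expect_equal(tab$disomy, 0.4)
    expect_equal(tab$aneuploidy, 1.0)
    expect_equal(tab$diploidy, 0.5)
    expect_equal(tab$others, 0)
    expect_equal(tab$total, 1.5)

    allNormal <- nontranslocatedTable(list("2" = autoSlide(500)))
    expect_equal(allNormal$total, 0)

    expect_warning(
        nontranslocatedTable(list("1" = sl), expected = c("1", "2")),
        "no slide for chromosome")
})

test_that("carrier cumulative frequencies follow the sum and pooling rules", {
    one <- nontranslocatedTable(list("1" = autoSlide(989, nDis = 5,
                                                     nDip = 6)))
    rows <- do.call(rbind, replicate(22, one, simplify = FALSE))
    rows$chromosome <- as.character(1:22)
    cum <- carrierCumulative(rows)
    expect_equal(cum$disomy, 22 * 0.5)
    ## pooled diploidy equals the single-slide rate when slides are identical
    expect_equal(cum$diploidy, 0.6)
    expect_equal(cum$total, cum$aneuploidy + cum$diploidy + cum$others)

    single <- carrierCumulative(one)
    expect_equal(single$disomy, one$disomy)
    expect_equal(single$diploidy, one$diploidy)
})

test_that("including the tri-color slide adds both chromosome rows once", {
    nt <- nontranslocatedTable(list("1" = autoSlide(990, nNull = 10)))
    tri <- triSlide(data.frame(n13 = c(1, 2, 2), n14 = c(1, 1, 2),
                               nctrl = c(1, 1, 2), count = c(180, 10, 10)))
    cum <- carrierCumulative(nt, tri, includeTranslocated = TRUE)
    ab <- translocatedAbnormalities(tri)
    expect_equal(cum$nullisomy, 1 + sum(ab$nullisomy))
    expect_equal(cum$disomy, sum(ab$disomy))
    ## pooled denominator counts the tri-color slide cells once
    expect_equal(cum$n, 1000 + 200)
    expect_equal(cum$diploidy, 100 * 10 / 1200)
    expect_false(carrierCumulative(nt)$includes_translocated)
})

test_that("cohort summary honours the SD convention switch", {
    t1 <- table1Carriers()
    sm <- summarizeCohort(t1[-1])
    expect_equal(sm$alternate[sm$statistic == "mean"], 74.374)
    expect_equal(sm$alternate[sm$statistic == "sd"], popSD(t1$alternate))
    smSample <- summarizeCohort(t1[-1], sd = "sample")
    expect_equal(smSample$alternate[smSample$statistic == "sd"],
                 stats::sd(t1$alternate))
    expect_true(all(sm[sm$statistic == "min", -1] <=
                    sm[sm$statistic == "mean", -1]))

    const <- data.frame(a = rep(3.2, 6))
    expect_equal(summarizeCohort(const)$a[2], 0)
    expect_error(summarizeCohort(data.frame(a = 1)),
                 class = "spermFISH_degenerate_error")
})

test_that("cohort summary is order- and translation-invariant", {
    t1 <- table1Carriers()
    shuffled <- t1[sample(nrow(t1)), ]
    expect_equal(summarizeCohort(t1[-1]), summarizeCohort(shuffled[-1]))
    shifted <- t1$alternate + 100
    expect_equal(popSD(shifted), popSD(t1$alternate))
})

test_that("diploid fraction of 3:0-like patterns behaves at the edges", {
    expect_equal(diploidFraction3to0(0.31, 1.63), 0.31 / 1.94)
    expect_equal(diploidFraction3to0(0, 2), 0)
    expect_error(diploidFraction3to0(0, 0),
                 class = "spermFISH_degenerate_error")
    expect_error(diploidFraction3to0(-1, 2),
                 class = "spermFISH_validation_error")
})
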