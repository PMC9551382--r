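triPanel <- translocatedPanel()

test_that("single-test scoring follows the published criteria", {
    pan <- autosomePanel(21)
    cases <- list(
        list(c(n_test1 = 0, n_ctrl = 1), "nullisomy"),
        list(c(n_test1 = 2, n_ctrl = 2), "diploidy"),
        list(c(n_test1 = 1, n_ctrl = 1), "haploid_normal"),
        list(c(n_test1 = 2, n_ctrl = 1), "disomy"),
        list(c(n_test1 = 3, n_ctrl = 1), "trisomy"),
        list(c(n_test1 = 3, n_ctrl = 3), "triploidy"),
        list(c(n_test1 = 4, n_ctrl = 4), "tetraploidy"),
        list(c(n_test1 = 0, n_ctrl = 0), "unscorable"),
        list(c(n_test1 = 5, n_ctrl = 2), "multiple_aneuploidy"))
    for (cs in cases)
        expect_equal(classifyCell(cs[[1]], pan), cs[[2]])
    expect_equal(reportingGroup("trisomy"), "others")
    expect_equal(reportingGroup("unscorable"), "excluded")
})

test_that("classification is total over the pattern grid", {
    grid <- expand.grid(t = 0:6, c = 0:6)
    cats <- mapply(function(t, c)
        classifyCell(c(n_test1 = t, n_ctrl = c), autosomePanel(5)),
        grid$t, grid$c)
    expect_true(all(cats %in% cellCategories()))
    grid3 <- expand.grid(g = 0:4, o = 0:4, a = 0:4)
    modes <- mapply(function(g, o, a)
        inferMode(c(n_test1 = g, n_test2 = o, n_ctrl = a)),
        grid3$g, grid3$o, grid3$a)
    expect_true(all(modes %in% modeCalls()))
})

test_that("tri-color mode calls follow the diagnostic pattern table", {
    call <- function(g, o, a)
        inferMode(c(n_test1 = g, n_test2 = o, n_ctrl = a), triPanel)
    expect_equal(call(1, 1, 1), "alternate_balanced")
    expect_equal(call(2, 1, 1), "adjacent_disomy13")
    expect_equal(call(0, 1, 1), "adjacent_nullisomy13")
    expect_equal(call(1, 2, 1), "adjacent_disomy14")
    expect_equal(call(1, 0, 1), "adjacent_nullisomy14")
    expect_equal(call(2, 2, 1), "three_to_zero_double_disomy")
    expect_equal(call(0, 0, 1), "three_to_zero_double_nullisomy")
    ## the ploidy control is what separates diploid sperm from 3:0 products
    expect_equal(call(2, 2, 2), "diploid")
    expect_equal(call(0, 0, 0), "unscorable")
    expect_equal(call(3, 1, 1), "others")
    expect_error(inferMode(c(n_test1 = 1, n_test2 = 1, n_ctrl = 1),
                           autosomePanel(1)),
                 class = "spermFISH_config_error")
})

test_that("noise-free gametes round-trip through the mode caller", {
    expected <- list(
        alternate = c("alternate_balanced", "alternate_balanced"),
        adjacent_13 = c("adjacent_disomy13", "adjacent_nullisomy13"),
        adjacent_14 = c("adjacent_disomy14", "adjacent_nullisomy14"),
        three_to_zero = c("three_to_zero_double_disomy",
                          "three_to_zero_double_nullisomy"))
    for (mode in segregationModes()) {
        g <- enumerateGametes(mode)
        calls <- mapply(function(a, b, c)
            inferMode(c(n_test1 = a, n_test2 = b, n_ctrl = c), triPanel),
            g$n13, g$n14, g$nctrl)
        expect_equal(unname(calls), expected[[mode]], info = mode)
    }
})

test_that("slide classification partitions every nucleus exactly once", {
    pats <- data.frame(n13 = c(1, 2, 0, 2, 2, 3, 0),
                       n14 = c(1, 1, 0, 2, 2, 3, 1),
                       nctrl = c(1, 1, 1, 1, 2, 3, 0),
                       count = c(50, 7, 3, 2, 4, 1, 6))
    cells <- expandTriCells(pats)
    sl <- classifySlide(cells, triPanel)
    expect_equal(nScored(sl) + nUnscorable(sl), sum(pats$count))
    expect_equal(sum(categoryCounts(sl)), nScored(sl))
    expect_equal(sum(modeCounts(sl)), nScored(sl))
    expect_equal(nUnscorable(sl), 6L)
    expect_equal(unname(modeCounts(sl)["three_to_zero_double_disomy"]), 2L)
    expect_equal(unname(categoryCounts(sl)["diploidy"]), 4L)
})

test_that("an all-balanced slide classifies as pure alternate", {
    cells <- expandTriCells(data.frame(n13 = 1, n14 = 1, nctrl = 1,
                                       count = 1000))
    sl <- classifySlide(cells, triPanel)
    expect_equal(unname(modeCounts(sl)["alternate_balanced"]), 1000L)
    expect_equal(sum(modeCounts(sl)[names(modeCounts(sl)) != "alternate_balanced"]), 0L)
})

test_that("slide classification rejects bad input", {
    expect_error(classifySlide(data.frame(), triPanel),
                 class = "spermFISH_empty_error")
    bad <- data.frame(panel_id = "chr5", n_test1 = 1, n_ctrl = 1)
    expect_error(classifySlide(bad, triPanel),
                 class = "spermFISH_config_error")
    neg <- data.frame(n_test1 = -1, n_test2 = 1, n_ctrl = 1)
    expect_error(classifySlide(neg, triPanel),
                 class = "spermFISH_validation_error")
})

test_that("sex-panel subtypes separate XY disomy from diploidy", {
    pan <- sexPanel()
    cells <- data.frame(
        n_test1 = c(1, 0, 1, 2, 0, 1, 0),
        n_test2 = c(0, 1, 1, 0, 2, 1, 0),
        n_ctrl = c(1, 1, 1, 1, 1, 2, 1))
    sl <- classifySlide(cells, pan)
    sub <- sl@subtypeCounts
    expect_equal(unname(sub["haploid_X"]), 1L)
    expect_equal(unname(sub["haploid_Y"]), 1L)
    expect_equal(unname(sub["disomy_XY"]), 1L)
    expect_equal(unname(sub["disomy_XX"]), 1L)
    expect_equal(unname(sub["disomy_YY"]), 1L)
    ## (1,1,2) is a diploid nucleus, not XY disomy
    expect_equal(unname(categoryCounts(sl)["diploidy"]), 1L)
    expect_equal(unname(categoryCounts(sl)["nullisomy"]), 1L)
})

test_that("scored-cell tables survive a disk round trip", {
    sim <- expandTriCells(data.frame(n13 = c(1, 2), n14 = c(1, 1),
                                     nctrl = 1, count = c(5, 3)))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeScoredCells(sim, path)
    back <- readScoredCells(path)
    expect_equal(back$n_test1, sim$n_test1)
    expect_error(readScoredCells(file.path(tempdir(), "absent.tsv")),
                 class = "spermFISH_config_error")
})

test_that("panel validity and JSON config round trip", {
    expect_error(ProbePanel("p", "autosome", data.frame(
        name = c("a", "b"), target = c("1", "18"),
        color = c("green", "green"), role = c("test", "control"))),
        "unique")
    expect_error(ProbePanel("p", "autosome", data.frame(
        name = "a", target = "1", color = "green", role = "test")),
        "control")
    panels <- defaultPanels("carrier")
    expect_equal(length(panels), 22L)
    expect_equal(panelKind(panels[["tri_13_14"]]), "translocated")
    path <- withr::local_tempfile(fileext = ".json")
    writePanelConfig(panels, path)
    back <- readPanelConfig(path)
    expect_equal(names(back), names(panels))
    expect_equal(probes(back[["sex"]]), probes(panels[["sex"]]))
    shipped <- readPanelConfig(system.file("extdata", "panels.json",
                                           package = "spermFISH"))
    expect_true("tri_13_14" %in% names(shipped))
})
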