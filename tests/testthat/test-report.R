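simSmall <- local({
    sim <- NULL
    function() {
        if (is.null(sim))
            sim <<- simulateCohort(defaultCarrierCohort(4),
                                   defaultDonorCohort(3),
                                   nCells = 400, seed = 7)
        sim
    }
})

test_that("the pipeline renders all three tables with exact identities", {
    sim <- simSmall()
    b <- runPipeline(sim$cells, sim$subjects)

    t1 <- b$table1
    pat <- t1[!t1$patient %in% c("mean", "sd"), ]
    expect_equal(nrow(pat), 4L)
    expect_equal(pat$aneuploidy13, pat$nullisomy13 + pat$disomy13)
    expect_equal(pat$total13,
                 pat$aneuploidy13 + pat$diploidy + pat$others)
    expect_equal(pat$total14,
                 pat$aneuploidy14 + pat$diploidy + pat$others)
    segSum <- unname(rowSums(pat[, c("alternate", "adjacent",
                                     "three_to_zero", "diploidy",
                                     "others")]))
    expect_equal(segSum, rep(100, 4))

    t2 <- b$table2
    expect_setequal(t2$chromosome, c(as.character(c(1:12, 15:22)), "XY"))
    expect_equal(t2$aneuploidy, t2$nullisomy + t2$disomy)
    expect_equal(t2$total, t2$aneuploidy + t2$diploidy + t2$others)
    expect_true(all(t2$nullisomy_stars %in% c("", "*", "**", "***")))

    t3 <- b$table3
    expect_equal(t3$aneuploidy, t3$nullisomy + t3$disomy)
    expect_equal(t3$total, t3$aneuploidy + t3$diploidy + t3$others)
    expect_setequal(unique(t3$block), c("all_chromosomes",
                                        "nontranslocated"))
    ## carriers: the all-chromosome block adds the translocated burden
    carr <- t3[t3$arm == "carrier", ]
    byBlock <- split(carr, carr$block)
    expect_true(all(byBlock$all_chromosomes$aneuploidy >
                    byBlock$nontranslocated$aneuploidy))

    expect_true(any(grepl("severity_glm", b$stats$block)))
})

test_that("report bundles are byte-identical across reruns", {
    sim <- simSmall()
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    runPipeline(sim$cells, sim$subjects, outputDir = d1, seed = 7)
    runPipeline(sim$cells, sim$subjects, outputDir = d2, seed = 7)
    for (f in c("table1_segregation.tsv", "table2_nontranslocated.tsv",
                "table3_cumulative.tsv", "stats.tsv", "results.json")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), info = f)
    }
    log <- readLines(file.path(d1, "run.log"))
    expect_true(any(grepl("seed = 7", log)))
    expect_true(any(grepl("scored=\\d+ unscorable=\\d+", log)))
})

test_that("the pipeline reproduces the published cohort rows from the fixture", {
    sm <- summarizeCohort(table1Carriers()[-1])
    expect_equal(round(sm$alternate[1], 2), 74.37)
    expect_equal(round(sm$three_to_zero[1], 2), 1.63)
    expect_equal(round(sm$total13[2], 2), 6.00)
})

test_that("malformed input fails with classed errors", {
    expect_error(runPipeline(data.frame()), class = "spermFISH_empty_error")
    bad <- data.frame(subject_id = "s", panel_id = "chr99",
                      n_test1 = 1, n_test2 = NA, n_ctrl = 1)
    expect_error(runPipeline(bad), class = "spermFISH_config_error")
    sim <- simSmall()
    expect_error(runPipeline(sim$cells, sim$subjects, rounding = -1),
                 class = "spermFISH_validation_error")
})

test_that("the command-line driver runs end to end", {
    script <- system.file("scripts", "spermfish.R", package = "spermFISH")
    expect_true(nzchar(script))
    dir <- withr::local_tempdir()
    rscript <- file.path(R.home("bin"), "Rscript")
    st <- system2(rscript, c(script, "simulate", "--carriers", "2",
                             "--donors", "2", "--ncells", "100",
                             "--seed", "5", "--out", dir),
                  stdout = TRUE, stderr = TRUE)
    expect_true(file.exists(file.path(dir, "cells.tsv")))
    st2 <- system2(rscript, c(script, "report", "--cells",
                              file.path(dir, "cells.tsv"), "--subjects",
                              file.path(dir, "subjects.tsv"), "--out",
                              file.path(dir, "report"), "--seed", "5"),
                   stdout = TRUE, stderr = TRUE)
    expect_true(file.exists(file.path(dir, "report",
                                      "table1_segregation.tsv")))
    ## unknown subcommand -> parse exit code
    st3 <- suppressWarnings(
        system2(rscript, c(script, "frobnicate"), stdout = NULL,
                stderr = NULL))
    expect_equal(st3, 2L)
})
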