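## End-to-end driver: scored cells -> classification -> report tables
## mirroring the published layouts, plus a tidy statistics file.

## every panel id the default study design can produce
.panelSet <- function() {
    panels <- c(list(translocatedPanel()), lapply(1:22, autosomePanel),
                list(sexPanel()))
    stats::setNames(panels, vapply(panels, panelId, character(1)))
}

## panel id -> chromosome label used in per-chromosome tables
.panelChrom <- function(pid) {
    ifelse(pid == "sex", "XY", sub("^chr", "", pid))
}

#' Classify every slide of a scored-cell dataset
#'
#' Splits a scored-cell table by subject and panel and classifies each
#' slide. Panels are resolved by `panel_id` against the default study
#' design (or a custom panel list).
#'
#' @param cells Scored-cell `data.frame` (see [readScoredCells()]).
#' @param panels Named list of [ProbePanel-class] objects keyed by id.
#' @return Nested list: `result[[subject_id]][[panel_id]]` is a
#'   [SlideClassification-class].
#' @export
#' @examples
#' sim <- simulateCohort(defaultCarrierCohort(1), list(), nCells = 200,
#'                       seed = 5)
#' cls <- classifyCohort(sim$cells)
#' names(cls[["carrier01"]])
classifyCohort <- function(cells, panels = .panelSet()) {
    if (!is.data.frame(cells) || nrow(cells) == 0L)
        stopEmpty("classifyCohort: no cells")
    unknown <- setdiff(unique(cells$panel_id), names(panels))
    if (length(unknown))
        stopConfig("no panel definition for: %s",
                   paste(unknown, collapse = ", "))
    out <- list()
    for (sid in unique(cells$subject_id)) {
        sub <- cells[cells$subject_id == sid, ]
        out[[sid]] <- lapply(
            stats::setNames(nm = unique(sub$panel_id)),
            function(pid) classifySlide(sub[sub$panel_id == pid, ],
                                        panels[[pid]]))
    }
    out
}

## per-subject frequency tables from one subject's classified slides
.subjectFrequencies <- function(slides) {
    pids <- names(slides)
    nontransIds <- setdiff(pids, "tri_13_14")
    nt <- NULL
    if (length(nontransIds)) {
        ntSlides <- stats::setNames(slides[nontransIds],
                                    .panelChrom(nontransIds))
        nt <- nontranslocatedTable(ntSlides)
    }
    tri <- if ("tri_13_14" %in% pids) slides[["tri_13_14"]] else NULL
    list(nontrans = nt, translocated = tri)
}

## Table-1-style block for the carriers: segregation row + per-chromosome
## 13/14 abnormality columns, with mean/SD cohort rows appended.
.buildTable1 <- function(classified, carrierIds, sdConvention) {
    rows <- lapply(carrierIds, function(sid) {
        tri <- classified[[sid]][["tri_13_14"]]
        if (is.null(tri)) return(NULL)
        seg <- segregationFrequencies(tri)
        ab <- translocatedAbnormalities(tri)
        a13 <- ab[ab$chromosome == "13", ]
        a14 <- ab[ab$chromosome == "14", ]
        data.frame(patient = sid, alternate = seg$alternate,
                   adjacent = seg$adjacent,
                   three_to_zero = seg$three_to_zero,
                   diploidy = seg$diploidy, others = seg$others,
                   nullisomy13 = a13$nullisomy, disomy13 = a13$disomy,
                   aneuploidy13 = a13$aneuploidy, total13 = a13$total,
                   nullisomy14 = a14$nullisomy, disomy14 = a14$disomy,
                   aneuploidy14 = a14$aneuploidy, total14 = a14$total)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) return(NULL)
    if (nrow(tab) >= 2L) {
        sm <- summarizeCohort(tab[-1], sd = sdConvention)
        sm <- sm[sm$statistic %in% c("mean", "sd"), ]
        tab <- rbind(tab, cbind(patient = sm$statistic, sm[-1]))
    }
    tab
}

## Table-2-style block: pooled per-chromosome carrier frequencies with
## two-proportion stars against the pooled donor counts.
.buildTable2 <- function(classified, subjects) {
    pool <- function(ids) {
        tabs <- lapply(ids, function(sid)
            .subjectFrequencies(classified[[sid]])$nontrans)
        tabs <- tabs[!vapply(tabs, is.null, logical(1))]
        if (!length(tabs)) return(NULL)
        all <- do.call(rbind, tabs)
        agg <- lapply(split(all, all$chromosome), function(d)
            data.frame(chromosome = d$chromosome[1], n = sum(d$n),
                       n_nullisomy = sum(d$n_nullisomy),
                       n_disomy = sum(d$n_disomy),
                       n_diploidy = sum(d$n_diploidy),
                       n_others = sum(d$n_others)))
        do.call(rbind, agg)
    }
    carr <- pool(subjects$subject_id[subjects$arm == "carrier"])
    dono <- pool(subjects$subject_id[subjects$arm == "donor"])
    if (is.null(carr)) return(NULL)
    types <- c("nullisomy", "disomy", "diploidy", "others")
    rows <- lapply(seq_len(nrow(carr)), function(i) {
        chrom <- carr$chromosome[i]
        d <- if (!is.null(dono)) dono[dono$chromosome == chrom, ] else NULL
        out <- data.frame(chromosome = chrom, n_carrier = carr$n[i])
        kN <- carr$n_nullisomy[i]; kD <- carr$n_disomy[i]
        counts <- c(nullisomy = kN, disomy = kD,
                    diploidy = carr$n_diploidy[i],
                    others = carr$n_others[i])
        for (ty in types) {
            out[[ty]] <- 100 * counts[[ty]] / carr$n[i]
            star <- ""
            if (!is.null(d) && nrow(d) == 1L) {
                res <- twoGroupCompare(c(counts[[ty]], carr$n[i]),
                                       c(d[[paste0("n_", ty)]], d$n),
                                       "two_proportion")
                star <- res$stars
            }
            out[[paste0(ty, "_stars")]] <- star
        }
        out$aneuploidy <- out$nullisomy + out$disomy
        star <- ""
        if (!is.null(d) && nrow(d) == 1L) {
            res <- twoGroupCompare(c(kN + kD, carr$n[i]),
                                   c(d$n_nullisomy + d$n_disomy, d$n),
                                   "two_proportion")
            star <- res$stars
        }
        out$aneuploidy_stars <- star
        out$total <- out$aneuploidy + out$diploidy + out$others
        star <- ""
        if (!is.null(d) && nrow(d) == 1L) {
            kAllC <- kN + kD + carr$n_diploidy[i] + carr$n_others[i]
            kAllD <- d$n_nullisomy + d$n_disomy + d$n_diploidy + d$n_others
            res <- twoGroupCompare(c(kAllC, carr$n[i]), c(kAllD, d$n),
                                   "two_proportion")
            star <- res$stars
        }
        out$total_stars <- star
        out
    })
    tab <- do.call(rbind, rows)
    ## chromosome order 1..22, XY
    ord <- match(tab$chromosome, c(as.character(1:22), "XY"))
    tab[order(ord), ]
}

## Table-3-style block: per-subject cumulative summaries, both column
## blocks, plus carrier-vs-donor Welch t per statistic.
.buildTable3 <- function(classified, subjects) {
    perSubject <- lapply(subjects$subject_id, function(sid) {
        fr <- .subjectFrequencies(classified[[sid]])
        if (is.null(fr$nontrans)) return(NULL)
        arm <- subjects$arm[subjects$subject_id == sid]
        if (arm == "carrier") {
            nt <- fr$nontrans
            withAll <- carrierCumulative(nt, fr$translocated,
                                         includeTranslocated =
                                             !is.null(fr$translocated))
            nonOnly <- carrierCumulative(nt)
        } else {
            ## donors: chromosome 13/14 slides are ordinary slides
            nt <- fr$nontrans
            withAll <- carrierCumulative(nt)
            nonOnly <- carrierCumulative(
                nt[!nt$chromosome %in% c("13", "14"), ])
        }
        cbind(subject_id = sid, arm = arm,
              rbind(cbind(block = "all_chromosomes",
                          withAll[1:6]),
                    cbind(block = "nontranslocated", nonOnly[1:6])))
    })
    tab <- do.call(rbind, perSubject)
    if (is.null(tab)) return(NULL)
    rownames(tab) <- NULL
    stats <- NULL
    types <- c("nullisomy", "disomy", "diploidy", "others", "aneuploidy",
               "total")
    for (blk in unique(tab$block)) {
        sub <- tab[tab$block == blk, ]
        if (length(unique(sub$arm)) < 2L) next
        for (ty in types) {
            xc <- sub[[ty]][sub$arm == "carrier"]
            xd <- sub[[ty]][sub$arm == "donor"]
            if (length(xc) < 2L || length(xd) < 2L) next
            res <- twoGroupCompare(xc, xd, "welch_t",
                                   c("carrier", "donor"))
            res$block <- blk
            res$type <- ty
            stats <- rbind(stats, res)
        }
    }
    list(perSubject = tab, tests = stats)
}

## severity GLM on pooled carrier counts per chromosome x severity group
.buildSeverityStats <- function(classified, subjects, type = "nullisomy") {
    carrIds <- subjects$subject_id[subjects$arm == "carrier"]
    if (length(unique(stats::na.omit(subjects$severity))) < 2L)
        return(NULL)
    rows <- lapply(carrIds, function(sid) {
        nt <- .subjectFrequencies(classified[[sid]])$nontrans
        if (is.null(nt)) return(NULL)
        data.frame(chromosome = nt$chromosome,
                   group = subjects$severity[subjects$subject_id == sid],
                   abnormal = nt[[paste0("n_", type)]], total = nt$n)
    })
    counts <- do.call(rbind, rows)
    if (is.null(counts)) return(NULL)
    agg <- stats::aggregate(cbind(abnormal, total) ~ chromosome + group,
                            counts, sum)
    res <- glmSeverity(agg)
    res$type <- type
    res
}

#' Run the full analysis pipeline
#'
#' From a scored-cell table (simulated or read from disk) to the three
#' report tables: the per-carrier segregation/translocated-abnormality
#' table with cohort mean/SD rows, the per-chromosome
#' carrier-versus-control table with significance stars from the pooled
#' two-proportion test, and the per-carrier cumulative table (both column
#' blocks, with and without the translocated chromosomes) with
#' carrier-versus-donor tests. A severity GLM is fitted when the subject
#' metadata carries at least two semen-severity groups. All percentages
#' are computed at full precision and rounded only in the rendered TSVs.
#'
#' @param cells Scored-cell `data.frame` or a TSV/CSV path.
#' @param subjects Subject metadata `data.frame` (`subject_id`, `arm`,
#'   optional `severity`) or a TSV/CSV path; defaults to every subject in
#'   `cells` treated as a carrier.
#' @param outputDir Directory for the rendered TSVs, `results.json` and
#'   run log; `NULL` skips writing.
#' @param rounding Decimals for rendered percentages.
#' @param sdConvention `"population"` or `"sample"` SD for cohort rows.
#' @param seed Seed echoed into the log (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with `table1`, `table2`, `table3`, `stats`,
#'   `log`.
#' @export
#' @examples
#' sim <- simulateCohort(defaultCarrierCohort(2), defaultDonorCohort(2),
#'                       nCells = 300, seed = 2)
#' bundle <- runPipeline(sim$cells, sim$subjects)
#' bundle$table1[, 1:6]
runPipeline <- function(cells, subjects = NULL, outputDir = NULL,
                        rounding = 2L, sdConvention = "population",
                        seed = NA_integer_) {
    if (is.character(cells)) cells <- readScoredCells(cells)
    if (!is.data.frame(cells) || nrow(cells) == 0L)
        stopEmpty("runPipeline: no scored cells")
    if (is.character(subjects)) {
        subjects <- as.data.frame(data.table::fread(subjects))
    }
    if (is.null(subjects)) {
        subjects <- data.frame(subject_id = unique(cells$subject_id),
                               arm = "carrier",
                               severity = NA_character_)
    }
    if (!"severity" %in% names(subjects))
        subjects$severity <- NA_character_
    if (rounding < 0) stopValidation("rounding must be >= 0 decimals")
    classified <- classifyCohort(cells)
    carrierIds <- subjects$subject_id[subjects$arm == "carrier"]

    table1 <- .buildTable1(classified, carrierIds, sdConvention)
    table2 <- .buildTable2(classified, subjects)
    t3 <- .buildTable3(classified, subjects)
    sevStats <- tryCatch(
        rbind(.buildSeverityStats(classified, subjects, "nullisomy"),
              .buildSeverityStats(classified, subjects, "disomy")),
        error = function(e) NULL)
    statRows <- t3$tests
    if (!is.null(sevStats)) {
        sevStats$block <- "severity_glm"
        statRows <- rbind(
            cbind(statRows, estimate = NA_real_)[
                , c(names(statRows), "estimate")],
            sevStats[, c(names(statRows), "estimate")])
    }

    ## run log: every denominator and exclusion count
    logLines <- c(sprintf("spermFISH pipeline run, seed = %s", seed),
                  sprintf("subjects: %d (%d carriers, %d donors)",
                          nrow(subjects), sum(subjects$arm == "carrier"),
                          sum(subjects$arm == "donor")))
    for (sid in names(classified)) {
        for (pid in names(classified[[sid]])) {
            sl <- classified[[sid]][[pid]]
            logLines <- c(logLines,
                sprintf("%s %s: scored=%d unscorable=%d", sid, pid,
                        nScored(sl), nUnscorable(sl)))
        }
    }

    bundle <- list(table1 = table1, table2 = table2,
                   table3 = t3$perSubject, stats = statRows,
                   log = logLines)
    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        wr <- function(x, f) {
            if (is.null(x)) return(invisible(NULL))
            data.table::fwrite(roundNumeric(x, rounding),
                               file.path(outputDir, f), sep = "\t")
        }
        wr(table1, "table1_segregation.tsv")
        wr(table2, "table2_nontranslocated.tsv")
        wr(t3$perSubject, "table3_cumulative.tsv")
        wr(statRows, "stats.tsv")
        jsonlite::write_json(
            lapply(bundle[c("table1", "table2", "table3", "stats")],
                   function(x) if (is.null(x)) list() else x),
            file.path(outputDir, "results.json"), dataframe = "rows",
            auto_unbox = TRUE, digits = NA, na = "null")
        writeLines(logLines, file.path(outputDir, "run.log"))
    }
    invisible(bundle)
}
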