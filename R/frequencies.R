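## Frequency aggregation: per-chromosome tables, segregation-mode rows,
## per-carrier cumulative summaries and cohort mean/SD rows.
##
## Frequencies are carried as percentages of scorable nuclei at full
## precision; rounding to the 2-decimal report precision happens only at
## report time. Two identities hold exactly on every output:
## aneuploidy = nullisomy + disomy, total = aneuploidy + diploidy + others.

.modeCountsOf <- function(x) {
    if (is(x, "SlideClassification")) {
        if (x@kind != "translocated")
            stopConfig("expected a translocated-panel classification, got '%s'",
                       x@kind)
        return(x@modeCounts)
    }
    keep <- setdiff(modeCalls(), "unscorable")
    if (!is.numeric(x) || !all(keep %in% names(x)))
        stopValidation("mode counts must be named over modeCalls()")
    x[keep]
}

#' Segregation-mode frequency row
#'
#' Collapses translocated-panel mode-call counts into the five reported
#' segregation columns: alternate, adjacent (sum of the four adjacent
#' products), 3:0 (sum of double disomy and double nullisomy), diploidy
#' and others, each as a percentage of scorable nuclei. The row sums to
#' 100% before rounding.
#'
#' @param x A translocated-panel [SlideClassification-class], or a named
#'   count vector over [modeCalls()] (without `unscorable`).
#' @return One-row `data.frame`: `alternate`, `adjacent`, `three_to_zero`,
#'   `diploidy`, `others` (percent) and `n` (scorable nuclei).
#' @export
#' @examples
#' cells <- data.frame(n_test1 = rep(1, 10), n_test2 = 1, n_ctrl = 1)
#' segregationFrequencies(classifySlide(cells, translocatedPanel()))
segregationFrequencies <- function(x) {
    m <- .modeCountsOf(x)
    n <- sum(m)
    if (n == 0L)
        stopEmpty("segregationFrequencies: zero scorable cells")
    pct <- function(k) 100 * k / n
    data.frame(
        alternate = pct(m[["alternate_balanced"]]),
        adjacent = pct(m[["adjacent_disomy13"]] +
                       m[["adjacent_nullisomy13"]] +
                       m[["adjacent_disomy14"]] +
                       m[["adjacent_nullisomy14"]]),
        three_to_zero = pct(m[["three_to_zero_double_disomy"]] +
                            m[["three_to_zero_double_nullisomy"]]),
        diploidy = pct(m[["diploid"]]),
        others = pct(m[["others"]]),
        n = n)
}

#' Translocated-chromosome abnormality rows
#'
#' Per-chromosome numerical abnormality of chromosomes 13 and 14 from the
#' tri-color slide. Nullisomy 13 pools the adjacent nullisomy-13 product
#' with the 3:0 double nullisomy; disomy 13 pools adjacent disomy-13 with
#' the 3:0 double disomy (likewise chromosome 14). Diploidy and others are
#' slide-level and shared by both rows.
#'
#' @inheritParams segregationFrequencies
#' @return Two-row `data.frame` (`chromosome` = "13", "14") with columns
#'   `nullisomy`, `disomy`, `aneuploidy`, `diploidy`, `others`, `total`
#'   (percent) and `n`.
#' @export
translocatedAbnormalities <- function(x) {
    m <- .modeCountsOf(x)
    n <- sum(m)
    if (n == 0L)
        stopEmpty("translocatedAbnormalities: zero scorable cells")
    pct <- function(k) 100 * k / n
    row <- function(chrom, nulls, dis) {
        nullisomy <- pct(nulls)
        disomy <- pct(dis)
        aneuploidy <- nullisomy + disomy
        diploidy <- pct(m[["diploid"]])
        others <- pct(m[["others"]])
        data.frame(chromosome = chrom, nullisomy = nullisomy,
                   disomy = disomy, aneuploidy = aneuploidy,
                   diploidy = diploidy, others = others,
                   total = aneuploidy + diploidy + others, n = n)
    }
    rbind(
        row("13",
            m[["adjacent_nullisomy13"]] +
                m[["three_to_zero_double_nullisomy"]],
            m[["adjacent_disomy13"]] + m[["three_to_zero_double_disomy"]]),
        row("14",
            m[["adjacent_nullisomy14"]] +
                m[["three_to_zero_double_nullisomy"]],
            m[["adjacent_disomy14"]] + m[["three_to_zero_double_disomy"]]))
}

#' Per-chromosome frequency table for nontranslocated slides
#'
#' One row per chromosome slide with counts and frequencies (percent of
#' scorable nuclei on that slide) of nullisomy, disomy, aneuploidy,
#' diploidy, others and total abnormality. Chromosomes expected but absent
#' from the input produce a warning and a gap, not a failure.
#'
#' @param slides Named list of [SlideClassification-class] objects, keyed
#'   by chromosome label (e.g. `"1"`, ..., `"22"`, `"XY"`).
#' @param expected Optional character vector of chromosome labels that
#'   should be present; missing ones trigger a warning.
#' @return `data.frame` with columns `chromosome`, `n`, count columns
#'   (`n_nullisomy`, `n_disomy`, `n_diploidy`, `n_others`) and frequency
#'   columns (`nullisomy`, `disomy`, `aneuploidy`, `diploidy`, `others`,
#'   `total`, percent).
#' @export
nontranslocatedTable <- function(slides, expected = NULL) {
    if (length(slides) == 0L)
        stopEmpty("nontranslocatedTable: no slides")
    if (is.null(names(slides)) || any(!nzchar(names(slides))))
        stopValidation("slides must be a named list keyed by chromosome")
    if (!is.null(expected)) {
        miss <- setdiff(expected, names(slides))
        if (length(miss))
            warning(sprintf("no slide for chromosome(s): %s",
                            paste(miss, collapse = ", ")))
    }
    rows <- lapply(names(slides), function(chrom) {
        sl <- slides[[chrom]]
        stopifnot(is(sl, "SlideClassification"))
        cc <- categoryCounts(sl)
        n <- nScored(sl)
        if (n == 0L)
            stopEmpty("slide '%s' has zero scorable cells", chrom)
        grp <- reportingGroup(names(cc))
        kNull <- sum(cc[grp == "nullisomy"])
        kDis <- sum(cc[grp == "disomy"])
        kDip <- sum(cc[grp == "diploidy"])
        kOth <- sum(cc[grp == "others"])
        pct <- function(k) 100 * k / n
        data.frame(chromosome = chrom, n = n,
                   n_nullisomy = kNull, n_disomy = kDis,
                   n_diploidy = kDip, n_others = kOth,
                   nullisomy = pct(kNull), disomy = pct(kDis),
                   aneuploidy = pct(kNull) + pct(kDis),
                   diploidy = pct(kDip), others = pct(kOth),
                   total = pct(kNull) + pct(kDis) + pct(kDip) + pct(kOth))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-carrier cumulative abnormality summary
#'
#' Overall nullisomy, disomy and aneuploidy are the SUMS of the
#' per-chromosome frequencies; diploidy and others are pooled-count ratios
#' (diploid or "other" nuclei over the summed denominator across slides),
#' because a diploid nucleus is a whole-cell event detected on every
#' slide. With `includeTranslocated = TRUE`, the tri-color slide's
#' chromosome-13 and -14 frequency rows are added to the sums and its
#' cells (counted once) to the pooled denominator.
#'
#' @param nontrans Output of [nontranslocatedTable()] for this carrier.
#' @param translocated Optional translocated-panel
#'   [SlideClassification-class] (required when `includeTranslocated`).
#' @param includeTranslocated Logical; add the translocated chromosomes.
#' @return One-row `data.frame`: `nullisomy`, `disomy`, `aneuploidy`,
#'   `diploidy`, `others`, `total` (percent), `n` (pooled denominator),
#'   `includes_translocated`.
#' @export
carrierCumulative <- function(nontrans, translocated = NULL,
                              includeTranslocated = !is.null(translocated)) {
    if (!is.data.frame(nontrans) || nrow(nontrans) == 0L)
        stopEmpty("carrierCumulative: empty chromosome table")
    sNull <- sum(nontrans$nullisomy)
    sDis <- sum(nontrans$disomy)
    kDip <- sum(nontrans$n_diploidy)
    kOth <- sum(nontrans$n_others)
    nTot <- sum(nontrans$n)
    if (includeTranslocated) {
        if (is.null(translocated))
            stopConfig("includeTranslocated = TRUE needs the translocated slide")
        tr <- translocatedAbnormalities(translocated)
        sNull <- sNull + sum(tr$nullisomy)
        sDis <- sDis + sum(tr$disomy)
        m <- .modeCountsOf(translocated)
        ## tri-color slide counted once in the pooled denominator
        kDip <- kDip + m[["diploid"]]
        kOth <- kOth + m[["others"]]
        nTot <- nTot + sum(m)
    }
    dip <- 100 * kDip / nTot
    oth <- 100 * kOth / nTot
    data.frame(nullisomy = sNull, disomy = sDis,
               aneuploidy = sNull + sDis, diploidy = dip, others = oth,
               total = sNull + sDis + dip + oth, n = nTot,
               includes_translocated = includeTranslocated)
}

#' Cohort mean/SD/range summary
#'
#' Column-wise mean, SD, min and max over subjects. The published summary
#' rows follow the population convention (divisor n), verified by
#' recomputation from the packaged per-patient table; the `sd` switch
#' selects the sample (divisor n-1) convention instead.
#'
#' @param x `data.frame` of per-subject rows; non-numeric columns are
#'   dropped.
#' @param sd `"population"` (default) or `"sample"`.
#' @return `data.frame` with a `statistic` column (`mean`, `sd`, `min`,
#'   `max`) and one column per input variable.
#' @export
#' @examples
#' summarizeCohort(table1Carriers()[-1])
summarizeCohort <- function(x, sd = c("population", "sample")) {
    sd <- match.arg(sd)
    x <- as.data.frame(x)
    x <- x[vapply(x, is.numeric, logical(1))]
    if (nrow(x) < 2L)
        stopDegenerate("summarizeCohort: SD undefined for fewer than 2 subjects")
    sdFun <- if (sd == "population") {
        function(v) sqrt(mean((v - mean(v))^2))
    } else stats::sd
    stat <- function(f) vapply(x, f, numeric(1))
    out <- rbind(stat(mean), stat(sdFun), stat(min), stat(max))
    data.frame(statistic = c("mean", "sd", "min", "max"), out,
               row.names = NULL, check.names = FALSE)
}

#' Diploid share of 3:0-like signal patterns
#'
#' On a dual-color design, diploid sperm and 3:0 double-disomy gametes
#' produce the same two-plus-two signal pattern; the tri-color control
#' probe separates them. This helper reports the fraction of "3:0-like"
#' nuclei the control reveals as diploid: `diploidy / (diploidy + 3:0)`.
#'
#' @param diploidy,threeToZero Frequencies (any common scale).
#' @return The diploid fraction in \[0, 1\].
#' @export
#' @examples
#' diploidFraction3to0(0.31, 1.63)  # ~0.16
diploidFraction3to0 <- function(diploidy, threeToZero) {
    if (any(c(diploidy, threeToZero) < 0))
        stopValidation("frequencies must be non-negative")
    if (diploidy + threeToZero == 0)
        stopDegenerate("diploidFraction3to0: zero denominator")
    diploidy / (diploidy + threeToZero)
}

#' Published per-carrier translocated-chromosome table
#'
#' The per-patient segregation-mode and chromosome-13/14 abnormality
#' frequencies of the ten der(13;14) carriers, as packaged CSV: columns
#' `patient`, `alternate`, `adjacent`, `three_to_zero`, `diploidy`,
#' `others`, then `nullisomy13` ... `total13` and `nullisomy14` ...
#' `total14` (percent, 2 decimals as printed).
#'
#' @return `data.frame` with 10 rows.
#' @export
#' @examples
#' summarizeCohort(table1Carriers()[-1])
table1Carriers <- function() {
    path <- system.file("extdata", "table1_carriers.csv",
                        package = "spermFISH", mustWork = TRUE)
    utils::read.csv(path, check.names = FALSE)
}

#' Pooled scored-cell category counts of the carrier cohort
#'
#' Cohort-level category totals: 20,828 nuclei scored on the translocated
#' tri-color slides and 240,275 on the nontranslocated slides, split into
#' haploid / nullisomic / disomic / diploid / "others".
#'
#' @return `data.frame` with rows `translocated` and `nontranslocated`.
#' @export
pooledCategoryCounts <- function() {
    data.frame(
        slide_set = c("translocated", "nontranslocated"),
        haploid = c(17931L, 233483L),
        nullisomy = c(1755L, 3184L),
        disomy = c(1024L, 2126L),
        diploidy = c(64L, 1369L),
        others = c(54L, 113L),
        total = c(20828L, 240275L))
}
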