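## Scoring rules: per-nucleus signal counts -> numerical-abnormality
## category, and (tri-color translocated panel) segregation-mode call.
##
## Scored cells travel as a data.frame with columns subject_id, panel_id,
## n_test1, n_test2 (NA on dual-color panels) and n_ctrl (total count of
## the control probe set; for autosome panels whose control is the X+Y
## centromere pair this is the X+Y total, 1 in a haploid nucleus).

## single-test-probe rules: test count t against control count c.
## c == 0 -> unscorable (no "strong fluorescence signal" for the control).
.classifySingleTest <- function(t, c) {
    out <- rep("multiple_aneuploidy", length(t))
    out[c == 1 & t == 1] <- "haploid_normal"
    out[c == 1 & t == 0] <- "nullisomy"
    out[c == 1 & t == 2] <- "disomy"
    out[c == 2 & t == 2] <- "diploidy"
    out[c == 1 & t == 3] <- "trisomy"
    out[c == 3 & t == 3] <- "triploidy"
    out[c == 4 & t == 4] <- "tetraploidy"
    out[c == 0] <- "unscorable"
    out
}

## sex panel: X count x, Y count y, autosomal control c.
.classifySex <- function(x, y, c) {
    s <- x + y
    cat <- rep("multiple_aneuploidy", length(x))
    cat[c == 1 & s == 1] <- "haploid_normal"
    cat[c == 1 & s == 0] <- "nullisomy"
    cat[c == 1 & s == 2] <- "disomy"
    cat[c == 2 & s == 2] <- "diploidy"
    cat[c == 1 & s == 3] <- "trisomy"
    cat[c == 3 & s == 3] <- "triploidy"
    cat[c == 4 & s == 4] <- "tetraploidy"
    cat[c == 0] <- "unscorable"
    sub <- rep(NA_character_, length(x))
    sub[cat == "haploid_normal" & x == 1] <- "haploid_X"
    sub[cat == "haploid_normal" & y == 1] <- "haploid_Y"
    sub[cat == "disomy" & x == 2] <- "disomy_XX"
    sub[cat == "disomy" & y == 2] <- "disomy_YY"
    sub[cat == "disomy" & x == 1 & y == 1] <- "disomy_XY"
    list(category = cat, subtype = sub)
}

## translocated tri-color panel: 13q count g, 14q count o, control a.
.inferModeVec <- function(g, o, a) {
    out <- rep("others", length(g))
    h <- a == 1
    out[h & g == 1 & o == 1] <- "alternate_balanced"
    out[h & g == 2 & o == 1] <- "adjacent_disomy13"
    out[h & g == 0 & o == 1] <- "adjacent_nullisomy13"
    out[h & g == 1 & o == 2] <- "adjacent_disomy14"
    out[h & g == 1 & o == 0] <- "adjacent_nullisomy14"
    out[h & g == 2 & o == 2] <- "three_to_zero_double_disomy"
    out[h & g == 0 & o == 0] <- "three_to_zero_double_nullisomy"
    out[a == 2 & g == 2 & o == 2] <- "diploid"
    out[a == 0] <- "unscorable"
    out
}

.modeToCategory <- c(
    alternate_balanced = "haploid_normal",
    adjacent_disomy13 = "disomy", adjacent_nullisomy13 = "nullisomy",
    adjacent_disomy14 = "disomy", adjacent_nullisomy14 = "nullisomy",
    three_to_zero_double_disomy = "disomy",
    three_to_zero_double_nullisomy = "nullisomy",
    diploid = "diploidy", others = "multiple_aneuploidy",
    unscorable = "unscorable")

.checkCounts <- function(...) {
    for (v in list(...)) {
        if (anyNA(v) || any(v < 0) || any(v != floor(v)))
            stopValidation("signal counts must be non-negative integers")
    }
}

#' Classify one nucleus's signal pattern
#'
#' Applies the scoring criteria to a single signal pattern: one signal per
#' test probe and one control signal is a normal haploid nucleus; zero/two
#' test signals against one control signal are nullisomy/disomy; two
#' signals for both test and control probes is diploidy; trisomy,
#' triploidy, tetraploidy and any remaining pattern roll up to "others" in
#' reports; a nucleus with no control signal is unscorable and excluded.
#'
#' @param pattern Named numeric: `n_test1`, `n_ctrl` and, for tri-color
#'   panels, `n_test2`.
#' @param panel The [ProbePanel-class] the pattern was scored under.
#' @return Category label (see [cellCategories()]).
#' @export
#' @examples
#' classifyCell(c(n_test1 = 0, n_ctrl = 1), autosomePanel(21))  # nullisomy
#' classifyCell(c(n_test1 = 2, n_test2 = 2, n_ctrl = 1), translocatedPanel())
classifyCell <- function(pattern, panel) {
    if (!is(panel, "ProbePanel"))
        stopConfig("classifyCell: 'panel' must be a ProbePanel")
    t1 <- pattern[["n_test1"]]
    ct <- pattern[["n_ctrl"]]
    kind <- panelKind(panel)
    if (kind == "autosome") {
        .checkCounts(t1, ct)
        return(.classifySingleTest(t1, ct))
    }
    t2 <- pattern[["n_test2"]]
    if (is.null(t2) || is.na(t2))
        stopConfig("tri-color panel '%s' needs an n_test2 count",
                   panelId(panel))
    .checkCounts(t1, t2, ct)
    if (kind == "sex")
        return(.classifySex(t1, t2, ct)$category)
    unname(.modeToCategory[.inferModeVec(t1, t2, ct)])
}

#' Segregation-mode call for a tri-color translocated-panel pattern
#'
#' Maps a `(13q, 14q, control)` signal pattern to the segregation product
#' it diagnoses. The internal ploidy control is what separates a diploid
#' nucleus (2,2,2) from a 3:0 double-disomy gamete (2,2,1) — dual-color
#' designs cannot tell these apart. Patterns with no control signal are
#' unscorable; anything not matching a segregation product, diploidy or
#' unscorability is "others".
#'
#' @param pattern Named numeric `c(n_test1=, n_test2=, n_ctrl=)` (13q, 14q,
#'   control).
#' @param panel A translocated [ProbePanel-class].
#' @return A label from [modeCalls()].
#' @export
#' @examples
#' inferMode(c(n_test1 = 2, n_test2 = 2, n_ctrl = 2))  # diploid, not 3:0
#' inferMode(c(n_test1 = 2, n_test2 = 2, n_ctrl = 1))  # 3:0 double disomy
inferMode <- function(pattern, panel = translocatedPanel()) {
    if (!is(panel, "ProbePanel") || panelKind(panel) != "translocated")
        stopConfig("inferMode needs the translocated tri-color panel")
    t1 <- pattern[["n_test1"]]; t2 <- pattern[["n_test2"]]
    ct <- pattern[["n_ctrl"]]
    .checkCounts(t1, t2, ct)
    .inferModeVec(t1, t2, ct)
}

#' Classify all nuclei of one slide
#'
#' Vectorized classification of a scored-cell table for a single panel.
#' Category counts plus the unscorable count always partition the input;
#' for the translocated panel, per-mode-call counts are kept alongside the
#' categories, and for the sex panel, haploid X/Y and XX/YY/XY disomy
#' subtypes are tallied.
#'
#' @param cells `data.frame` with columns `n_test1`, `n_ctrl` and (for
#'   tri-color panels) `n_test2`; typically one panel's rows from
#'   [readScoredCells()] or the simulator.
#' @param panel The [ProbePanel-class] the slide was hybridized with.
#' @return A [SlideClassification-class] object.
#' @export
#' @examples
#' cells <- data.frame(n_test1 = c(1, 0, 2), n_test2 = c(1, 1, 2),
#'                     n_ctrl = c(1, 1, 1))
#' classifySlide(cells, translocatedPanel())
classifySlide <- function(cells, panel) {
    if (!is(panel, "ProbePanel"))
        stopConfig("classifySlide: 'panel' must be a ProbePanel")
    if (!is.data.frame(cells) || nrow(cells) == 0L)
        stopEmpty("classifySlide: no cells to classify for panel '%s'",
                  panelId(panel))
    if ("panel_id" %in% names(cells) &&
        !all(cells$panel_id == panelId(panel)))
        stopConfig("cells carry panel ids not matching panel '%s'",
                   panelId(panel))
    kind <- panelKind(panel)
    t1 <- cells$n_test1
    ct <- cells$n_ctrl
    subtype <- integer(0)
    mode <- integer(0)
    if (kind == "autosome") {
        .checkCounts(t1, ct)
        cat <- .classifySingleTest(t1, ct)
    } else {
        t2 <- cells$n_test2
        .checkCounts(t1, t2, ct)
        if (kind == "sex") {
            cs <- .classifySex(t1, t2, ct)
            cat <- cs$category
            subs <- c("haploid_X", "haploid_Y", "disomy_XX", "disomy_YY",
                      "disomy_XY")
            subtype <- vapply(subs, function(s)
                sum(cs$subtype == s, na.rm = TRUE), integer(1))
        } else {
            mc <- .inferModeVec(t1, t2, ct)
            cat <- unname(.modeToCategory[mc])
            keep <- setdiff(modeCalls(), "unscorable")
            mode <- vapply(keep, function(m) sum(mc == m), integer(1))
        }
    }
    scorable <- cat != "unscorable"
    cats <- setdiff(cellCategories(), "unscorable")
    counts <- vapply(cats, function(cc) sum(cat == cc), integer(1))
    new("SlideClassification", panelId = panelId(panel), kind = kind,
        categoryCounts = counts, modeCounts = mode,
        subtypeCounts = subtype,
        nScored = sum(scorable), nUnscorable = sum(!scorable))
}

#' Read / write scored-cell tables
#'
#' Scored cells are exchanged as TSV/CSV with columns `subject_id`,
#' `panel_id`, `n_test1`, `n_test2`, `n_ctrl` (`n_test2` empty for
#' dual-color panels). The delimiter is inferred from the file.
#'
#' @param path File path.
#' @return `readScoredCells()`: a `data.frame` of scored cells.
#' @export
readScoredCells <- function(path) {
    if (!file.exists(path))
        stopConfig("scored-cell file not found: %s", path)
    df <- as.data.frame(data.table::fread(path))
    need <- c("subject_id", "panel_id", "n_test1", "n_ctrl")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stopValidation("scored-cell table %s is missing columns: %s",
                       path, paste(miss, collapse = ", "))
    if (!"n_test2" %in% names(df)) df$n_test2 <- NA_integer_
    df
}

#' @rdname readScoredCells
#' @param cells `data.frame` of scored cells.
#' @export
writeScoredCells <- function(cells, path) {
    data.table::fwrite(cells, path, sep = "\t")
    invisible(path)
}
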