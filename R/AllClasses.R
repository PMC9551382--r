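#' @import methods
NULL

## ---------------------------------------------------------------------------
## Vocabulary
## ---------------------------------------------------------------------------

#' Classification vocabularies
#'
#' `cellCategories()` returns the per-nucleus numerical-abnormality
#' categories; `modeCalls()` the segregation-mode call labels used for the
#' translocated tri-color panel; `segregationModes()` the four meiotic
#' segregation modes of the der(13;14) trivalent.
#'
#' @return Character vector of labels.
#' @export
#' @examples
#' segregationModes()
#' cellCategories()
cellCategories <- function() {
    c("haploid_normal", "nullisomy", "disomy", "diploidy", "trisomy",
      "triploidy", "tetraploidy", "multiple_aneuploidy", "unscorable")
}

#' @rdname cellCategories
#' @export
modeCalls <- function() {
    c("alternate_balanced",
      "adjacent_disomy13", "adjacent_nullisomy13",
      "adjacent_disomy14", "adjacent_nullisomy14",
      "three_to_zero_double_disomy", "three_to_zero_double_nullisomy",
      "diploid", "others", "unscorable")
}

#' @rdname cellCategories
#' @export
segregationModes <- function() {
    c("alternate", "adjacent_13", "adjacent_14", "three_to_zero")
}

#' Reporting group of a cell category
#'
#' Rolls the fine-grained categories up to the groups used in every report
#' table: trisomy, triploidy, tetraploidy and multiple aneuploidies all count
#' as "others"; unscorable nuclei are excluded from denominators.
#'
#' @param category Character vector of categories from [cellCategories()].
#' @return Character vector: one of normal, nullisomy, disomy, diploidy,
#'   others, excluded.
#' @export
#' @examples
#' reportingGroup(c("trisomy", "haploid_normal", "unscorable"))
reportingGroup <- function(category) {
    map <- c(haploid_normal = "normal", nullisomy = "nullisomy",
             disomy = "disomy", diploidy = "diploidy",
             trisomy = "others", triploidy = "others",
             tetraploidy = "others", multiple_aneuploidy = "others",
             unscorable = "excluded")
    bad <- setdiff(unique(category), names(map))
    if (length(bad))
        stopValidation("unknown cell category: %s", paste(bad, collapse = ", "))
    unname(map[category])
}

## ---------------------------------------------------------------------------
## ProbePanel
## ---------------------------------------------------------------------------

#' FISH probe panel
#'
#' An S4 class describing one hybridization round: the test probe(s)
#' interrogating the chromosome(s) of interest and the internal
#' ploidy-control probe set. Three kinds are distinguished because the
#' scoring rules differ: `"translocated"` (tri-color 13q + 14q + control),
#' `"autosome"` (one autosomal test probe + control, where the control may
#' be the X+Y centromere pair counted as one set), and `"sex"` (X + Y test
#' probes + autosomal control).
#'
#' @slot panelId Character scalar identifying the panel.
#' @slot kind One of `"translocated"`, `"autosome"`, `"sex"`.
#' @slot probes `data.frame` with columns `name`, `target`, `color`, `role`
#'   (`"test"` or `"control"`).
#' @export
setClass("ProbePanel",
    representation(panelId = "character", kind = "character",
                   probes = "data.frame"))

setValidity("ProbePanel", function(object) {
    msg <- character()
    if (length(object@panelId) != 1L || !nzchar(object@panelId))
        msg <- c(msg, "panelId must be a non-empty string")
    if (!object@kind %in% c("translocated", "autosome", "sex"))
        msg <- c(msg, "kind must be translocated, autosome or sex")
    pr <- object@probes
    need <- c("name", "target", "color", "role")
    if (!all(need %in% names(pr))) {
        msg <- c(msg, sprintf("probes must have columns %s",
                              paste(need, collapse = ", ")))
    } else {
        if (!any(pr$role == "test"))
            msg <- c(msg, "panel needs at least one test probe")
        if (!any(pr$role == "control"))
            msg <- c(msg, "panel needs a ploidy-control probe set")
        if (anyDuplicated(pr$color))
            msg <- c(msg, "probe colors must be unique within a panel")
        nTest <- sum(pr$role == "test")
        if (object@kind == "translocated" && nTest != 2L)
            msg <- c(msg, "translocated panel needs exactly two test probes")
        if (object@kind == "sex" && nTest != 2L)
            msg <- c(msg, "sex panel needs exactly two test probes (X and Y)")
        if (object@kind == "autosome" && nTest != 1L)
            msg <- c(msg, "autosome panel needs exactly one test probe")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ProbePanel Constructor.
#' @param panelId,kind,probes See slots.
#' @export
ProbePanel <- function(panelId, kind, probes) {
    probes <- as.data.frame(probes, stringsAsFactors = FALSE)
    new("ProbePanel", panelId = panelId, kind = kind, probes = probes)
}

#' @describeIn ProbePanel Panel identifier.
#' @param object A `ProbePanel`.
#' @export
setGeneric("panelId", function(object) standardGeneric("panelId"))
#' @rdname ProbePanel-class
#' @export
setMethod("panelId", "ProbePanel", function(object) object@panelId)

#' @describeIn ProbePanel Panel kind.
#' @export
setGeneric("panelKind", function(object) standardGeneric("panelKind"))
#' @rdname ProbePanel-class
#' @export
setMethod("panelKind", "ProbePanel", function(object) object@kind)

#' @describeIn ProbePanel Probe table.
#' @export
setGeneric("probes", function(object) standardGeneric("probes"))
#' @rdname ProbePanel-class
#' @export
setMethod("probes", "ProbePanel", function(object) object@probes)

setMethod("show", "ProbePanel", function(object) {
    cat(sprintf("ProbePanel '%s' (%s)\n", object@panelId, object@kind))
    p <- object@probes
    for (i in seq_len(nrow(p)))
        cat(sprintf("  %-12s %-8s %-7s %s\n",
                    p$name[i], p$target[i], p$color[i], p$role[i]))
})

## ---------------------------------------------------------------------------
## SlideClassification
## ---------------------------------------------------------------------------

#' Classified FISH slide
#'
#' Result container for [classifySlide()]: per-category counts (and, for the
#' translocated tri-color panel, per-mode-call counts), the number of
#' scorable nuclei and the number excluded as unscorable.
#'
#' @slot panelId Panel the counts refer to.
#' @slot kind Panel kind (see [ProbePanel-class]).
#' @slot categoryCounts Named integer vector over [cellCategories()]
#'   (without `unscorable`).
#' @slot modeCounts Named integer vector over [modeCalls()] (without
#'   `unscorable`); empty for non-translocated panels.
#' @slot subtypeCounts Named integer vector of sex-chromosome subtypes
#'   (haploid_X, haploid_Y, disomy_XX, disomy_YY, disomy_XY); empty
#'   otherwise.
#' @slot nScored,nUnscorable Integer scalars.
#' @export
setClass("SlideClassification",
    representation(panelId = "character", kind = "character",
                   categoryCounts = "integer", modeCounts = "integer",
                   subtypeCounts = "integer",
                   nScored = "integer", nUnscorable = "integer"))

setValidity("SlideClassification", function(object) {
    if (sum(object@categoryCounts) != object@nScored)
        return("category counts must sum to nScored")
    if (length(object@modeCounts) &&
        sum(object@modeCounts) != object@nScored)
        return("mode counts must sum to nScored")
    TRUE
})

#' @describeIn SlideClassification Per-category counts.
#' @param object A `SlideClassification`.
#' @export
setGeneric("categoryCounts", function(object) standardGeneric("categoryCounts"))
#' @rdname SlideClassification-class
#' @export
setMethod("categoryCounts", "SlideClassification",
          function(object) object@categoryCounts)

#' @describeIn SlideClassification Per-mode-call counts (translocated panel).
#' @export
setGeneric("modeCounts", function(object) standardGeneric("modeCounts"))
#' @rdname SlideClassification-class
#' @export
setMethod("modeCounts", "SlideClassification",
          function(object) object@modeCounts)

#' @describeIn SlideClassification Number of scorable nuclei.
#' @export
setGeneric("nScored", function(object) standardGeneric("nScored"))
#' @rdname SlideClassification-class
#' @export
setMethod("nScored", "SlideClassification", function(object) object@nScored)

#' @describeIn SlideClassification Number of excluded (unscorable) nuclei.
#' @export
setGeneric("nUnscorable", function(object) standardGeneric("nUnscorable"))
#' @rdname SlideClassification-class
#' @export
setMethod("nUnscorable", "SlideClassification",
          function(object) object@nUnscorable)

setMethod("show", "SlideClassification", function(object) {
    cat(sprintf("SlideClassification '%s' (%s): %d scored, %d unscorable\n",
                object@panelId, object@kind, object@nScored,
                object@nUnscorable))
    cc <- object@categoryCounts[object@categoryCounts > 0]
    if (length(cc))
        cat("  ", paste(sprintf("%s=%d", names(cc), cc), collapse = " "),
            "\n", sep = "")
})
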