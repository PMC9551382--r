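## Default probe-panel layouts mirroring the study design, plus JSON I/O.

#' Built-in probe panels
#'
#' `translocatedPanel()` is the tri-color panel for the translocated
#' chromosomes: an RB1 locus probe for 13q (green), a 14q subtelomere probe
#' (orange) and a chromosome-18 centromere probe (aqua) as the internal
#' ploidy control. `autosomePanel(chrom)` builds the dual/tri-color panel
#' for one nontranslocated autosome; chromosomes 1-4, 6-12 and 16-18 use
#' the X+Y centromere pair as the control set, the others a chromosome-18
#' control (chromosome 18 itself uses the XY control). `sexPanel()` is the
#' X + Y panel with an autosomal control.
#'
#' @param chrom Autosome number (1-12, 15-22 for carriers; donors also use
#'   13 and 14 dual-color panels).
#' @return A [ProbePanel-class] object.
#' @export
#' @examples
#' translocatedPanel()
#' autosomePanel(21)
translocatedPanel <- function() {
    ProbePanel("tri_13_14", "translocated", data.frame(
        name = c("RB1_13q", "subtel_14q", "cen_18"),
        target = c("13", "14", "18"),
        color = c("green", "orange", "aqua"),
        role = c("test", "test", "control")))
}

#' @rdname translocatedPanel
#' @export
autosomePanel <- function(chrom) {
    chrom <- as.integer(chrom)
    if (!chrom %in% 1:22)
        stopConfig("autosomePanel: chromosome must be 1-22, got %s", chrom)
    xyControl <- chrom %in% c(1:4, 6:12, 16:18)
    ctrl <- if (xyControl) {
        data.frame(name = c("cen_X", "cen_Y"), target = c("X", "Y"),
                   color = c("aqua", "gold"), role = "control")
    } else {
        data.frame(name = "cen_18", target = "18", color = "aqua",
                   role = "control")
    }
    test <- data.frame(name = sprintf("probe_%d", chrom),
                       target = as.character(chrom), color = "green",
                       role = "test")
    ProbePanel(sprintf("chr%d", chrom), "autosome", rbind(test, ctrl))
}

#' @rdname translocatedPanel
#' @export
sexPanel <- function() {
    ProbePanel("sex", "sex", data.frame(
        name = c("cen_X", "cen_Y", "cen_18"),
        target = c("X", "Y", "18"),
        color = c("green", "orange", "aqua"),
        role = c("test", "test", "control")))
}

#' Default panel set for one study arm
#'
#' Carriers get the tri-color translocated panel plus 20 autosome panels
#' (1-12, 15-22) and the sex panel; donors get 22 autosome panels (1-22)
#' plus the sex panel.
#'
#' @param arm `"carrier"` or `"donor"`.
#' @return Named list of [ProbePanel-class] objects keyed by panel id.
#' @export
#' @examples
#' names(defaultPanels("carrier"))
defaultPanels <- function(arm = c("carrier", "donor")) {
    arm <- match.arg(arm)
    autos <- if (arm == "carrier") NONTRANS_AUTOSOMES else 1:22
    panels <- lapply(autos, autosomePanel)
    if (arm == "carrier")
        panels <- c(list(translocatedPanel()), panels)
    panels <- c(panels, list(sexPanel()))
    stats::setNames(panels, vapply(panels, panelId, character(1)))
}

#' Read / write probe-panel configurations as JSON
#'
#' The JSON layout is a list of panels, each with `panel_id`, `kind` and a
#' `probes` array of `{name, target, color, role}` records. A default
#' configuration mirroring the study design ships in
#' `system.file("extdata", "panels.json", package = "spermFISH")`.
#'
#' @param path Path to a JSON file.
#' @return `readPanelConfig()`: named list of [ProbePanel-class] objects.
#' @export
#' @examples
#' cfg <- system.file("extdata", "panels.json", package = "spermFISH")
#' panels <- readPanelConfig(cfg)
#' panels[["tri_13_14"]]
readPanelConfig <- function(path) {
    if (!file.exists(path))
        stopConfig("panel config not found: %s", path)
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    panels <- lapply(raw, function(entry) {
        if (is.null(entry$panel_id) || is.null(entry$kind) ||
            is.null(entry$probes))
            stopConfig("panel entries need panel_id, kind and probes")
        probes <- do.call(rbind, lapply(entry$probes, function(p)
            data.frame(name = p$name, target = p$target, color = p$color,
                       role = p$role)))
        ProbePanel(entry$panel_id, entry$kind, probes)
    })
    stats::setNames(panels, vapply(panels, panelId, character(1)))
}

#' @rdname readPanelConfig
#' @param panels Named list of [ProbePanel-class] objects.
#' @export
writePanelConfig <- function(panels, path) {
    out <- lapply(panels, function(p)
        list(panel_id = panelId(p), kind = panelKind(p), probes = probes(p)))
    jsonlite::write_json(unname(out), path, auto_unbox = TRUE,
                         dataframe = "rows", pretty = TRUE)
    invisible(path)
}
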