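## Seeded synthetic-cohort generator emulating the study design:
## per carrier one tri-color translocated slide plus 20 autosome slides and
## one sex-chromosome slide (~1,000 nuclei each); per donor 22 autosome
## slides plus the sex slide. Every draw is i.i.d. per nucleus; probe
## hybridization failure thins each probe-target copy independently.

.thin <- function(trueCount, failRate) {
    stats::rbinom(length(trueCount), trueCount, 1 - failRate)
}

#' Simulate the translocated tri-color slide of one carrier
#'
#' Per nucleus: draw diploid / "other" / a segregation mode from the
#' profile probabilities; within a mode pick one of the two complementary
#' gametes by fair coin; then thin every probe-target copy independently
#' by the per-copy hybridization-failure rates. "Other" nuclei emit a
#' triploid-like (3,3,3) genotype.
#'
#' @param profile A [CarrierProfile-class].
#' @param nCells Number of nuclei to score.
#' @param seed Optional integer; when given, seeds the RNG for a
#'   standalone reproducible slide.
#' @return `data.frame` of scored cells (`subject_id`, `panel_id`,
#'   `n_test1` = 13q, `n_test2` = 14q, `n_ctrl`).
#' @export
#' @examples
#' sl <- simulateTranslocatedSlide(carrierProfile(), 500, seed = 7)
#' table(sl$n_test1, sl$n_test2)
simulateTranslocatedSlide <- function(profile, nCells = 1000L,
                                      seed = NULL) {
    if (!is(profile, "CarrierProfile"))
        stopValidation("simulateTranslocatedSlide: 'profile' must be a CarrierProfile")
    validObject(profile)
    if (nCells < 1L)
        stopValidation("nCells must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    geno <- .genotypeTable(profile)
    idx <- sample.int(nrow(geno), nCells, replace = TRUE, prob = geno$prob)
    fT <- profile@probeFailure[["test"]]
    fC <- profile@probeFailure[["control"]]
    data.frame(subject_id = profile@subjectId, panel_id = "tri_13_14",
               n_test1 = .thin(geno$n13[idx], fT),
               n_test2 = .thin(geno$n14[idx], fT),
               n_ctrl = .thin(geno$nctrl[idx], fC))
}

## category draw shared by the nontranslocated simulators
.drawCategories <- function(nCells, rates) {
    if (sum(rates) > 1 + 1e-9)
        stopValidation("abnormality rates sum to %.4f > 1", sum(rates))
    probs <- c(rates, normal = 1 - sum(rates))
    sample(names(probs), nCells, replace = TRUE, prob = probs)
}

#' Simulate one nontranslocated-chromosome slide
#'
#' Autosome slides draw each nucleus's true category
#' (normal / nullisomy / disomy / diploidy / other-trisomy) and emit the
#' §-standard signal genotype, then apply per-copy probe failure — so a
#' test-probe failure on a normal nucleus is observed as nullisomy, the
#' confound the failure model exists to expose. Sex slides emit X/Y
#' patterns: meiosis-I nondisjunction yields XY disomy, meiosis-II yields
#' XX or YY (fair coin); normal haploids are X or Y; diploid nuclei carry
#' XX/XY/YY complements at 1/4, 1/2, 1/4.
#'
#' @param panel An autosome or sex [ProbePanel-class].
#' @param nCells Number of nuclei.
#' @param nullisomy,disomy,diploidy,other Per-cell category rates
#'   (autosome panels; `disomy` is ignored for sex panels).
#' @param sexNondisjMI,sexNondisjMII Sex-panel disomy rates by meiotic
#'   origin.
#' @param probeFailure Named `c(test=, control=)` per-copy failure rates.
#' @param subjectId Subject label stamped on the rows.
#' @param seed Optional integer seed.
#' @return `data.frame` of scored cells (`n_test2` is `NA` on dual-color
#'   autosome slides, the Y count on sex slides).
#' @export
#' @examples
#' sl <- simulateNontranslocatedSlide(autosomePanel(21), 1000,
#'     nullisomy = 0.011, disomy = 0.019, diploidy = 0.006, seed = 3)
#' head(sl)
simulateNontranslocatedSlide <- function(panel, nCells = 1000L,
    nullisomy = 0, disomy = 0, diploidy = 0, other = 0,
    sexNondisjMI = 0, sexNondisjMII = 0,
    probeFailure = c(test = 0, control = 0),
    subjectId = "subject", seed = NULL) {
    if (!is(panel, "ProbePanel") || panelKind(panel) == "translocated")
        stopConfig("simulateNontranslocatedSlide needs an autosome or sex panel")
    checkProb(c(nullisomy, disomy, diploidy, other, sexNondisjMI,
                sexNondisjMII), "rates")
    checkProb(probeFailure, "probeFailure")
    if (!is.null(seed)) set.seed(seed)
    fT <- probeFailure[["test"]]
    fC <- probeFailure[["control"]]
    if (panelKind(panel) == "autosome") {
        cat <- .drawCategories(nCells, c(
            nullisomy = nullisomy, disomy = disomy, diploidy = diploidy,
            other = other))
        t1 <- c(normal = 1L, nullisomy = 0L, disomy = 2L, diploidy = 2L,
                other = 3L)[cat]
        ct <- c(normal = 1L, nullisomy = 1L, disomy = 1L, diploidy = 2L,
                other = 1L)[cat]
        return(data.frame(subject_id = subjectId, panel_id = panelId(panel),
                          n_test1 = .thin(t1, fT),
                          n_test2 = NA_integer_,
                          n_ctrl = .thin(ct, fC)))
    }
    cat <- .drawCategories(nCells, c(
        nullisomy = nullisomy, mi = sexNondisjMI, mii = sexNondisjMII,
        diploidy = diploidy, other = other))
    n <- length(cat)
    x <- integer(n); y <- integer(n); ct <- rep(1L, n)
    coin <- stats::runif(n) < 0.5
    isNorm <- cat == "normal"
    x[isNorm & coin] <- 1L
    y[isNorm & !coin] <- 1L
    x[cat == "mi"] <- 1L; y[cat == "mi"] <- 1L
    isMII <- cat == "mii"
    x[isMII & coin] <- 2L
    y[isMII & !coin] <- 2L
    isDip <- cat == "diploidy"
    u <- stats::runif(n)
    x[isDip & u < 0.25] <- 2L
    y[isDip & u >= 0.75] <- 2L
    mixed <- isDip & u >= 0.25 & u < 0.75
    x[mixed] <- 1L; y[mixed] <- 1L
    ct[isDip] <- 2L
    isOth <- cat == "other"       # sex trisomy
    x[isOth & coin] <- 2L; y[isOth & coin] <- 1L
    x[isOth & !coin] <- 1L; y[isOth & !coin] <- 2L
    data.frame(subject_id = subjectId, panel_id = panelId(panel),
               n_test1 = .thin(x, fT), n_test2 = .thin(y, fT),
               n_ctrl = .thin(ct, fC))
}

## all slides of one carrier
.simulateCarrier <- function(profile, panels, nCells) {
    ice <- profile@iceMultiplier
    out <- list(simulateTranslocatedSlide(profile, nCells))
    for (chrom in NONTRANS_AUTOSOMES) {
        key <- as.character(chrom)
        out[[length(out) + 1L]] <- simulateNontranslocatedSlide(
            panels[[sprintf("chr%d", chrom)]], nCells,
            nullisomy = min(1, ice * profile@nullisomyRates[[key]]),
            disomy = min(1, ice * profile@disomyRates[[key]]),
            diploidy = profile@diploidyNontrans,
            other = profile@otherNontrans,
            probeFailure = profile@probeFailure,
            subjectId = profile@subjectId)
    }
    out[[length(out) + 1L]] <- simulateNontranslocatedSlide(
        panels[["sex"]], nCells,
        nullisomy = min(1, ice * profile@sexNullisomy),
        diploidy = profile@diploidyNontrans,
        other = profile@otherNontrans,
        sexNondisjMI = min(1, ice * profile@sexNondisjMI),
        sexNondisjMII = min(1, ice * profile@sexNondisjMII),
        probeFailure = profile@probeFailure,
        subjectId = profile@subjectId)
    do.call(rbind, out)
}

.simulateDonor <- function(profile, panels, nCells) {
    out <- list()
    for (chrom in 1:22) {
        key <- as.character(chrom)
        out[[length(out) + 1L]] <- simulateNontranslocatedSlide(
            panels[[sprintf("chr%d", chrom)]], nCells,
            nullisomy = profile@nullisomyRates[[key]],
            disomy = profile@disomyRates[[key]],
            diploidy = profile@diploidy, other = profile@otherRate,
            probeFailure = profile@probeFailure,
            subjectId = profile@subjectId)
    }
    out[[length(out) + 1L]] <- simulateNontranslocatedSlide(
        panels[["sex"]], nCells,
        nullisomy = profile@sexNullisomy, diploidy = profile@diploidy,
        other = profile@otherRate,
        sexNondisjMI = profile@sexNondisjMI,
        sexNondisjMII = profile@sexNondisjMII,
        probeFailure = profile@probeFailure,
        subjectId = profile@subjectId)
    do.call(rbind, out)
}

.profileTruth <- function(p) {
    if (is(p, "CarrierProfile")) {
        vals <- c(modeProbs(p),
                  diploidy = p@diploidy, others = p@otherRate,
                  diploidy_nontrans = p@diploidyNontrans,
                  others_nontrans = p@otherNontrans,
                  stats::setNames(p@nullisomyRates,
                      paste0("nullisomy_", names(p@nullisomyRates))),
                  stats::setNames(p@disomyRates,
                      paste0("disomy_", names(p@disomyRates))),
                  sex_nondisj_MI = p@sexNondisjMI,
                  sex_nondisj_MII = p@sexNondisjMII,
                  sex_nullisomy = p@sexNullisomy,
                  ice_multiplier = p@iceMultiplier,
                  failure_test = p@probeFailure[["test"]],
                  failure_control = p@probeFailure[["control"]])
        arm <- "carrier"; sev <- p@severity
    } else {
        vals <- c(stats::setNames(p@nullisomyRates,
                      paste0("nullisomy_", names(p@nullisomyRates))),
                  stats::setNames(p@disomyRates,
                      paste0("disomy_", names(p@disomyRates))),
                  diploidy = p@diploidy, others = p@otherRate,
                  sex_nondisj_MI = p@sexNondisjMI,
                  sex_nondisj_MII = p@sexNondisjMII,
                  sex_nullisomy = p@sexNullisomy,
                  failure_test = p@probeFailure[["test"]],
                  failure_control = p@probeFailure[["control"]])
        arm <- "donor"; sev <- NA_character_
    }
    data.frame(subject_id = subjectId(p), arm = arm, severity = sev,
               parameter = names(vals), value = unname(vals))
}

#' Severity-group rate presets
#'
#' Mean nontranslocated-chromosome rates (percent) by semen-severity
#' group: nullisomy 1.49 / 0.83 / 0.47 and diploidy 0.74 / 0.77 / 0.51 for
#' severe oligozoospermia, oligoasthenoteratozoospermia (OAT) and
#' teratozoospermia; disomy runs the other way (0.48 / 0.59 / 0.64).
#'
#' @return `data.frame` with columns `severity`, `nullisomy`, `disomy`,
#'   `diploidy` (percent).
#' @export
severityPresets <- function() {
    data.frame(
        severity = c("severe_oligozoospermia",
                     "oligoasthenoteratozoospermia", "teratozoospermia"),
        nullisomy = c(1.49, 0.83, 0.47),
        disomy = c(0.48, 0.59, 0.64),
        diploidy = c(0.74, 0.77, 0.51))
}

#' Default study-design cohort profiles
#'
#' `defaultCarrierCohort()` builds the 10-carrier arm (one severe
#' oligozoospermic, three OAT, six teratozoospermic); each carrier's
#' per-chromosome nullisomy/disomy rates are rescaled so their mean
#' matches the [severityPresets()] value of its group, and its
#' nontranslocated diploidy follows the group preset.
#' `defaultDonorCohort()` builds 10 control donors at [donorProfile()]
#' defaults.
#'
#' @param n Number of subjects.
#' @return List of profiles.
#' @export
#' @examples
#' length(defaultCarrierCohort())
defaultCarrierCohort <- function(n = 10L) {
    sev <- rep(c("severe_oligozoospermia", "oligoasthenoteratozoospermia",
                 "teratozoospermia"),
               times = pmax(0, c(1, 3, n - 4)))[seq_len(n)]
    pre <- severityPresets()
    lapply(seq_len(n), function(i) {
        pr <- pre[pre$severity == sev[i], ]
        nullScale <- (pr$nullisomy / 100) / mean(.carrierNullisomyPct / 100)
        disScale <- (pr$disomy / 100) / mean(.carrierDisomyPct / 100)
        carrierProfile(sprintf("carrier%02d", i),
            nullisomyRates = pmin(.carrierNullisomyPct / 100 * nullScale, 1),
            disomyRates = pmin(.carrierDisomyPct / 100 * disScale, 1),
            diploidyNontrans = pr$diploidy / 100,
            severity = sev[i], seed = i)
    })
}

#' @rdname defaultCarrierCohort
#' @export
defaultDonorCohort <- function(n = 10L) {
    lapply(seq_len(n), function(i)
        donorProfile(sprintf("donor%02d", i), seed = i))
}

#' Simulate a complete two-arm cohort
#'
#' Generates every panel for every subject — the full scored-cell dataset
#' the classifier and frequency pipeline consume — plus a ground-truth
#' parameter table for recovery tests. The truth table is emitted
#' separately from the scored cells so no generating parameter leaks into
#' the analysis path. Byte-identical output under the same `seed`.
#'
#' @param carriers List of [CarrierProfile-class] objects.
#' @param donors List of [DonorProfile-class] objects.
#' @param nCells Nuclei per slide (the study scored ~1,000).
#' @param seed Master seed.
#' @return List with elements `cells` (scored-cell `data.frame`), `truth`
#'   (long `data.frame`: `subject_id`, `arm`, `severity`, `parameter`,
#'   `value`) and `subjects` (metadata `data.frame`).
#' @export
#' @examples
#' sim <- simulateCohort(defaultCarrierCohort(2), defaultDonorCohort(2),
#'                       nCells = 200, seed = 11)
#' nrow(sim$cells)
simulateCohort <- function(carriers = defaultCarrierCohort(),
                           donors = defaultDonorCohort(),
                           nCells = 1000L, seed = 1L) {
    ids <- c(vapply(carriers, subjectId, character(1)),
             vapply(donors, subjectId, character(1)))
    if (anyDuplicated(ids))
        stopValidation("duplicate subject ids: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (length(carriers) + length(donors) < 1L)
        stopEmpty("simulateCohort: no subjects")
    set.seed(seed)
    carrierPanels <- defaultPanels("carrier")
    donorPanels <- defaultPanels("donor")
    cells <- do.call(rbind, c(
        lapply(carriers, .simulateCarrier, panels = carrierPanels,
               nCells = nCells),
        lapply(donors, .simulateDonor, panels = donorPanels,
               nCells = nCells)))
    truth <- do.call(rbind, lapply(c(carriers, donors), .profileTruth))
    subjects <- data.frame(
        subject_id = ids,
        arm = rep(c("carrier", "donor"),
                  c(length(carriers), length(donors))),
        severity = c(vapply(carriers, function(p) p@severity,
                            character(1)),
                     rep(NA_character_, length(donors))))
    rownames(cells) <- rownames(truth) <- NULL
    list(cells = cells, truth = truth, subjects = subjects)
}
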