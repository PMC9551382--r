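## Generative subject profiles for the synthetic cohort.

NONTRANS_AUTOSOMES <- c(1:12, 15:22)

## Per-chromosome default rates (%) for a der(13;14) carrier. Chromosomes
## 1-12 follow the published per-chromosome table; 15, 18, 21, 22 and the
## sex chromosomes follow values stated in the text; 16, 17, 19, 20 are
## unpublished and fixed once at values consistent with the size-group
## ordering (small chromosomes 19-22 most disomy-prone). See the vignette.
.carrierNullisomyPct <- c(
    "1" = 0.57, "2" = 0.60, "3" = 1.64, "4" = 0.62, "5" = 0.30, "6" = 0.98,
    "7" = 0.35, "8" = 0.46, "9" = 0.54, "10" = 0.41, "11" = 0.56,
    "12" = 0.51, "15" = 0.50, "16" = 0.60, "17" = 0.40, "18" = 0.61,
    "19" = 0.70, "20" = 0.70, "21" = 1.11, "22" = 0.59)
.carrierDisomyPct <- c(
    "1" = 0.39, "2" = 0.44, "3" = 0.34, "4" = 0.29, "5" = 1.08, "6" = 0.28,
    "7" = 0.18, "8" = 0.17, "9" = 0.39, "10" = 0.17, "11" = 0.23,
    "12" = 0.29, "15" = 0.35, "16" = 0.20, "17" = 0.18, "18" = 0.18,
    "19" = 1.40, "20" = 0.31, "21" = 1.91, "22" = 1.13)

#' Carrier generative profile
#'
#' S4 class holding every parameter the synthetic-cohort generator needs for
#' one der(13;14) translocation carrier: trivalent segregation-mode
#' probabilities, sperm diploidy and "others" rates (split by panel because
#' the two slide types detect diploidy at different rates), per-chromosome
#' nondisjunction rates for the nontranslocated chromosomes, sex-chromosome
#' nondisjunction split into meiosis I (producing XY disomy) and meiosis II
#' (producing XX or YY), an interchromosomal-effect multiplier, and
#' per-copy probe hybridization-failure rates.
#'
#' All rates are probabilities in \[0, 1\]. Mode probabilities plus the
#' translocated-slide diploidy and "others" rates must sum to 1 (every
#' nucleus on the tri-color slide is a segregation product, diploid, or
#' "other").
#'
#' @slot subjectId Character scalar.
#' @slot modeProbs Named numeric over [segregationModes()].
#' @slot diploidy,otherRate Translocated-slide diploidy / "others" rates.
#' @slot diploidyNontrans,otherNontrans Same, for nontranslocated slides.
#' @slot nullisomyRates,disomyRates Named numeric over chromosomes
#'   1-12, 15-22 (as character names).
#' @slot sexNondisjMI,sexNondisjMII,sexNullisomy Sex-chromosome rates.
#' @slot iceMultiplier Multiplier (>= 1) on nontranslocated nondisjunction.
#' @slot probeFailure Named numeric `c(test=, control=)`: per-copy
#'   hybridization-failure probability.
#' @slot severity One of `"severe_oligozoospermia"`,
#'   `"oligoasthenoteratozoospermia"`, `"teratozoospermia"`.
#' @slot seed Integer scalar used when the profile is simulated standalone.
#' @export
setClass("CarrierProfile",
    representation(subjectId = "character", modeProbs = "numeric",
                   diploidy = "numeric", otherRate = "numeric",
                   diploidyNontrans = "numeric", otherNontrans = "numeric",
                   nullisomyRates = "numeric", disomyRates = "numeric",
                   sexNondisjMI = "numeric", sexNondisjMII = "numeric",
                   sexNullisomy = "numeric", iceMultiplier = "numeric",
                   probeFailure = "numeric", severity = "character",
                   seed = "integer"))

setValidity("CarrierProfile", function(object) {
    msg <- character()
    if (!setequal(names(object@modeProbs), segregationModes()))
        msg <- c(msg, "modeProbs must be named over the four segregation modes")
    if (any(object@modeProbs < 0) || any(object@modeProbs > 1))
        msg <- c(msg, "modeProbs must lie in [0, 1]")
    tot <- sum(object@modeProbs) + object@diploidy + object@otherRate
    if (abs(tot - 1) > 1e-6)
        msg <- c(msg, sprintf(
            "modeProbs + diploidy + otherRate must sum to 1 (got %.8f)", tot))
    want <- as.character(NONTRANS_AUTOSOMES)
    if (!setequal(names(object@nullisomyRates), want) ||
        !setequal(names(object@disomyRates), want))
        msg <- c(msg, "nullisomyRates/disomyRates must cover chromosomes 1-12, 15-22")
    rates <- c(object@nullisomyRates, object@disomyRates,
               object@diploidyNontrans, object@otherNontrans,
               object@sexNondisjMI, object@sexNondisjMII,
               object@sexNullisomy, object@probeFailure)
    if (any(rates < 0) || any(rates > 1))
        msg <- c(msg, "all rates must lie in [0, 1]")
    if (object@iceMultiplier < 1)
        msg <- c(msg, "iceMultiplier must be >= 1")
    if (!setequal(names(object@probeFailure), c("test", "control")))
        msg <- c(msg, "probeFailure must be named c(test=, control=)")
    if (!object@severity %in% c("severe_oligozoospermia",
                                "oligoasthenoteratozoospermia",
                                "teratozoospermia"))
        msg <- c(msg, "unknown severity label")
    if (length(msg)) msg else TRUE
})

#' Construct a carrier profile
#'
#' Defaults reproduce the study's carrier cohort means: segregation-mode
#' vector (alternate 74.37%, adjacent 23.42% split equally between the two
#' adjacent variants, 3:0 1.63%), tri-color-slide diploidy 0.31% and
#' "others" 0.26% (normalized to sum to 1), per-chromosome nondisjunction
#' rates from the per-chromosome results, XY-disomy 0.31% via meiosis I and
#' XX/YY 0.16% each via meiosis II, and a 0.2% per-copy probe-failure rate.
#'
#' @param subjectId Subject identifier.
#' @param modeProbs Named numeric over [segregationModes()].
#' @param diploidy,otherRate Translocated-slide diploidy and "others"
#'   probabilities.
#' @param diploidyNontrans,otherNontrans Nontranslocated-slide diploidy and
#'   "others" probabilities.
#' @param nullisomyRates,disomyRates Named per-chromosome rates
#'   (probabilities, chromosomes 1-12 and 15-22).
#' @param sexNondisjMI,sexNondisjMII,sexNullisomy Sex-chromosome rates.
#' @param iceMultiplier Interchromosomal-effect multiplier (>= 1) applied to
#'   the nontranslocated nondisjunction rates at simulation time.
#' @param probeFailure Named numeric `c(test=, control=)`.
#' @param severity Semen-phenotype label.
#' @param seed Integer seed.
#' @return A [CarrierProfile-class] object.
#' @export
#' @examples
#' p <- carrierProfile("carrier01")
#' sum(slot(p, "modeProbs"))
carrierProfile <- function(subjectId = "carrier01",
    modeProbs = NULL,
    diploidy = 0.0031, otherRate = 0.0026,
    diploidyNontrans = 0.0059, otherNontrans = 0.0003,
    nullisomyRates = .carrierNullisomyPct / 100,
    disomyRates = .carrierDisomyPct / 100,
    sexNondisjMI = 0.0031, sexNondisjMII = 0.0032,
    sexNullisomy = 0.0092, iceMultiplier = 1,
    probeFailure = c(test = 0.002, control = 0.002),
    severity = "teratozoospermia", seed = 1L) {
    if (is.null(modeProbs)) {
        modeProbs <- c(alternate = 0.7437, adjacent_13 = 0.1171,
                       adjacent_14 = 0.1171, three_to_zero = 0.0163)
        ## cohort-mean columns sum to 99.99%; absorb rounding into alternate
        modeProbs["alternate"] <- 1 - sum(modeProbs[-1]) - diploidy - otherRate
    }
    new("CarrierProfile", subjectId = subjectId, modeProbs = modeProbs,
        diploidy = diploidy, otherRate = otherRate,
        diploidyNontrans = diploidyNontrans, otherNontrans = otherNontrans,
        nullisomyRates = nullisomyRates[as.character(NONTRANS_AUTOSOMES)],
        disomyRates = disomyRates[as.character(NONTRANS_AUTOSOMES)],
        sexNondisjMI = sexNondisjMI, sexNondisjMII = sexNondisjMII,
        sexNullisomy = sexNullisomy, iceMultiplier = iceMultiplier,
        probeFailure = probeFailure, severity = severity,
        seed = as.integer(seed))
}

#' Donor (control) generative profile
#'
#' Baseline per-chromosome disomy/nullisomy rates for a normozoospermic
#' control donor. Per-chromosome donor rates were not published; defaults
#' spread the donors' cumulative rates uniformly over the 22 chromosome
#' slides (disomy 3.21%/22, nullisomy 7.08%/22 per slide) with diploidy
#' 0.36%.
#'
#' @slot subjectId Character scalar.
#' @slot nullisomyRates,disomyRates Named numeric over chromosomes 1-22.
#' @slot sexNondisjMI,sexNondisjMII,sexNullisomy Sex-chromosome rates.
#' @slot diploidy,otherRate Per-slide diploidy / "others" rates.
#' @slot probeFailure Named numeric `c(test=, control=)`.
#' @slot seed Integer scalar.
#' @export
setClass("DonorProfile",
    representation(subjectId = "character",
                   nullisomyRates = "numeric", disomyRates = "numeric",
                   sexNondisjMI = "numeric", sexNondisjMII = "numeric",
                   sexNullisomy = "numeric",
                   diploidy = "numeric", otherRate = "numeric",
                   probeFailure = "numeric", seed = "integer"))

setValidity("DonorProfile", function(object) {
    msg <- character()
    want <- as.character(1:22)
    if (!setequal(names(object@nullisomyRates), want) ||
        !setequal(names(object@disomyRates), want))
        msg <- c(msg, "rates must cover chromosomes 1-22")
    rates <- c(object@nullisomyRates, object@disomyRates, object@diploidy,
               object@otherRate, object@sexNondisjMI, object@sexNondisjMII,
               object@sexNullisomy, object@probeFailure)
    if (any(rates < 0) || any(rates > 1))
        msg <- c(msg, "all rates must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname DonorProfile-class
#' @param subjectId,nullisomyRates,disomyRates,sexNondisjMI,sexNondisjMII,sexNullisomy,diploidy,otherRate,probeFailure,seed
#'   See slots.
#' @return A [DonorProfile-class] object.
#' @export
donorProfile <- function(subjectId = "donor01",
    nullisomyRates = stats::setNames(rep(0.0708 / 22, 22),
                                     as.character(1:22)),
    disomyRates = stats::setNames(rep(0.0321 / 22, 22),
                                  as.character(1:22)),
    sexNondisjMI = 0.0008, sexNondisjMII = 0.0007,
    sexNullisomy = 0.0032,
    diploidy = 0.0036, otherRate = 0.0002,
    probeFailure = c(test = 0.002, control = 0.002), seed = 1L) {
    new("DonorProfile", subjectId = subjectId,
        nullisomyRates = nullisomyRates[as.character(1:22)],
        disomyRates = disomyRates[as.character(1:22)],
        sexNondisjMI = sexNondisjMI, sexNondisjMII = sexNondisjMII,
        sexNullisomy = sexNullisomy, diploidy = diploidy,
        otherRate = otherRate, probeFailure = probeFailure,
        seed = as.integer(seed))
}

#' @describeIn CarrierProfile-class Subject identifier accessor.
#' @param object A profile object.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname CarrierProfile-class
#' @export
setMethod("subjectId", "CarrierProfile", function(object) object@subjectId)
#' @rdname DonorProfile-class
#' @export
setMethod("subjectId", "DonorProfile", function(object) object@subjectId)

#' @describeIn CarrierProfile-class Segregation-mode probabilities.
#' @export
setGeneric("modeProbs", function(object) standardGeneric("modeProbs"))
#' @rdname CarrierProfile-class
#' @export
setMethod("modeProbs", "CarrierProfile", function(object) object@modeProbs)

setMethod("show", "CarrierProfile", function(object) {
    cat(sprintf("CarrierProfile '%s' (%s)\n", object@subjectId,
                object@severity))
    mp <- object@modeProbs
    cat(sprintf("  modes: %s\n",
                paste(sprintf("%s=%.4f", names(mp), mp), collapse = " ")))
    cat(sprintf("  diploidy=%.4f others=%.4f ICE x%.2f failure(test)=%.3f\n",
                object@diploidy, object@otherRate, object@iceMultiplier,
                object@probeFailure[["test"]]))
})

setMethod("show", "DonorProfile", function(object) {
    cat(sprintf("DonorProfile '%s': mean disomy %.4f, mean nullisomy %.4f, diploidy %.4f\n",
                object@subjectId, mean(object@disomyRates),
                mean(object@nullisomyRates), object@diploidy))
})
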