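## The meiotic segregation model of the der(13;14) trivalent.
##
## At meiosis I the trivalent (der(13;14), chromosome 13, chromosome 14)
## partitions in one of four ways. Each mode yields two complementary
## gamete classes; the derivative chromosome contributes one 13q and one
## 14q probe-target copy to whichever gamete carries it, so copy counts
## across a complementary pair always sum to 2 for each chromosome.

#' Gamete genotypes produced by a segregation mode
#'
#' Returns the two complementary gamete classes of one trivalent
#' segregation mode as probe-target copy counts: `n13` (13q copies), `n14`
#' (14q copies) and `nctrl` (control-chromosome copies, 1 in any haploid
#' gamete). Alternate segregation yields the balanced pair \{13, 14\} and
#' \{der\} — observationally identical (one copy of each target);
#' adjacent-13 yields disomy 13 \{der, 13\} and nullisomy 13 \{14\};
#' adjacent-14 the mirror; 3:0 yields double disomy \{der, 13, 14\} and
#' double nullisomy \{\}.
#'
#' @param mode One of [segregationModes()].
#' @return `data.frame` with two rows and columns `n13`, `n14`, `nctrl`,
#'   `provenance`.
#' @export
#' @examples
#' enumerateGametes("three_to_zero")
enumerateGametes <- function(mode) {
    if (!is.character(mode) || length(mode) != 1L ||
        !mode %in% segregationModes())
        stopValidation("unknown segregation mode: %s",
                       paste(mode, collapse = ","))
    g <- switch(mode,
        alternate = data.frame(n13 = c(1L, 1L), n14 = c(1L, 1L)),
        adjacent_13 = data.frame(n13 = c(2L, 0L), n14 = c(1L, 1L)),
        adjacent_14 = data.frame(n13 = c(1L, 1L), n14 = c(2L, 0L)),
        three_to_zero = data.frame(n13 = c(2L, 0L), n14 = c(2L, 0L)))
    g$nctrl <- 1L
    g$provenance <- mode
    g
}

## Gamete/cell genotype table implied by a carrier profile on the
## tri-color slide: every segregation product (each complementary gamete
## at half its mode's probability), diploid sperm (2,2,2) and "others"
## (emitted as a triploid-like 3,3,3 pattern; see the vignette).
.genotypeTable <- function(profile) {
    stopifnot(is(profile, "CarrierProfile"))
    validObject(profile)
    rows <- do.call(rbind, lapply(segregationModes(), function(m) {
        g <- enumerateGametes(m)
        g$prob <- modeProbs(profile)[[m]] / 2
        g
    }))
    extra <- data.frame(
        n13 = c(2L, 3L), n14 = c(2L, 3L), nctrl = c(2L, 3L),
        provenance = c("diploid", "other"),
        prob = c(profile@diploidy, profile@otherRate))
    rbind(rows, extra)
}

#' Closed-form signal-pattern distribution for the tri-color slide
#'
#' Marginalizes the carrier's gamete genotype distribution over independent
#' per-copy probe hybridization failure to give the exact probability of
#' every observable signal pattern `(n13, n14, nctrl)` on the translocated
#' tri-color panel. Each probe-target copy hybridizes independently with
#' probability `1 - f` for its probe's failure rate `f`, so the observed
#' count given `k` true copies is Binomial(`k`, `1 - f`).
#'
#' This is the analytic oracle behind the simulator/classifier round-trip:
#' with all failure rates zero, the probability of each mode-diagnostic
#' pattern equals the generating mode probability (split between the two
#' complementary gametes).
#'
#' @param profile A [CarrierProfile-class].
#' @param panel A translocated [ProbePanel-class] (defaults to
#'   [translocatedPanel()]).
#' @return `data.frame` with columns `n13`, `n14`, `nctrl`, `prob`;
#'   probabilities sum to 1.
#' @export
#' @examples
#' p <- carrierProfile(probeFailure = c(test = 0, control = 0))
#' d <- expectedPatternDistribution(p)
#' sum(d$prob)
expectedPatternDistribution <- function(profile, panel = translocatedPanel()) {
    if (!is(panel, "ProbePanel") || panelKind(panel) != "translocated")
        stopConfig("expectedPatternDistribution needs the translocated tri-color panel")
    geno <- .genotypeTable(profile)
    fTest <- profile@probeFailure[["test"]]
    fCtrl <- profile@probeFailure[["control"]]
    checkProb(c(fTest, fCtrl), "probeFailure")
    maxN <- max(geno$n13, geno$n14, geno$nctrl)
    grid <- expand.grid(n13 = 0:maxN, n14 = 0:maxN, nctrl = 0:maxN)
    prob <- numeric(nrow(grid))
    for (i in seq_len(nrow(geno))) {
        prob <- prob + geno$prob[i] *
            stats::dbinom(grid$n13, geno$n13[i], 1 - fTest) *
            stats::dbinom(grid$n14, geno$n14[i], 1 - fTest) *
            stats::dbinom(grid$nctrl, geno$nctrl[i], 1 - fCtrl)
    }
    out <- cbind(grid, prob = prob)
    out <- out[out$prob > 0 | (out$n13 + out$n14 + out$nctrl) == 0, ]
    rownames(out) <- NULL
    out
}
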