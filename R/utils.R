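## Classed conditions so callers (and the CLI) can distinguish failure kinds.

stopValidation <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c("spermFISH_validation_error", "spermFISH_error")))
}

stopConfig <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c("spermFISH_config_error", "spermFISH_error")))
}

stopEmpty <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c("spermFISH_empty_error", "spermFISH_error")))
}

stopDegenerate <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
        class = c("spermFISH_degenerate_error", "spermFISH_error")))
}

#' Significance stars at the conventional thresholds
#'
#' Maps p-values to the star codes used throughout the reports:
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
#' @examples
#' pStars(c(0.2, 0.04, 0.004, 4e-4))
pStars <- function(p) {
    out <- character(length(p))
    out[!is.na(p) & p < 0.05]  <- "*"
    out[!is.na(p) & p < 0.01]  <- "**"
    out[!is.na(p) & p < 0.001] <- "***"
    out[is.na(p)] <- NA_character_
    out
}

## round() that keeps data.frame character columns intact
roundNumeric <- function(df, digits) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
    df
}

checkProb <- function(x, what) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
        stopValidation("'%s' must be numeric in [0, 1]", what)
    invisible(x)
}
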