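## Statistical comparisons: paired t, two-group tests, one-way ANOVA with
## Student-Newman-Keuls, Kruskal-Wallis with Steel-Dwass, and a binomial
## GLM with Bonferroni-adjusted pairwise severity contrasts.
##
## Every function returns tidy one-row-per-comparison data.frames with
## columns comparison, method, statistic, df, p, p_adjusted, stars, so
## results from different tests can be stacked into one report.

.statRow <- function(comparison, method, statistic, df, p,
                     p_adjusted = NA_real_) {
    starsOn <- ifelse(is.na(p_adjusted), p, p_adjusted)
    data.frame(comparison = comparison, method = method,
               statistic = unname(statistic), df = unname(df),
               p = unname(p), p_adjusted = unname(p_adjusted),
               stars = pStars(starsOn))
}

#' Dependent-samples (paired) t-test
#'
#' Classical paired t on per-subject value pairs: `t = mean(d) /
#' (sd(d)/sqrt(n))` with `df = n - 1` and a two-sided p. Identical pairs
#' (every difference exactly zero) return `t = 0, p = 1`; a nonzero
#' constant difference has zero variance and raises a degenerate-test
#' condition.
#'
#' @param x,y Numeric vectors of equal length >= 2, paired by subject.
#' @param labels Length-2 character used to build the comparison label.
#' @return One-row `data.frame` (see [twoGroupCompare()] for columns).
#' @export
#' @examples
#' t1 <- table1Carriers()
#' pairedT(t1$nullisomy13, t1$disomy13, c("nullisomy 13", "disomy 13"))
pairedT <- function(x, y, labels = c("x", "y")) {
    if (length(x) != length(y))
        stopValidation("pairedT: x and y must have equal length")
    n <- length(x)
    if (n < 2L)
        stopDegenerate("pairedT: need at least 2 pairs")
    d <- x - y
    cmp <- paste(labels, collapse = " vs ")
    if (all(d == 0))
        return(.statRow(cmp, "paired_t", 0, n - 1L, 1))
    sdd <- stats::sd(d)
    if (sdd == 0)
        stopDegenerate("pairedT: differences are constant (%g); t undefined",
                       d[1])
    tstat <- mean(d) / (sdd / sqrt(n))
    .statRow(cmp, "paired_t", tstat, n - 1L,
             2 * stats::pt(-abs(tstat), n - 1L))
}

#' Two-group comparison with a selectable test
#'
#' Carrier-versus-control comparison by one of four methods:
#' `"student_t"` (pooled-variance t), `"welch_t"`, `"mann_whitney"`
#' (Wilcoxon rank-sum; midranks for ties, exact p when sample sizes allow
#' and there are no ties, otherwise normal approximation with continuity
#' correction) or `"two_proportion"` (pooled two-proportion z on counts).
#' For `two_proportion`, `x` and `y` are length-2 `c(events, total)`
#' count pairs and the statistic is the signed z; equal proportions give
#' statistic 0.
#'
#' @param x,y Numeric vectors of values (or `c(events, total)` counts for
#'   `two_proportion`).
#' @param method Test name.
#' @param labels Length-2 character comparison labels.
#' @return One-row `data.frame`: `comparison`, `method`, `statistic`,
#'   `df`, `p`, `p_adjusted`, `stars`.
#' @export
#' @examples
#' twoGroupCompare(c(6, 1000), c(2, 1000), "two_proportion",
#'                 c("carrier", "donor"))
twoGroupCompare <- function(x, y,
    method = c("two_proportion", "student_t", "welch_t", "mann_whitney"),
    labels = c("group1", "group2")) {
    if (is.character(method) && length(method) == 1L &&
        !method %in% c("two_proportion", "student_t", "welch_t",
                       "mann_whitney"))
        stopConfig("unknown two-group method '%s'", method)
    method <- match.arg(method)
    cmp <- paste(labels, collapse = " vs ")
    if (method == "two_proportion") {
        if (length(x) != 2L || length(y) != 2L || x[1] > x[2] ||
            y[1] > y[2])
            stopValidation("two_proportion needs c(events, total) pairs")
        p1 <- x[1] / x[2]; p2 <- y[1] / y[2]
        pp <- (x[1] + y[1]) / (x[2] + y[2])
        se <- sqrt(pp * (1 - pp) * (1 / x[2] + 1 / y[2]))
        z <- if (p1 == p2) 0 else (p1 - p2) / se
        return(.statRow(cmp, method, z, NA_real_, 2 * stats::pnorm(-abs(z))))
    }
    if (length(x) < 2L || length(y) < 2L)
        stopDegenerate("need at least 2 values per group")
    if (method %in% c("student_t", "welch_t")) {
        ht <- stats::t.test(x, y, var.equal = method == "student_t")
        return(.statRow(cmp, method, unname(ht$statistic),
                        unname(ht$parameter), ht$p.value))
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    .statRow(cmp, method, unname(ht$statistic), NA_real_, ht$p.value)
}

#' One-way ANOVA with Student-Newman-Keuls post-test
#'
#' Fits the one-way fixed-effects ANOVA, and, when the overall F is
#' significant at `alpha`, performs the SNK stepwise procedure: group
#' means are ordered and each pair is tested against the studentized-range
#' distribution with the stretch of the pair (the number of ordered means
#' it spans) as the range parameter; a pair nested inside a retained
#' (nonsignificant) stretch is not declared significant. Unequal group
#' sizes use the harmonic-style standard error
#' `sqrt(MSE/2 * (1/ni + 1/nj))`. Critical values come from `ptukey`,
#' R's numerically integrated studentized-range distribution.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of group labels, same length.
#' @param alpha Significance level for the stepwise decisions.
#' @return `data.frame` of pairwise rows with extra columns `stretch` and
#'   `significant`; the overall fit is attached as
#'   `attr(, "anova")` (`F`, `df1`, `df2`, `p`).
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(5), rnorm(5), rnorm(5, 3))
#' g <- rep(c("a", "b", "c"), each = 5)
#' anovaSNK(v, g)
anovaSNK <- function(values, groups, alpha = 0.05) {
    groups <- factor(groups)
    if (nlevels(groups) < 2L)
        stopValidation("anovaSNK: need at least 2 groups")
    ns <- table(groups)
    if (any(ns < 2L))
        stopDegenerate("anovaSNK: every group needs >= 2 values (got %s)",
                       paste(ns, collapse = ","))
    k <- nlevels(groups)
    N <- length(values)
    means <- tapply(values, groups, mean)
    grand <- mean(values)
    ssb <- sum(ns * (means - grand)^2)
    sse <- sum((values - means[groups])^2)
    dfe <- N - k
    if (sse == 0 && ssb == 0) {
        fstat <- 0; pF <- 1; mse <- 0
    } else if (sse == 0) {
        stopDegenerate("anovaSNK: zero within-group variance")
    } else {
        mse <- sse / dfe
        fstat <- (ssb / (k - 1)) / mse
        pF <- stats::pf(fstat, k - 1, dfe, lower.tail = FALSE)
    }
    ord <- order(means)
    lev <- levels(groups)[ord]
    m <- means[ord]
    nOrd <- as.numeric(ns)[ord]
    rows <- list()
    blocked <- matrix(FALSE, k, k)
    overall <- pF < alpha
    ## widest stretches first so nonsignificant ranges can block sub-pairs
    pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
    pairs <- pairs[pairs$i < pairs$j, ]
    pairs <- pairs[order(-(pairs$j - pairs$i)), ]
    for (r in seq_len(nrow(pairs))) {
        i <- pairs$i[r]; j <- pairs$j[r]
        stretch <- j - i + 1L
        se <- sqrt(mse / 2 * (1 / nOrd[i] + 1 / nOrd[j]))
        q <- if (se == 0) 0 else (m[j] - m[i]) / se
        pPair <- if (mse == 0) 1 else
            stats::ptukey(q, stretch, dfe, lower.tail = FALSE)
        sig <- overall && !blocked[i, j] && pPair < alpha
        if (overall && !blocked[i, j] && pPair >= alpha && stretch > 2L) {
            for (a in i:(j - 1L)) for (b in (a + 1L):j)
                blocked[a, b] <- TRUE
        }
        row <- .statRow(paste(lev[j], "vs", lev[i]), "snk", q, dfe, pPair)
        row$stretch <- stretch
        row$significant <- sig
        rows[[length(rows) + 1L]] <- row
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "anova") <- data.frame(F = fstat, df1 = k - 1, df2 = dfe,
                                     p = pF)
    out
}

## tie-corrected standardized rank-sum statistic for one pair
.pairRankStat <- function(xi, xj) {
    ni <- length(xi); nj <- length(xj); N <- ni + nj
    rk <- rank(c(xi, xj))
    R <- sum(rk[seq_len(ni)])
    E <- ni * (N + 1) / 2
    V <- ni * nj / (N * (N - 1)) * (sum(rk^2) - N * (N + 1)^2 / 4)
    t <- if (V == 0) 0 else (R - E) / sqrt(V)
    list(t = t, R = R, V = V)
}

#' Kruskal-Wallis test with Steel-Dwass all-pairs comparisons
#'
#' Nonparametric analogue of [anovaSNK()] for skewed or
#' variance-heterogeneous frequency data. The omnibus test is
#' Kruskal-Wallis (tie-corrected); each pair is then re-ranked in
#' isolation and compared with the tie-corrected standardized rank-sum
#' statistic. The family-adjusted p-value refers `sqrt(2)|t|` to the
#' studentized-range distribution with `k` groups and infinite error
#' degrees of freedom (the Steel-Dwass reference); the raw pairwise
#' p-value is exact (full enumeration of group assignments) when the pair
#' has at most `exactThreshold` observations, otherwise a normal
#' approximation.
#'
#' @inheritParams anovaSNK
#' @param exactThreshold Largest pair size for exact enumeration.
#' @return `data.frame` of pairwise rows; the omnibus result is attached
#'   as `attr(, "kruskal")` (`H`, `df`, `p`).
#' @export
kruskalSteelDwass <- function(values, groups, exactThreshold = 12L) {
    groups <- factor(groups)
    if (nlevels(groups) < 2L)
        stopValidation("kruskalSteelDwass: need at least 2 groups")
    if (any(table(groups) < 2L))
        stopDegenerate("kruskalSteelDwass: every group needs >= 2 values")
    k <- nlevels(groups)
    if (length(unique(values)) == 1L) {
        kw <- data.frame(H = 0, df = k - 1, p = 1)
    } else {
        ht <- stats::kruskal.test(values, groups)
        kw <- data.frame(H = unname(ht$statistic),
                         df = unname(ht$parameter), p = ht$p.value)
    }
    lev <- levels(groups)
    rows <- list()
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        xi <- values[groups == lev[i]]
        xj <- values[groups == lev[j]]
        st <- .pairRankStat(xi, xj)
        N <- length(xi) + length(xj)
        if (N <= exactThreshold) {
            ## exact permutation distribution of the standardized statistic
            combos <- utils::combn(N, length(xi))
            pool <- c(xi, xj)
            tAbs <- apply(combos, 2, function(idx)
                abs(.pairRankStat(pool[idx], pool[-idx])$t))
            pRaw <- mean(tAbs >= abs(st$t) - 1e-12)
        } else {
            pRaw <- 2 * stats::pnorm(-abs(st$t))
        }
        pAdj <- stats::ptukey(sqrt(2) * abs(st$t), k, Inf,
                              lower.tail = FALSE)
        rows[[length(rows) + 1L]] <-
            .statRow(paste(lev[i], "vs", lev[j]), "steel_dwass",
                     st$t, NA_real_, pRaw, pAdj)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "kruskal") <- kw
    out
}

#' Binomial GLM severity comparison with Bonferroni contrasts
#'
#' Models per-chromosome abnormal-cell counts as binomial with
#' semen-severity group and chromosome as additive factors (logit link,
#' fitted by iteratively reweighted least squares via `stats::glm`), i.e.
#' the comparison of severity groups is adjusted for chromosome. Pairwise
#' group contrasts are Wald tests on log-odds differences,
#' Bonferroni-multiplied by the number of pairs.
#'
#' @param counts `data.frame` with columns `chromosome`, `group`,
#'   `abnormal`, `total` (one row per chromosome x group).
#' @return `data.frame` of pairwise contrast rows with an extra `estimate`
#'   column (log-odds difference, group2 minus group1); the fitted model
#'   is attached as `attr(, "model")`.
#' @export
#' @examples
#' counts <- expand.grid(chromosome = c("1", "2"), group = c("a", "b"))
#' counts$total <- 1000
#' counts$abnormal <- c(12, 9, 25, 20)
#' glmSeverity(counts)
glmSeverity <- function(counts) {
    need <- c("chromosome", "group", "abnormal", "total")
    miss <- setdiff(need, names(counts))
    if (length(miss))
        stopValidation("glmSeverity: missing columns: %s",
                       paste(miss, collapse = ", "))
    if (any(counts$abnormal > counts$total) || any(counts$abnormal < 0))
        stopValidation("glmSeverity: abnormal counts must lie in [0, total]")
    counts$group <- factor(counts$group)
    counts$chromosome <- factor(counts$chromosome)
    tab <- table(counts$chromosome, counts$group)
    if (any(tab == 0))
        warning("glmSeverity: chromosome x group table is incomplete")
    form <- if (nlevels(counts$chromosome) > 1L) {
        cbind(abnormal, total - abnormal) ~ group + chromosome
    } else cbind(abnormal, total - abnormal) ~ group
    fit <- stats::glm(form, family = stats::binomial(), data = counts)
    if (!fit$converged)
        stopDegenerate("glmSeverity: IRLS did not converge in %d iterations (coefficients: %s)",
                       fit$iter,
                       paste(round(stats::coef(fit), 3), collapse = ", "))
    lev <- levels(counts$group)
    k <- length(lev)
    cf <- stats::coef(fit)
    V <- stats::vcov(fit)
    coefName <- function(g) if (g == lev[1]) NA_character_ else
        paste0("group", g)
    npairs <- k * (k - 1) / 2
    rows <- list()
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        ci <- coefName(lev[i]); cj <- coefName(lev[j])
        bi <- if (is.na(ci)) 0 else cf[[ci]]
        bj <- if (is.na(cj)) 0 else cf[[cj]]
        vii <- if (is.na(ci)) 0 else V[ci, ci]
        vjj <- if (is.na(cj)) 0 else V[cj, cj]
        vij <- if (is.na(ci) || is.na(cj)) 0 else V[ci, cj]
        est <- bj - bi
        se <- sqrt(vii + vjj - 2 * vij)
        z <- if (se == 0) 0 else est / se
        p <- 2 * stats::pnorm(-abs(z))
        row <- .statRow(paste(lev[j], "vs", lev[i]), "glm_binomial", z,
                        NA_real_, p, min(1, p * npairs))
        row$estimate <- est
        rows[[length(rows) + 1L]] <- row
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "model") <- fit
    out
}
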