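## Fixture builders and independent oracles used across the suite.

## expand a pattern table (n13, n14, nctrl, count) into a scored-cell df
expandTriCells <- function(patterns, subject = "s1") {
    idx <- rep(seq_len(nrow(patterns)), patterns$count)
    data.frame(subject_id = subject, panel_id = "tri_13_14",
               n_test1 = patterns$n13[idx], n_test2 = patterns$n14[idx],
               n_ctrl = patterns$nctrl[idx])
}

## Brute-force signal-pattern distribution: enumerate every gamete/cell
## genotype and every binary hybridization mask over its probe-target
## copies. Independent of the dbinom-based closed form under test.
bruteForcePatternDistribution <- function(modeProbs, diploidy, other,
                                          fTest, fCtrl) {
    genotypes <- list()
    addGeno <- function(n13, n14, nctrl, prob) {
        genotypes[[length(genotypes) + 1L]] <<-
            list(n13 = n13, n14 = n14, nctrl = nctrl, prob = prob)
    }
    gametes <- list(
        alternate = list(c(1, 1), c(1, 1)),
        adjacent_13 = list(c(2, 1), c(0, 1)),
        adjacent_14 = list(c(1, 2), c(1, 0)),
        three_to_zero = list(c(2, 2), c(0, 0)))
    for (m in names(gametes)) {
        for (g in gametes[[m]])
            addGeno(g[1], g[2], 1, modeProbs[[m]] / 2)
    }
    addGeno(2, 2, 2, diploidy)
    addGeno(3, 3, 3, other)

    acc <- new.env()
    addMass <- function(k13, k14, kc, p) {
        key <- paste(k13, k14, kc, sep = "_")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
    }
    for (geno in genotypes) {
        if (geno$prob == 0) next
        copies <- c(rep("t13", geno$n13), rep("t14", geno$n14),
                    rep("ctrl", geno$nctrl))
        fRates <- ifelse(copies == "ctrl", fCtrl, fTest)
        nMask <- length(copies)
        masks <- as.matrix(expand.grid(rep(list(0:1), nMask)))
        for (r in seq_len(nrow(masks))) {
            keep <- masks[r, ] == 1
            pMask <- prod(ifelse(keep, 1 - fRates, fRates))
            addMass(sum(keep & copies == "t13"),
                    sum(keep & copies == "t14"),
                    sum(keep & copies == "ctrl"), geno$prob * pMask)
        }
    }
    keys <- ls(acc)
    parts <- do.call(rbind, strsplit(keys, "_"))
    data.frame(n13 = as.integer(parts[, 1]),
               n14 = as.integer(parts[, 2]),
               nctrl = as.integer(parts[, 3]),
               prob = vapply(keys, function(k) acc[[k]], numeric(1)),
               row.names = NULL)
}

## population SD, from scratch
popSD <- function(x) sqrt(mean((x - mean(x))^2))

## exact permutation p-value for the two-sample rank-sum statistic
exactRankP <- function(x, y) {
    pool <- c(x, y)
    N <- length(pool)
    obs <- abs(spermFISH:::.pairRankStat(x, y)$t)
    combos <- utils::combn(N, length(x))
    tAbs <- apply(combos, 2, function(idx)
        abs(spermFISH:::.pairRankStat(pool[idx], pool[-idx])$t))
    mean(tAbs >= obs - 1e-12)
}

## a small valid carrier profile with chosen translocated-slide mixture
triProfile <- function(alternate, adj13 = 0, adj14 = 0, t30 = 0,
                       diploidy = 0, other = 0,
                       fTest = 0, fCtrl = 0) {
    carrierProfile("oracle",
        modeProbs = c(alternate = unname(alternate),
                      adjacent_13 = unname(adj13),
                      adjacent_14 = unname(adj14),
                      three_to_zero = unname(t30)),
        diploidy = diploidy, otherRate = other,
        probeFailure = c(test = fTest, control = fCtrl))
}
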