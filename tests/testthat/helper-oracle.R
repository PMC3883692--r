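# Independent step-by-step oracle for the moderated t-statistic.
# Deliberately written as plain scalar arithmetic, separate from the
# package's vectorized implementation: per-group means and variances,
# pooled variance, scaled inverse-chi-square prior fitted by moment
# matching on log variances (prior df via uniroot inversion of the
# trigamma equation), posterior variance, t and two-sided p.
oracleModeratedT <- function(groupA, groupB) {
    n <- nrow(groupA)
    delta <- s2 <- df <- numeric(n)
    for (i in seq_len(n)) {
        a <- groupA[i, ][!is.na(groupA[i, ])]
        b <- groupB[i, ][!is.na(groupB[i, ])]
        delta[i] <- mean(a) - mean(b)
        df[i] <- length(a) + length(b) - 2
        s2[i] <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df[i]
    }
    # prior fit on the ensemble
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    ebar <- mean(e)
    target <- mean((e - ebar)^2) * length(e) / (length(e) - 1) -
        mean(trigamma(df / 2))
    if (target > 0) {
        half <- uniroot(function(y) trigamma(y) - target,
                        lower = 1e-8, upper = 1e8, tol = 1e-14)$root
        d0 <- 2 * half
        s02 <- exp(ebar + digamma(half) - log(half))
    } else {
        d0 <- Inf
        s02 <- exp(ebar)
    }
    s2post <- if (is.infinite(d0)) rep(s02, n) else
        (d0 * s02 + df * s2) / (d0 + df)
    tmod <- p <- numeric(n)
    for (i in seq_len(n)) {
        nA <- sum(!is.na(groupA[i, ])); nB <- sum(!is.na(groupB[i, ]))
        se <- sqrt(s2post[i] * (1 / nA + 1 / nB))
        tmod[i] <- delta[i] / se
        p[i] <- if (is.infinite(d0)) 2 * pnorm(-abs(tmod[i])) else
            2 * pt(-abs(tmod[i]), d0 + df[i])
    }
    list(delta = delta, s2 = s2, d0 = d0, s02 = s02, s2post = s2post,
         t = tmod, p = p)
}

# ordinary pooled two-sample t (shrinkage-free reference)
plainPooledT <- function(a, b) {
    nA <- length(a); nB <- length(b)
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (nA + nB - 2)
    (mean(a) - mean(b)) / sqrt(s2 * (1 / nA + 1 / nB))
}
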